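#' Build a wild-type-versus-variant comparison configuration
#'
#' Assembles and validates the single configuration object driving
#' [run_comparison()]. Each system supplies its frames in one of three
#' ways: an in-memory [trajectory_ensemble()] (`ensemble`), a generator
#' recipe (`recipe`, an [ensemble_recipe()] or [detachment_recipe()]), or
#' files (`topology` path plus `trajectories` paths, with optional
#' `stride` and `dt`).
#'
#' @param systems named list of system descriptions (see Details); the
#'   wild type plus at least one variant.
#' @param wt name of the wild-type system (default: first).
#' @param regions named list of [region_spec()]s.
#' @param interface character pair `c(region_a, region_b)` naming the
#'   interface to quantify (names into `regions`).
#' @param fit_region optional region name used for superposition fitting.
#' @param discard_ns equilibration discarded per replica, ns (default 0).
#' @param contact_cutoff heavy-atom contact cutoff, A (default 5).
#' @param probe_radius SASA probe, A (default 1.4).
#' @param sasa_points sphere points per atom (default 960).
#' @param area_stride frame stride for interface-area series (default 1).
#' @param ndf_threshold NDF-difference classification threshold (default
#'   0.1).
#' @param pca_k leading components reported (default 3).
#' @param hbonds optional list of `list(donor, acceptor, mode)` atom-index
#'   pairs whose occupancy is reported per system.
#' @param bootstrap replica-block bootstrap resamples for interface-mean
#'   error bars (default 1000; 0 disables).
#' @param seed root seed for the bootstrap (default 1).
#' @param output_dir optional directory for `report.json` + `tables/*.csv`.
#' @return object of class `comparison_config`.
#' @export
comparison_config <- function(systems, wt = names(systems)[1], regions,
                              interface, fit_region = NULL, discard_ns = 0,
                              contact_cutoff = 5.0, probe_radius = 1.4,
                              sasa_points = 960L, area_stride = 1L,
                              ndf_threshold = 0.1, pca_k = 3L,
                              hbonds = NULL, bootstrap = 1000L, seed = 1L,
                              output_dir = NULL) {
  stopifnot(length(systems) >= 2, !is.null(names(systems)),
            wt %in% names(systems), length(interface) == 2,
            all(interface %in% names(regions)))
  if (!is.null(fit_region)) stopifnot(fit_region %in% names(regions))
  structure(list(systems = systems, wt = wt, regions = regions,
                 interface = interface, fit_region = fit_region,
                 discard_ns = discard_ns, contact_cutoff = contact_cutoff,
                 probe_radius = probe_radius,
                 sasa_points = as.integer(sasa_points),
                 area_stride = as.integer(area_stride),
                 ndf_threshold = ndf_threshold, pca_k = as.integer(pca_k),
                 hbonds = hbonds, bootstrap = as.integer(bootstrap),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "comparison_config")
}

#' Read a comparison configuration from a YAML file
#'
#' File layout: `systems:` (name -> `topology:` path, `trajectories:`
#' list, optional `stride`, `dt`), `wt:`, `regions:` (name -> list of
#' `"CHAIN:first-last"`), `interface: [a, b]`, and any of the scalar
#' options of [comparison_config()].
#'
#' @param path YAML config path.
#' @return a [comparison_config()].
#' @export
read_comparison_config <- function(path) {
  y <- yaml::read_yaml(path)
  regions <- lapply(names(y$regions), function(nm) {
    region_from_ranges(nm, unlist(y$regions[[nm]]))
  })
  names(regions) <- names(y$regions)
  args <- list(systems = y$systems, regions = regions,
               interface = unlist(y$interface))
  for (opt in c("wt", "fit_region", "discard_ns", "contact_cutoff",
                "probe_radius", "sasa_points", "area_stride",
                "ndf_threshold", "pca_k", "bootstrap", "seed",
                "output_dir")) {
    if (!is.null(y[[opt]])) args[[opt]] <- y[[opt]]
  }
  do.call(comparison_config, args)
}

# Materialise a system description into a trajectory ensemble.
resolve_system <- function(sys) {
  if (inherits(sys, "trajectory_ensemble")) return(sys)
  if (!is.null(sys$ensemble)) return(sys$ensemble)
  if (!is.null(sys$recipe)) {
    r <- sys$recipe
    if (inherits(r, "detachment_recipe")) {
      return(sample_detachment_ensemble(r))
    }
    return(sample_gaussian_ensemble(r))
  }
  if (!is.null(sys$topology)) {
    top <- load_topology(sys$topology)
    return(load_trajectory(top, unlist(sys$trajectories),
                           stride = if (is.null(sys$stride)) 1L else sys$stride,
                           dt = if (is.null(sys$dt)) 1 else sys$dt))
  }
  stop("system description needs an ensemble, a recipe, or topology + trajectories")
}

# Replica-block bootstrap (each replica one block) of a per-frame series
# mean. Returns c(lo, hi) 95% percentile interval, or NULL for < 2 blocks.
block_bootstrap_mean <- function(series, replica_labels, n_boot, seed) {
  labs <- unique(replica_labels)
  if (length(labs) < 2 || n_boot < 1) return(NULL)
  blocks <- lapply(labs, function(l) series[replica_labels == l])
  means <- local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      pick <- sample.int(length(blocks), replace = TRUE)
      mean(unlist(blocks[pick]))
    }, 0.0)
  })
  stats::quantile(means, c(0.025, 0.975), names = FALSE)
}

config_hash <- function(config) {
  strip <- config
  strip$output_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  serialize(strip, con, version = 2)
  close(con)
  unname(tools::md5sum(tmp))
}

#' Run the full wild-type-versus-variant comparison
#'
#' Executes the fixed stage order — pool, superpose, interface
#' contacts/areas (and optional hydrogen bonds), distance fluctuations and
#' NDF, cross-correlation matrices, PCA — for every system, then derives
#' all wild-type-relative quantities: percent changes of interface area
#' and contact count, per-residue NDF differences with per-region
#' summaries, pairwise similarity of the variant difference-DCCMs, and
#' per-system top-k PCA variance with region involvement. Each stage logs
#' frame counts to stderr. With `output_dir` set, writes `report.json`
#' and `tables/*.csv`; on error, partial outputs are removed and the
#' error names the failing stage and system.
#'
#' @param config a [comparison_config()].
#' @return the comparison report (nested list, JSON-shaped), invisibly
#'   written to disk when `output_dir` is configured.
#' @export
run_comparison <- function(config) {
  stopifnot(inherits(config, "comparison_config"))
  out_dir <- config$output_dir
  created <- character(0)
  stage <- "setup"
  sysname <- ""
  report <- tryCatch(
    run_comparison_impl(config, function(s, n = "") {
      stage <<- s; sysname <<- n
    }),
    error = function(e) {
      if (!is.null(out_dir)) {
        unlink(file.path(out_dir, "report.json"))
        unlink(file.path(out_dir, "tables"), recursive = TRUE)
      }
      stop("comparison failed at stage '", stage, "'",
           if (nzchar(sysname)) paste0(" (system '", sysname, "')"),
           ": ", conditionMessage(e), call. = FALSE)
    })
  if (!is.null(out_dir)) write_report(report, config, out_dir)
  report
}

log_stage <- function(...) message(sprintf(...))

run_comparison_impl <- function(config, set_stage) {
  sys_names <- names(config$systems)
  wt <- config$wt
  variants <- setdiff(sys_names, wt)
  reg <- config$regions
  ra <- reg[[config$interface[1]]]
  rb <- reg[[config$interface[2]]]
  fit <- if (is.null(config$fit_region)) NULL else reg[[config$fit_region]]

  per_sys <- list()
  for (nm in sys_names) {
    set_stage("load", nm)
    ens <- resolve_system(config$systems[[nm]])
    nf0 <- n_frames(ens)
    set_stage("pool", nm)
    ens <- pool_equilibrated(ens, config$discard_ns)
    log_stage("[pool] %s: %d -> %d frames (discard %g ns/replica)", nm,
              nf0, n_frames(ens), config$discard_ns)
    set_stage("superpose", nm)
    t0 <- proc.time()[["elapsed"]]
    ens <- superpose(ens, fit)
    log_stage("[superpose] %s: %d frames fitted (%.1f s)", nm,
              n_frames(ens), proc.time()[["elapsed"]] - t0)

    set_stage("contacts", nm)
    iface <- interface_timeseries(ens, ra, rb,
                                  cutoff = config$contact_cutoff,
                                  probe_radius = config$probe_radius,
                                  n_points = config$sasa_points,
                                  area_stride = config$area_stride)
    log_stage("[contacts] %s: Nc %.1f, area %.1f A^2", nm, iface$nc_mean,
              iface$area_mean)
    hb <- NULL
    if (!is.null(config$hbonds)) {
      set_stage("hbonds", nm)
      hb <- lapply(config$hbonds, function(site) {
        res <- hbond_occupancy(ens, donors = site$donor,
                               acceptors = site$acceptor,
                               mode = if (is.null(site$mode)) "strict"
                                      else site$mode)
        occ <- if (length(res) == 0) 0 else res[[1]]$occupancy
        list(donor = site$donor, acceptor = site$acceptor, occupancy = occ)
      })
    }

    set_stage("fluctuations", nm)
    ndf <- ndf_profile(distance_fluctuation_matrix(ens))
    set_stage("dccm", nm)
    cm <- dccm(ens)
    set_stage("pca", nm)
    pca <- suppressWarnings(pca_motions(ens))
    log_stage("[pca] %s: top-%d variance fraction %.3f", nm, config$pca_k,
              sum(pca$variance_fractions[seq_len(config$pca_k)]))

    boot <- list()
    if (config$bootstrap > 0) {
      set_stage("bootstrap", nm)
      nc_ci <- block_bootstrap_mean(iface$nc_series, ens$replica_labels,
                                    config$bootstrap, config$seed)
      ar_ci <- block_bootstrap_mean(iface$area_series,
                                    ens$replica_labels[iface$area_frames],
                                    config$bootstrap, config$seed + 1L)
      if (!is.null(nc_ci)) boot$nc_mean_ci95 <- nc_ci
      if (!is.null(ar_ci)) boot$area_mean_ci95 <- ar_ci
    }
    per_sys[[nm]] <- list(ens = ens, iface = iface, hb = hb, ndf = ndf,
                          dccm = cm, pca = pca, boot = boot)
  }

  set_stage("deltas", "")
  interface_block <- list(
    pair = as.list(config$interface),
    per_system = lapply(per_sys, function(s) c(
      list(nc_mean = s$iface$nc_mean, nc_sd = s$iface$nc_sd,
           area_mean = s$iface$area_mean, area_sd = s$iface$area_sd),
      s$boot)),
    percent_change = lapply(per_sys[variants], function(s) list(
      nc = percent_change(s$iface$nc_mean, per_sys[[wt]]$iface$nc_mean),
      area = percent_change(s$iface$area_mean,
                            per_sys[[wt]]$iface$area_mean))))

  deltas <- lapply(per_sys[variants], function(s) {
    d <- delta_ndf(s$ndf, per_sys[[wt]]$ndf, threshold = config$ndf_threshold)
    list(deltas = d$deltas,
         classification = as.character(d$classification),
         region_summary = region_summary(d, unname(reg)))
  })
  map <- per_sys[[wt]]$ndf$residue_index_map

  set_stage("similarity", "")
  diffs <- lapply(per_sys[variants], function(s) {
    dccm_difference(s$dccm, per_sys[[wt]]$dccm)
  })
  sim <- list()
  if (length(variants) >= 2) {
    pairs <- utils::combn(variants, 2)
    for (p in seq_len(ncol(pairs))) {
      v1 <- pairs[1, p]; v2 <- pairs[2, p]
      s <- matrix_similarity(diffs[[v1]], diffs[[v2]])
      sim[[paste(v1, v2, sep = "|")]] <- list(
        a = v1, b = v2, cosine = unname(s["cosine"]),
        spearman = unname(s["spearman"]))
    }
  }

  pca_block <- lapply(per_sys, function(s) {
    inv <- lapply(reg, function(rg) {
      region_involvement(s$pca, rg, k = config$pca_k)$fraction
    })
    list(top_k = config$pca_k,
         top_k_variance_fraction =
           sum(s$pca$variance_fractions[seq_len(config$pca_k)]),
         eigenvalues = s$pca$eigenvalues[seq_len(config$pca_k)],
         region_involvement = inv)
  })

  report <- list(
    systems = as.list(sys_names), wt = wt, variants = as.list(variants),
    parameters = list(contact_cutoff = config$contact_cutoff,
                      probe_radius = config$probe_radius,
                      sasa_points = config$sasa_points,
                      area_stride = config$area_stride,
                      discard_ns = config$discard_ns,
                      ndf_threshold = config$ndf_threshold,
                      pca_k = config$pca_k),
    frames = lapply(per_sys, function(s) n_frames(s$ens)),
    interface = interface_block,
    hbonds = lapply(per_sys, function(s) s$hb),
    residue_map = paste0(map$chain_id, ":", map$residue_index),
    delta_ndf = deltas,
    dccm_similarity = sim,
    pca = pca_block,
    provenance = list(package = "trajcomp",
                      version = as.character(utils::packageVersion("trajcomp")),
                      config_hash = config_hash(config),
                      seed = config$seed))
  report
}

# Report + CSV tables on disk. JSON written with full precision so rerun
# bytes match exactly.
write_report <- function(report, config, out_dir) {
  dir.create(file.path(out_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ifc <- report$interface
  rows <- do.call(rbind, lapply(names(ifc$per_system), function(nm) {
    p <- ifc$per_system[[nm]]
    data.frame(system = nm, nc_mean = p$nc_mean, nc_sd = p$nc_sd,
               area_mean = p$area_mean, area_sd = p$area_sd,
               delta_nc_pct = if (nm %in% names(ifc$percent_change))
                 ifc$percent_change[[nm]]$nc else 0,
               delta_area_pct = if (nm %in% names(ifc$percent_change))
                 ifc$percent_change[[nm]]$area else 0)
  }))
  utils::write.csv(rows, file.path(out_dir, "tables", "interface.csv"),
                   row.names = FALSE)
  dn <- data.frame(residue = unlist(report$residue_map))
  for (v in names(report$delta_ndf)) {
    dn[[paste0("delta_ndf_", v)]] <- unlist(report$delta_ndf[[v]]$deltas)
  }
  utils::write.csv(dn, file.path(out_dir, "tables", "delta_ndf.csv"),
                   row.names = FALSE)
  if (length(report$dccm_similarity) > 0) {
    sim <- do.call(rbind, lapply(report$dccm_similarity, function(s) {
      data.frame(a = s$a, b = s$b, cosine = s$cosine,
                 spearman = s$spearman)
    }))
    utils::write.csv(sim, file.path(out_dir, "tables", "similarity.csv"),
                     row.names = FALSE)
  }
  pc <- do.call(rbind, lapply(names(report$pca), function(nm) {
    p <- report$pca[[nm]]
    cbind(data.frame(system = nm,
                     top_k_variance_fraction = p$top_k_variance_fraction),
          as.data.frame(p$region_involvement))
  }))
  utils::write.csv(pc, file.path(out_dir, "tables", "pca.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' Interface scan over all chain pairs
#'
#' For every unordered chain pair with at least one heavy-atom contact in
#' at least one frame (in any system), reports per-system mean contact
#' count and interface area plus percent changes versus wild type —
#' the all-subunit-interfaces control around a focal interface.
#' Contact-free pairs are omitted with a log line.
#'
#' @param config a [comparison_config()] (regions/interface entries are
#'   ignored here; chains come from each system's topology).
#' @return data.frame, one row per (chain pair, variant).
#' @export
batch_interfaces <- function(config) {
  stopifnot(inherits(config, "comparison_config"))
  sys_names <- names(config$systems)
  wt <- config$wt
  ens_list <- lapply(config$systems, resolve_system)
  ens_list <- lapply(ens_list, pool_equilibrated,
                     discard_per_replica = config$discard_ns)
  chains <- ens_list[[wt]]$topology$chains
  if (length(chains) < 2) stop("batch_interfaces needs >= 2 chains")
  pairs <- utils::combn(chains, 2)
  rows <- list()
  for (p in seq_len(ncol(pairs))) {
    ca <- pairs[1, p]; cb <- pairs[2, p]
    res <- lapply(ens_list, function(e) {
      interface_timeseries(e, region_chain(e$topology, ca),
                           region_chain(e$topology, cb),
                           cutoff = config$contact_cutoff,
                           probe_radius = config$probe_radius,
                           n_points = config$sasa_points,
                           area_stride = config$area_stride)
    })
    if (all(vapply(res, function(r) max(r$nc_series) == 0, TRUE))) {
      log_stage("[interfaces] pair %s/%s: no contacts in any frame; omitted",
                ca, cb)
      next
    }
    for (v in setdiff(sys_names, wt)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain_a = ca, chain_b = cb, variant = v,
        wt_nc_mean = res[[wt]]$nc_mean, nc_mean = res[[v]]$nc_mean,
        delta_nc_pct = if (res[[wt]]$nc_mean > 0)
          percent_change(res[[v]]$nc_mean, res[[wt]]$nc_mean) else NA_real_,
        wt_area_mean = res[[wt]]$area_mean, area_mean = res[[v]]$area_mean,
        delta_area_pct = if (res[[wt]]$area_mean != 0)
          percent_change(res[[v]]$area_mean, res[[wt]]$area_mean)
          else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
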