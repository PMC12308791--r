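#' @useDynLib trajcomp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a Calpha toy complex
#'
#' Lays each chain out as a non-overlapping 3D curve with exact 3.8 A
#' consecutive-Calpha spacing (random walk with a strong forward bias,
#' seeded, so geometry is deterministic). Chains are stacked along y at
#' `chain_spacing` so neighbouring chains form an interface. Optionally
#' each residue is decorated with backbone N/C/O and one sidechain
#' pseudo-atom (CB) for contact, surface-area and hydrogen-bond tests.
#'
#' @param chains list of `(chain_id, n_residues)` pairs, e.g.
#'   `list(c("A", 10), c("B", 10))`.
#' @param seed integer seed; same seed, same coordinates.
#' @param chain_spacing inter-chain offset in Angstrom (default 5.0, so
#'   adjacent chains touch at the 5 A heavy-atom contact cutoff).
#' @param decorate add backbone N/C/O + CB pseudo-atom per residue.
#' @return a [topology()] whose `$xyz` holds the mean structure.
#' @export
make_toy_complex <- function(chains, seed = 1L, chain_spacing = 5.0,
                             decorate = FALSE) {
  stopifnot(length(chains) >= 1)
  chains <- lapply(chains, function(ch) list(id = as.character(ch[[1]]),
                                             n = as.integer(ch[[2]])))
  if (any(vapply(chains, function(c) c$n, 1L) < 2)) {
    stop("each chain needs >= 2 residues")
  }
  local_seed(seed, {
    dmin <- 0
    nmax <- max(vapply(chains, function(c) c$n, 1L))
    for (attempt in 1:10) {
      # one shared backbone wiggle so chains run parallel (guaranteed
      # interfaces at chain_spacing), plus a small per-chain perturbation
      shared <- cbind(stats::rnorm(nmax - 1, 0, 0.10),
                      stats::rnorm(nmax - 1, 0, 0.10))
      coords <- list()
      for (k in seq_along(chains)) {
        n <- chains[[k]]$n
        # forward-biased unit steps scaled to exactly 3.8 A
        dirs <- cbind(1,
                      shared[seq_len(n - 1), 1] +
                        stats::rnorm(n - 1, 0, 0.03),
                      shared[seq_len(n - 1), 2] +
                        stats::rnorm(n - 1, 0, 0.03))
        dirs <- dirs / sqrt(rowSums(dirs^2)) * 3.8
        ca <- rbind(c(0, 0, 0), apply(dirs, 2, cumsum))
        ca[, 2] <- ca[, 2] + (k - 1) * chain_spacing +
          (attempt - 1) * 0.5 * (k - 1)
        coords[[k]] <- ca
      }
      # reject layouts where non-adjacent atoms collide
      all_ca <- do.call(rbind, coords)
      dmin <- min(stats::dist(all_ca))
      if (dmin > 2.5) break
    }
    if (dmin <= 2.5) {
      stop("toy-complex generation failed: chains overlap after 10 retries")
    }

    atom_rows <- list()
    xyz_rows <- list()
    for (k in seq_along(chains)) {
      id <- chains[[k]]$id
      n <- chains[[k]]$n
      ca <- coords[[k]]
      for (r in seq_len(n)) {
        if (decorate) {
          nm <- c("N", "CA", "C", "O", "CB")
          el <- c("N", "C", "C", "O", "C")
          off <- rbind(c(-1.2, 0.8, 0.3), c(0, 0, 0), c(1.2, 0.8, 0.3),
                       c(1.8, 1.9, 0.3), c(0, -1.3, 0.8))
        } else {
          nm <- "CA"; el <- "C"; off <- rbind(c(0, 0, 0))
        }
        atom_rows[[length(atom_rows) + 1L]] <- data.frame(
          atom_name = nm, element = el, residue_index = r,
          residue_name = "GLY", chain_id = id, stringsAsFactors = FALSE)
        xyz_rows[[length(xyz_rows) + 1L]] <- sweep(off, 2, ca[r, ], `+`)
      }
    }
    atoms <- do.call(rbind, atom_rows)
    atoms <- cbind(atom_id = 0:(nrow(atoms) - 1L), atoms)
    topology(atoms, xyz = do.call(rbind, xyz_rows))
  })
}

#' Recipe for a Gaussian trajectory ensemble
#'
#' Describes a synthetic ensemble with known statistical structure: a mean
#' structure, a per-residue base variance (A^2, per Cartesian axis), and
#' target correlation blocks between named residue regions. The implied
#' residue-residue covariance is checked for positive semi-definiteness;
#' if violated it is repaired by clipping negative eigenvalues at zero and
#' the recipe records a `repaired` flag.
#'
#' @param top a [topology()] with `$xyz` (e.g. from [make_toy_complex()]).
#' @param covariance_blocks list of `list(region_a, region_b, correlation)`
#'   with correlation in `[-1, 1]`; `region_a == region_b` programs
#'   block-internal correlation.
#' @param base_variance per-axis displacement variance in A^2 (default 0.5).
#' @param n_frames total frames (>= 2).
#' @param seed integer seed.
#' @param variance_overrides optional list of `list(region, variance)`
#'   raising (or lowering) per-axis variance inside named regions —
#'   emulates regions with elevated positional disorder.
#' @param n_replicas split frames into this many equal replicas (default 1).
#' @param dt frame spacing, ns (default 1).
#' @return object of class `ensemble_recipe`.
#' @export
ensemble_recipe <- function(top, covariance_blocks = list(),
                            base_variance = 0.5, n_frames = 1000L,
                            seed = 1L, variance_overrides = list(),
                            n_replicas = 1L, dt = 1) {
  stopifnot(inherits(top, "topology"), !is.null(top$xyz), n_frames >= 2)
  map <- residue_table(top)[, c("chain_id", "residue_index")]
  nres <- nrow(map)
  v <- rep(base_variance, nres)
  for (ov in variance_overrides) {
    v[map_region_rows(map, ov[[1]])] <- ov[[2]]
  }
  R <- diag(nres)
  for (bl in covariance_blocks) {
    ra <- which(map_region_rows(map, bl[[1]]))
    rb <- which(map_region_rows(map, bl[[2]]))
    rho <- bl[[3]]
    stopifnot(rho >= -1, rho <= 1)
    R[ra, rb] <- rho
    R[rb, ra] <- rho
  }
  diag(R) <- 1
  sigma <- sqrt(v) %o% sqrt(v) * R
  ev <- eigen(sigma, symmetric = TRUE)
  repaired <- FALSE
  if (min(ev$values) < -1e-8 * max(abs(ev$values))) {
    repaired <- TRUE
    warning("recipe covariance not positive semi-definite; ",
            "repaired by clipping eigenvalues at 0")
  }
  lam <- pmax(ev$values, 0)
  chol_like <- ev$vectors %*% diag(sqrt(lam), nres)
  structure(list(topology = top, residue_map = map, variance = v,
                 correlation = R, sigma = sigma, sqrt_sigma = chol_like,
                 repaired = repaired, n_frames = as.integer(n_frames),
                 seed = as.integer(seed), n_replicas = as.integer(n_replicas),
                 dt = dt),
            class = "ensemble_recipe")
}

# frame times / replica labels for a recipe
recipe_frame_meta <- function(recipe) {
  nf <- recipe$n_frames
  k <- recipe$n_replicas
  sizes <- rep(nf %/% k, k)
  if (nf %% k > 0) sizes[seq_len(nf %% k)] <- sizes[seq_len(nf %% k)] + 1L
  list(times = unlist(lapply(sizes, function(s) (seq_len(s) - 1) * recipe$dt)),
       labels = rep(paste0("R", seq_len(k)), sizes))
}

#' Sample a Gaussian trajectory ensemble from a recipe
#'
#' Per-frame Calpha displacements are drawn from a zero-mean multivariate
#' Gaussian realising the recipe covariance, independently per Cartesian
#' axis (isotropic), and added to the mean structure. All atoms of a
#' residue move rigidly with its Calpha, so local geometry (contacts,
#' hydrogen bonds) is preserved under the residue-level noise. Sampling is
#' deterministic in the recipe seed.
#'
#' @param recipe an [ensemble_recipe()].
#' @return a [trajectory_ensemble()].
#' @export
sample_gaussian_ensemble <- function(recipe) {
  stopifnot(inherits(recipe, "ensemble_recipe"))
  top <- recipe$topology
  nres <- nrow(recipe$residue_map)
  nf <- recipe$n_frames
  disp <- local_seed(recipe$seed, {
    lapply(1:3, function(ax) {
      matrix(stats::rnorm(nf * nres), nf, nres) %*% t(recipe$sqrt_sigma)
    })
  })
  # map residue displacements onto every atom of the residue
  akey <- paste(top$atoms$chain_id, top$atoms$residue_index)
  rkey <- paste(recipe$residue_map$chain_id, recipe$residue_map$residue_index)
  a2r <- match(akey, rkey)
  coords <- array(0, dim = c(nf, n_atoms(top), 3))
  for (ax in 1:3) {
    coords[, , ax] <- matrix(top$xyz[, ax], nf, n_atoms(top), byrow = TRUE) +
      disp[[ax]][, a2r, drop = FALSE]
  }
  meta <- recipe_frame_meta(recipe)
  trajectory_ensemble(top, coords, meta$times, meta$labels)
}

#' Recipe for a partially detached-interface ensemble
#'
#' Extends an [ensemble_recipe()] with a mobile region that, in a seeded
#' random fraction of frames, is rigidly displaced away from the rest of
#' the complex along the interface normal before the Gaussian noise is
#' applied — a controllable analogue of a weakened subunit interface whose
#' contacts are lost in the displaced frames.
#'
#' @param base an [ensemble_recipe()].
#' @param mobile_region a [region_spec()] inside the base topology.
#' @param separation_fraction fraction of frames displaced, in `[0, 1]`.
#' @param displacement displacement magnitude (Angstrom).
#' @return object of class `detachment_recipe`.
#' @export
detachment_recipe <- function(base, mobile_region, separation_fraction,
                              displacement) {
  stopifnot(inherits(base, "ensemble_recipe"),
            separation_fraction >= 0, separation_fraction <= 1,
            displacement >= 0)
  check_region(base$topology, mobile_region)
  structure(list(base = base, mobile_region = mobile_region,
                 separation_fraction = separation_fraction,
                 displacement = displacement),
            class = "detachment_recipe")
}

#' Sample a detachment ensemble
#'
#' Exactly `round(separation_fraction * n_frames)` frames (chosen by a
#' seeded draw without replacement) have the mobile region rigidly shifted
#' by `displacement` Angstrom along the unit vector from the complex
#' remainder's centroid to the mobile region's centroid. Ground-truth
#' per-frame labels are attached as `attr(ens, "detached")`.
#'
#' @param recipe a [detachment_recipe()].
#' @return a [trajectory_ensemble()] with a logical `"detached"` attribute.
#' @export
sample_detachment_ensemble <- function(recipe) {
  stopifnot(inherits(recipe, "detachment_recipe"))
  base <- recipe$base
  ens <- sample_gaussian_ensemble(base)
  nf <- n_frames(ens)
  n_det <- round(recipe$separation_fraction * nf)
  det_frames <- local_seed(base$seed + 104729L, sample.int(nf, n_det))
  detached <- logical(nf)
  detached[det_frames] <- TRUE

  mob_idx <- region_atoms(ens$topology, recipe$mobile_region, atoms = "all")
  rest_idx <- setdiff(seq_len(n_atoms(ens$topology)), mob_idx)
  if (length(rest_idx) == 0) stop("mobile region covers the whole topology")
  normal <- colMeans(ens$topology$xyz[mob_idx, , drop = FALSE]) -
    colMeans(ens$topology$xyz[rest_idx, , drop = FALSE])
  normal <- normal / sqrt(sum(normal^2))
  shift <- recipe$displacement * normal
  for (f in det_frames) {
    for (ax in 1:3) {
      ens$coords[f, mob_idx, ax] <- ens$coords[f, mob_idx, ax] + shift[ax]
    }
  }
  attr(ens, "detached") <- detached
  ens
}

#' Hydrogen-bond fixture series with programmed occupancy
#'
#' Builds a donor-hydrogen-acceptor triad (amide N-H donating to a
#' carbonyl O) whose geometry satisfies the hydrogen-bond criterion
#' (donor-acceptor 2.9 A, D-H...A angle 170 degrees) in a programmed
#' fraction of frames and violates the distance criterion (donor-acceptor
#' 6 A, same angle) in the rest. In `"deterministic"` mode exactly
#' `round(occupancy * n_frames)` frames are bound (seeded shuffle); in
#' `"bernoulli"` mode each frame is bound independently with probability
#' `occupancy`.
#'
#' @param occupancy target occupancy in `[0, 1]`.
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param mode `"deterministic"` (exact count) or `"bernoulli"`.
#' @return a [trajectory_ensemble()] with logical attribute `"bound"`.
#' @export
sample_hbond_series <- function(occupancy, n_frames, seed = 1L,
                                mode = c("deterministic", "bernoulli")) {
  mode <- match.arg(mode)
  stopifnot(occupancy >= 0, occupancy <= 1, n_frames >= 1)
  atoms <- data.frame(
    atom_id = 0:3,
    atom_name = c("N", "H", "O", "C"),
    element = c("N", "H", "O", "C"),
    residue_index = c(1L, 1L, 2L, 2L),
    residue_name = c("GLY", "GLY", "GLY", "GLY"),
    chain_id = c("A", "A", "B", "B"),
    stringsAsFactors = FALSE)

  # donor at origin, H along +x; acceptor on the ray making a 170 degree
  # D-H...A angle; h solves |D-A| = target for A = H + h * u.
  u <- c(cos(10 * pi / 180), sin(10 * pi / 180), 0)
  h_for <- function(da) {
    (-2 * u[1] + sqrt(4 * u[1]^2 - 4 * (1 - da^2))) / 2
  }
  place <- function(da) {
    acc <- c(1, 0, 0) + h_for(da) * u
    rbind(c(0, 0, 0), c(1, 0, 0), acc, acc + c(0.5, 1.2, 0))
  }
  bound_xyz <- place(2.9)
  unbound_xyz <- place(6.0)

  bound <- local_seed(seed, {
    if (mode == "deterministic") {
      b <- logical(n_frames)
      b[sample.int(n_frames, round(occupancy * n_frames))] <- TRUE
      b
    } else {
      stats::runif(n_frames) < occupancy
    }
  })
  coords <- array(0, dim = c(n_frames, 4, 3))
  for (f in seq_len(n_frames)) {
    coords[f, , ] <- if (bound[f]) bound_xyz else unbound_xyz
  }
  top <- topology(atoms, xyz = bound_xyz)
  ens <- trajectory_ensemble(top, coords)
  attr(ens, "bound") <- bound
  ens
}

#' Write a synthetic ensemble fixture with its ground-truth sidecar
#'
#' Writes the ensemble as a multi-model PDB plus a YAML sidecar recording
#' the generator parameters, any per-frame ground-truth labels (detached /
#' bound) and the realised per-residue Calpha displacement variance.
#'
#' @param ens a [trajectory_ensemble()] from one of the samplers.
#' @param dir output directory (created if needed).
#' @param name fixture base name.
#' @param recipe optional recipe used to generate `ens`, summarised in the
#'   sidecar.
#' @return paths of the files written (invisibly).
#' @export
write_fixture <- function(ens, dir, name, recipe = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb_path <- file.path(dir, paste0(name, ".pdb"))
  yml_path <- file.path(dir, paste0(name, ".truth.yaml"))
  write_pdb_trajectory(ens, pdb_path)
  ca <- region_atoms(ens$topology, atoms = "ca")
  if (length(ca) == 0) ca <- seq_len(n_atoms(ens$topology))
  realised_var <- colMeans(sapply(1:3, function(ax) {
    apply(ens$coords[, ca, ax, drop = FALSE], 2, stats::var)
  }))
  side <- list(n_frames = n_frames(ens), n_atoms = n_atoms(ens$topology),
               replica_labels = as.list(unique(ens$replica_labels)),
               realized_ca_variance = as.list(round(realised_var, 6)))
  if (!is.null(attr(ens, "detached"))) {
    side$detached_frames <- which(attr(ens, "detached"))
  }
  if (!is.null(attr(ens, "bound"))) {
    side$bound_frames <- which(attr(ens, "bound"))
  }
  if (!is.null(recipe)) {
    if (inherits(recipe, "detachment_recipe")) {
      side$recipe <- list(kind = "detachment",
                          separation_fraction = recipe$separation_fraction,
                          displacement = recipe$displacement,
                          mobile_region = recipe$mobile_region$name,
                          seed = recipe$base$seed,
                          n_frames = recipe$base$n_frames)
    } else if (inherits(recipe, "ensemble_recipe")) {
      side$recipe <- list(kind = "gaussian", seed = recipe$seed,
                          n_frames = recipe$n_frames,
                          repaired = recipe$repaired)
    }
  }
  yaml::write_yaml(side, yml_path)
  invisible(c(pdb_path, yml_path))
}
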