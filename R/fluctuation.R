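#' Distance-fluctuation matrix
#'
#' For each residue pair `(i, j)` (one selected atom per residue, default
#' the alpha carbon) the variance of their inter-atomic distance over the
#' pooled frames: `DF_ij = <d_ij^2> - <d_ij>^2` (A^2). Rigid-body motion
#' leaves all pairwise distances — hence the whole matrix — unchanged, so
#' no superposition is required.
#'
#' @param ens a [trajectory_ensemble()] with >= 2 frames.
#' @param region optional [region_spec()] restricting the residues.
#' @param atom_name representative atom per residue (default `"CA"`; a
#'   residue without one falls back to its first heavy atom).
#' @return object of class `df_matrix`: `values` (N x N, symmetric, zero
#'   diagonal), `mean_distances`, `residue_index_map`.
#' @export
distance_fluctuation_matrix <- function(ens, region = NULL,
                                        atom_name = "CA") {
  if (n_frames(ens) < 2) {
    stop("distance fluctuations undefined for a single frame")
  }
  rep_sel <- residue_representatives(ens$topology, region, atom_name)
  if (length(rep_sel$idx) < 2) stop("need >= 2 residues")
  X <- ens$coords[, rep_sel$idx, 1, drop = FALSE]; dim(X) <- dim(X)[1:2]
  Y <- ens$coords[, rep_sel$idx, 2, drop = FALSE]; dim(Y) <- dim(Y)[1:2]
  Z <- ens$coords[, rep_sel$idx, 3, drop = FALSE]; dim(Z) <- dim(Z)[1:2]
  acc <- cpp_distance_fluctuation(X, Y, Z)
  structure(list(values = acc$var, mean_distances = acc$mean,
                 residue_index_map = rep_sel$map),
            class = "df_matrix")
}

#' Normalized distance fluctuation (NDF) profile
#'
#' Per-residue score summarising how much a residue's distances to the
#' rest of the protein fluctuate relative to the global average:
#' `NDF_i = mean_{j != i}(DF_ij) / mean_{i < j}(DF_ij)`. Dimensionless;
#' the mean over residues is exactly 1, so values above 1 mark residues
#' whose motion is decoupled from (fluctuates against) the rest of the
#' structure. An alternative normalisation by the median off-diagonal
#' fluctuation is available.
#'
#' @param df a `df_matrix` from [distance_fluctuation_matrix()].
#' @param normalization `"mean"` (default; row mean over global mean) or
#'   `"median"` (row mean over global median).
#' @return object of class `ndf_profile` with `scores` and
#'   `residue_index_map`.
#' @export
ndf_profile <- function(df, normalization = c("mean", "median")) {
  normalization <- match.arg(normalization)
  v <- df$values
  n <- nrow(v)
  stopifnot(n >= 2)
  off <- v[upper.tri(v)]
  if (all(off == 0)) {
    stop("degenerate ensemble: all distance fluctuations are zero")
  }
  row_means <- (rowSums(v)) / (n - 1)  # diagonal is 0
  denom <- if (normalization == "mean") mean(off) else stats::median(off)
  if (denom == 0) stop("normalization denominator is zero")
  structure(list(scores = row_means / denom,
                 residue_index_map = df$residue_index_map,
                 normalization = normalization),
            class = "ndf_profile")
}

#' Variant-minus-wild-type NDF difference profile
#'
#' Elementwise `variant - wt` NDF scores with a three-way classification:
#' residues with a difference above `threshold` have increased disorder,
#' below `-threshold` are stiffened, otherwise unchanged. The default
#' threshold 0.1 separates small differences from meaningful ones.
#' Profiles must share the same residue map; each is normalised within its
#' own system.
#'
#' @param variant,wt [ndf_profile()]s on identical residue maps.
#' @param threshold classification threshold (default 0.1).
#' @return object of class `delta_ndf_profile` with `deltas`,
#'   `classification` (factor) and `residue_index_map`.
#' @export
delta_ndf <- function(variant, wt, threshold = 0.1) {
  mv <- variant$residue_index_map
  mw <- wt$residue_index_map
  if (nrow(mv) != nrow(mw) ||
      !all(mv$chain_id == mw$chain_id & mv$residue_index == mw$residue_index)) {
    bad <- if (nrow(mv) != nrow(mw)) 1L else {
      which(mv$chain_id != mw$chain_id |
              mv$residue_index != mw$residue_index)[1]
    }
    stop("residue maps differ (first discrepancy at position ", bad, ")")
  }
  deltas <- variant$scores - wt$scores
  cls <- rep("unchanged", length(deltas))
  cls[deltas > threshold] <- "increased_disorder"
  cls[deltas < -threshold] <- "stiffened"
  structure(list(deltas = deltas,
                 classification = factor(cls, levels = c(
                   "increased_disorder", "stiffened", "unchanged")),
                 threshold = threshold, residue_index_map = mv),
            class = "delta_ndf_profile")
}

#' Per-region summary of an NDF difference profile
#'
#' Mean, min and max of the per-residue differences within each named
#' region (e.g. individual helices of a detachable domain). Regions with
#' no residues in the profile are excluded with a warning.
#'
#' @param profile a [delta_ndf()] result.
#' @param regions list of [region_spec()]s.
#' @return data.frame with one row per region: `region`, `n_residues`,
#'   `mean`, `min`, `max`.
#' @export
region_summary <- function(profile, regions) {
  rows <- lapply(regions, function(rg) {
    inr <- map_region_rows(profile$residue_index_map, rg)
    if (!any(inr)) {
      warning("region '", rg$name, "' has no residues in the profile; excluded")
      return(NULL)
    }
    d <- profile$deltas[inr]
    data.frame(region = rg$name, n_residues = sum(inr), mean = mean(d),
               min = min(d), max = max(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Export a distance-fluctuation matrix or profile as CSV
#'
#' `df_matrix` objects are written as a dense labelled matrix;
#' `ndf_profile` and `delta_ndf_profile` objects as per-residue tables.
#'
#' @param x a `df_matrix`, `ndf_profile` or `delta_ndf_profile`.
#' @param path output CSV path.
#' @export
write_fluctuation_csv <- function(x, path) {
  labels <- paste0(x$residue_index_map$chain_id, ":",
                   x$residue_index_map$residue_index)
  if (inherits(x, "df_matrix")) {
    m <- as.data.frame(x$values)
    names(m) <- labels
    utils::write.csv(cbind(residue = labels, m), path, row.names = FALSE)
  } else if (inherits(x, "ndf_profile")) {
    utils::write.csv(data.frame(residue = labels, ndf = x$scores),
                     path, row.names = FALSE)
  } else if (inherits(x, "delta_ndf_profile")) {
    utils::write.csv(data.frame(residue = labels, delta_ndf = x$deltas,
                                class = as.character(x$classification)),
                     path, row.names = FALSE)
  } else {
    stop("unsupported object for write_fluctuation_csv")
  }
  invisible(path)
}

#' Classification intervals of an NDF difference profile
#'
#' Collapses consecutive residues with the same classification into
#' 1-based inclusive intervals (BED-like rows: chain, first, last, class),
#' for downstream visualisation.
#'
#' @param profile a [delta_ndf()] result.
#' @return data.frame with `chain_id`, `first`, `last`, `class`.
#' @export
classification_intervals <- function(profile) {
  m <- profile$residue_index_map
  cls <- as.character(profile$classification)
  out <- list()
  i <- 1L
  n <- nrow(m)
  while (i <= n) {
    j <- i
    while (j < n && m$chain_id[j + 1] == m$chain_id[i] &&
           cls[j + 1] == cls[i] &&
           m$residue_index[j + 1] == m$residue_index[j] + 1L) {
      j <- j + 1L
    }
    out[[length(out) + 1L]] <- data.frame(
      chain_id = m$chain_id[i], first = m$residue_index[i],
      last = m$residue_index[j], class = cls[i], stringsAsFactors = FALSE)
    i <- j + 1L
  }
  do.call(rbind, out)
}
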