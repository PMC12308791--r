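#' Dynamic cross-correlation matrix (DCCM)
#'
#' Normalised dot-product correlation of residue displacement vectors
#' about their ensemble means:
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`,
#' one selected atom per residue (default alpha carbon). The ensemble must
#' be superposed first ([superpose()]); otherwise global tumbling
#' masquerades as correlation. A zero-variance residue gets zeros
#' off-diagonal (1 on the diagonal) with a warning.
#'
#' @param ens a superposed [trajectory_ensemble()] with >= 2 frames.
#' @param region optional [region_spec()] restricting the residues.
#' @param atom_name representative atom per residue (default `"CA"`).
#' @return object of class `correlation_matrix`: `values` (N x N in
#'   `[-1, 1]`, unit diagonal), `residue_index_map`.
#' @export
dccm <- function(ens, region = NULL, atom_name = "CA") {
  if (n_frames(ens) < 2) stop("DCCM undefined for a single frame")
  rep_sel <- residue_representatives(ens$topology, region, atom_name)
  n <- length(rep_sel$idx)
  F <- n_frames(ens)
  dots <- matrix(0, n, n)
  for (ax in 1:3) {
    M <- ens$coords[, rep_sel$idx, ax, drop = FALSE]
    dim(M) <- dim(M)[1:2]
    M <- sweep(M, 2, colMeans(M))
    dots <- dots + crossprod(M) / F
  }
  amp <- diag(dots)
  zero <- amp <= 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance residue(s); rows/columns zeroed")
    amp[zero] <- 1
  }
  vals <- dots / sqrt(amp %o% amp)
  vals[zero, ] <- 0
  vals[, zero] <- 0
  vals <- pmin(pmax(vals, -1), 1)
  diag(vals) <- 1
  structure(list(values = vals, residue_index_map = rep_sel$map),
            class = "correlation_matrix")
}

check_same_map <- function(a, b) {
  ma <- a$residue_index_map
  mb <- b$residue_index_map
  if (nrow(ma) != nrow(mb) ||
      !all(ma$chain_id == mb$chain_id &
             ma$residue_index == mb$residue_index)) {
    stop("residue maps differ between the two matrices")
  }
  invisible(TRUE)
}

#' Variant-minus-wild-type DCCM difference matrix
#'
#' Elementwise `variant - wt` correlations; symmetric with zero diagonal,
#' entries in `[-2, 2]`.
#'
#' @param variant,wt [dccm()] results on identical residue maps.
#' @return object of class `difference_matrix`.
#' @export
dccm_difference <- function(variant, wt) {
  check_same_map(variant, wt)
  structure(list(values = variant$values - wt$values,
                 residue_index_map = variant$residue_index_map),
            class = "difference_matrix")
}

#' Cosine and Spearman similarity of two difference matrices
#'
#' Both scores are computed over the strict upper triangle flattened in
#' row-major order (the diagonal is identically zero and the lower
#' triangle duplicates the upper): cosine is the normalised dot product,
#' Spearman the rank correlation with average ranks on ties.
#'
#' @param diff_a,diff_b [dccm_difference()] results on identical maps.
#' @return named numeric vector `c(cosine = ..., spearman = ...)`.
#' @export
matrix_similarity <- function(diff_a, diff_b) {
  check_same_map(diff_a, diff_b)
  ut <- upper.tri(diff_a$values)
  # row-major flattening of the upper triangle = column-major of the lower;
  # either ordering pairs identical (i, j) entries, so scores are unchanged.
  va <- t(diff_a$values)[t(ut)]
  vb <- t(diff_b$values)[t(ut)]
  if (all(va == 0) || all(vb == 0)) {
    stop("similarity undefined for an all-zero difference matrix")
  }
  cosine <- sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
  spearman <- stats::cor(va, vb, method = "spearman")
  c(cosine = cosine, spearman = spearman)
}

#' Essential-dynamics PCA of an ensemble
#'
#' Eigendecomposition of the 3N x 3N covariance matrix of the selected
#' atoms' coordinates (one atom per residue, default alpha carbon;
#' coordinates ordered x1, y1, z1, x2, ...). Eigenvalues are returned in
#' descending order with variance fractions relative to the trace ("total
#' motion"); eigenvector signs are fixed so each vector's
#' largest-magnitude component is positive, making results reproducible
#' across platforms. The ensemble must be superposed first.
#'
#' @param ens a superposed [trajectory_ensemble()].
#' @param region optional [region_spec()].
#' @param atom_name representative atom per residue (default `"CA"`).
#' @return object of class `pca_result`: `eigenvalues` (A^2),
#'   `eigenvectors` (3N x 3N, columns orthonormal), `variance_fractions`,
#'   `mean_structure` (3N), `residue_index_map`.
#' @export
pca_motions <- function(ens, region = NULL, atom_name = "CA") {
  rep_sel <- residue_representatives(ens$topology, region, atom_name)
  n <- length(rep_sel$idx)
  F <- n_frames(ens)
  if (F < 2) stop("PCA undefined for a single frame")
  if (F <= 3 * n) {
    warning("fewer frames (", F, ") than coordinate dimensions (", 3 * n,
            "); covariance is rank-deficient")
  }
  X <- matrix(0, F, 3 * n)
  for (ax in 1:3) {
    M <- ens$coords[, rep_sel$idx, ax, drop = FALSE]
    dim(M) <- dim(M)[1:2]
    X[, seq(ax, 3 * n, by = 3)] <- M
  }
  if (any(!is.finite(X))) stop("non-finite coordinates in ensemble")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  covm <- crossprod(Xc) / (F - 1)
  ev <- eigen(covm, symmetric = TRUE)
  lam <- pmax(ev$values, 0)  # clip numerically negative zero modes
  vec <- ev$vectors
  for (m in seq_len(ncol(vec))) {
    peak <- which.max(abs(vec[, m]))
    if (vec[peak, m] < 0) vec[, m] <- -vec[, m]
  }
  structure(list(eigenvalues = lam, eigenvectors = vec,
                 variance_fractions = lam / sum(lam),
                 mean_structure = mu, residue_index_map = rep_sel$map),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(3, length(x$eigenvalues))
  cat(sprintf("essential-dynamics PCA: %d modes; top-%d variance fraction %.3f\n",
              length(x$eigenvalues), k, sum(x$variance_fractions[1:k])))
  invisible(x)
}

#' Region involvement in the leading principal components
#'
#' Fraction of the top-`k` essential-dynamics motion attributable to a
#' residue region. By default eigenvalue-weighted:
#' `sum_m lambda_m * s_m(region) / sum_m lambda_m` over modes `m = 1..k`,
#' where `s_m(region)` is the squared-component mass of eigenvector `m` on
#' the region's residues (all three Cartesian components). The unweighted
#' alternative averages `s_m(region)` over the k modes. Involvements of a
#' partition of the residues sum to 1 for any k.
#'
#' @param pca a [pca_motions()] result.
#' @param region a [region_spec()].
#' @param k number of leading components (default 3).
#' @param weighted eigenvalue-weighted (default) or plain mode average.
#' @return object of class `involvement_report`: `region`, `k`,
#'   `fraction`, `per_mode` (s_m values).
#' @export
region_involvement <- function(pca, region, k = 3L, weighted = TRUE) {
  stopifnot(k >= 1, k <= length(pca$eigenvalues))
  inr <- map_region_rows(pca$residue_index_map, region)
  comp <- rep(inr, each = 3)
  s <- vapply(seq_len(k), function(m) {
    sum(pca$eigenvectors[comp, m]^2) / sum(pca$eigenvectors[, m]^2)
  }, 0.0)
  lam <- pca$eigenvalues[seq_len(k)]
  fraction <- if (weighted) {
    if (sum(lam) == 0) 0 else sum(lam * s) / sum(lam)
  } else {
    mean(s)
  }
  structure(list(region = region$name, k = as.integer(k),
                 fraction = fraction, per_mode = s, weighted = weighted),
            class = "involvement_report")
}

#' @export
print.involvement_report <- function(x, ...) {
  cat(sprintf("region '%s' involvement in top-%d PCs: %.1f%%%s\n",
              x$region, x$k, 100 * x$fraction,
              if (x$weighted) " (eigenvalue-weighted)" else ""))
  invisible(x)
}

#' Export a correlation or difference matrix as CSV
#'
#' @param x a `correlation_matrix` or `difference_matrix`.
#' @param path output path.
#' @param long write long-form `(i, j, value)` rows instead of a dense
#'   matrix.
#' @export
write_matrix_csv <- function(x, path, long = FALSE) {
  labels <- paste0(x$residue_index_map$chain_id, ":",
                   x$residue_index_map$residue_index)
  if (long) {
    idx <- which(upper.tri(x$values, diag = TRUE), arr.ind = TRUE)
    utils::write.csv(data.frame(i = labels[idx[, 1]], j = labels[idx[, 2]],
                                value = x$values[idx]),
                     path, row.names = FALSE)
  } else {
    m <- as.data.frame(x$values)
    names(m) <- labels
    utils::write.csv(cbind(residue = labels, m), path, row.names = FALSE)
  }
  invisible(path)
}
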