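#' Trajectory ensemble
#'
#' A `trajectory_ensemble` holds pooled coordinates for one simulated
#' system: a `frames x atoms x 3` array in Angstrom, one time stamp (ns)
#' per frame, and one replica label per frame so frames can be traced back
#' to the independent simulation they came from.
#'
#' @param top a [topology()].
#' @param coords frames x atoms x 3 numeric array (Angstrom).
#' @param frame_times numeric vector, ns, one per frame; non-decreasing
#'   within each replica.
#' @param replica_labels character vector, one per frame.
#' @return object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(top, coords, frame_times = NULL,
                                replica_labels = NULL) {
  stopifnot(inherits(top, "topology"))
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    stop("coords must be a frames x atoms x 3 array")
  }
  if (dim(coords)[2] != n_atoms(top)) {
    stop(sprintf("coordinate array has %d atoms but topology has %d",
                 dim(coords)[2], n_atoms(top)))
  }
  nf <- dim(coords)[1]
  if (is.null(frame_times)) frame_times <- as.numeric(seq_len(nf) - 1)
  if (is.null(replica_labels)) replica_labels <- rep("R1", nf)
  stopifnot(length(frame_times) == nf, length(replica_labels) == nf)
  for (rep_lab in unique(replica_labels)) {
    tt <- frame_times[replica_labels == rep_lab]
    if (is.unsorted(tt)) {
      stop("frame times not non-decreasing within replica '", rep_lab, "'")
    }
  }
  structure(list(topology = top, coords = coords,
                 frame_times = as.numeric(frame_times),
                 replica_labels = as.character(replica_labels)),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf(
    "trajectory ensemble: %d frames, %d atoms, %d replica(s), t = [%g, %g] ns\n",
    n_frames(x), n_atoms(x$topology), length(unique(x$replica_labels)),
    min(x$frame_times), max(x$frame_times)))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens a [trajectory_ensemble()].
#' @export
n_frames <- function(ens) dim(ens$coords)[1]

# One frame as an atoms x 3 matrix.
frame_xyz <- function(ens, f) {
  matrix(ens$coords[f, , ], ncol = 3)
}

# Subset frames, keeping metadata aligned.
subset_frames <- function(ens, keep) {
  trajectory_ensemble(ens$topology,
                      ens$coords[keep, , , drop = FALSE],
                      ens$frame_times[keep],
                      ens$replica_labels[keep])
}

#' Load trajectory files into an ensemble
#'
#' Reads one file per replica and concatenates frames in path order.
#' Supported formats: multi-model PDB, DCD (via \pkg{bio3d}) and
#' multi-frame GRO (nm, converted to Angstrom). Frame times restart at 0
#' for each file with spacing `dt`; every `stride`-th frame is kept (times
#' keep their pre-stride values, so striding subsamples rather than
#' relabels the time axis).
#'
#' @param top a [topology()] the files must match in atom count.
#' @param paths character vector of trajectory file paths, one per replica.
#' @param stride keep every `stride`-th frame (default 1 = all).
#' @param dt frame spacing in ns (default 1).
#' @param replica_labels labels, one per path; defaults to `R1`, `R2`, ...
#' @return a [trajectory_ensemble()].
#' @export
load_trajectory <- function(top, paths, stride = 1L, dt = 1,
                            replica_labels = NULL) {
  stopifnot(length(paths) >= 1, stride >= 1)
  if (is.null(replica_labels)) replica_labels <- paste0("R", seq_along(paths))
  stopifnot(length(replica_labels) == length(paths))
  nat <- n_atoms(top)
  blocks <- vector("list", length(paths))
  times <- labs <- vector("list", length(paths))
  for (k in seq_along(paths)) {
    xyz <- read_trajectory_frames(paths[k])  # frames x 3N, Angstrom
    if (ncol(xyz) != 3L * nat) {
      stop(sprintf("trajectory '%s' has %d atoms but topology has %d",
                   paths[k], ncol(xyz) %/% 3L, nat))
    }
    tt <- (seq_len(nrow(xyz)) - 1) * dt
    keep <- seq(1L, nrow(xyz), by = stride)
    blocks[[k]] <- xyz[keep, , drop = FALSE]
    times[[k]] <- tt[keep]
    labs[[k]] <- rep(replica_labels[k], length(keep))
  }
  flat <- do.call(rbind, blocks)
  nf <- nrow(flat)
  coords <- array(0, dim = c(nf, nat, 3))
  coords[, , 1] <- flat[, seq(1, 3 * nat, by = 3), drop = FALSE]
  coords[, , 2] <- flat[, seq(2, 3 * nat, by = 3), drop = FALSE]
  coords[, , 3] <- flat[, seq(3, 3 * nat, by = 3), drop = FALSE]
  trajectory_ensemble(top, coords, unlist(times), unlist(labs))
}

# Read any supported trajectory file as a frames x 3N matrix in Angstrom.
read_trajectory_frames <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    return(unclass(xyz))
  }
  if (ext == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    return(unclass(xyz))
  }
  if (ext == "gro") return(read_gro_frames(path))
  if (ext %in% c("xtc", "trr")) {
    stop("format '.", ext, "' is not supported; supply DCD, multi-model ",
         "PDB or multi-frame GRO")
  }
  stop("unrecognised trajectory format: ", path)
}

# Multi-frame GRO -> frames x 3N matrix (Angstrom).
read_gro_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  pos <- 1L
  while (pos + 1L <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(nat)) stop("failed to parse GRO '", path,
                         "': bad atom count at line ", pos + 1L)
    if (pos + 1L + nat > length(lines)) {
      stop("failed to parse GRO '", path, "': truncated frame at line ", pos)
    }
    al <- lines[(pos + 2L):(pos + 1L + nat)]
    x <- as.numeric(substr(al, 21, 28))
    y <- as.numeric(substr(al, 29, 36))
    z <- as.numeric(substr(al, 37, 44))
    flat <- numeric(3L * nat)
    flat[seq(1, 3 * nat, 3)] <- x * 10
    flat[seq(2, 3 * nat, 3)] <- y * 10
    flat[seq(3, 3 * nat, 3)] <- z * 10
    frames[[length(frames) + 1L]] <- flat
    pos <- pos + nat + 3L  # title + count + atoms + box
  }
  if (length(frames) == 0) stop("no frames in GRO '", path, "'")
  do.call(rbind, frames)
}

#' Write an ensemble (or single frame) as a multi-model PDB
#'
#' The package's plain-text trajectory dialect for fixtures and debugging.
#'
#' @param ens a [trajectory_ensemble()], or a [topology()] with `$xyz`.
#' @param path output path.
#' @export
write_pdb_trajectory <- function(ens, path) {
  if (inherits(ens, "topology")) {
    stopifnot(!is.null(ens$xyz))
    ens <- trajectory_ensemble(ens, array(ens$xyz,
                                          dim = c(1, n_atoms(ens), 3)))
  }
  a <- ens$topology$atoms
  flat <- matrix(0, n_frames(ens), 3 * nrow(a))
  flat[, seq(1, ncol(flat), 3)] <- ens$coords[, , 1]
  flat[, seq(2, ncol(flat), 3)] <- ens$coords[, , 2]
  flat[, seq(3, ncol(flat), 3)] <- ens$coords[, , 3]
  bio3d::write.pdb(file = path, xyz = flat,
                   type = rep("ATOM", nrow(a)),
                   resno = a$residue_index, resid = a$residue_name,
                   eleno = a$atom_id + 1L, elety = a$atom_name,
                   chain = a$chain_id, elesy = a$element)
  invisible(path)
}

#' Discard per-replica equilibration and pool the remainder
#'
#' For each replica, frames earlier than `replica start + discard` ns are
#' dropped; the surviving frames of all replicas are concatenated in their
#' original order. This realises the common design of pooling the
#' equilibrated tails of several independent replicas into one analysis
#' ensemble (e.g. three 2000 ns replicas minus 500 ns each pool to 4500 ns).
#'
#' @param ens a [trajectory_ensemble()].
#' @param discard_per_replica ns to drop at the start of each replica
#'   (>= 0).
#' @return the pooled [trajectory_ensemble()].
#' @export
pool_equilibrated <- function(ens, discard_per_replica) {
  stopifnot(discard_per_replica >= 0)
  keep <- logical(n_frames(ens))
  for (rep_lab in unique(ens$replica_labels)) {
    in_rep <- ens$replica_labels == rep_lab
    start <- min(ens$frame_times[in_rep])
    ok <- in_rep & ens$frame_times >= start + discard_per_replica
    if (!any(ok)) {
      stop("replica '", rep_lab, "' fully discarded (discard ",
           discard_per_replica, " ns >= its duration)")
    }
    keep <- keep | ok
  }
  subset_frames(ens, which(keep))
}

# Optimal rotation (Kabsch, SVD with determinant correction) mapping
# moving (n x 3, centred) onto ref (n x 3, centred). Returns 3x3 R such
# that moving %*% t(R) ~ ref.
kabsch_rotation <- function(moving, ref) {
  h <- crossprod(moving, ref)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

#' Superpose all frames onto a common reference
#'
#' Rigid-body least-squares fit (Kabsch) of every frame onto an iteratively
#' refined mean structure (2 passes), fitting on the alpha carbons of
#' `fit_selection` (all residues by default; for topologies without CA
#' atoms, all heavy atoms of the selection are used). Rotations and
#' translations are applied to all atoms, so internal geometry is
#' untouched. Removing global rotation/translation is a prerequisite for
#' displacement-based analyses (cross-correlation matrices, essential
#' dynamics).
#'
#' @param ens a [trajectory_ensemble()].
#' @param fit_selection optional [region_spec()] restricting the fit atoms.
#' @param n_iter mean-structure refinement passes (default 2).
#' @return the superposed [trajectory_ensemble()].
#' @export
superpose <- function(ens, fit_selection = NULL, n_iter = 2L) {
  fit_idx <- region_atoms(ens$topology, fit_selection, atoms = "ca")
  if (length(fit_idx) < 3) {
    fit_idx <- region_atoms(ens$topology, fit_selection, atoms = "heavy")
  }
  if (length(fit_idx) < 3) {
    stop("superposition needs at least 3 fit atoms; got ", length(fit_idx))
  }
  ref <- frame_xyz(ens, 1)[fit_idx, , drop = FALSE]
  sv <- svd(scale(ref, scale = FALSE))$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) {
    stop("superposition reference atoms are collinear")
  }
  coords <- ens$coords
  nf <- dim(coords)[1]
  for (pass in seq_len(n_iter)) {
    ref_c <- colMeans(ref)
    ref0 <- sweep(ref, 2, ref_c)
    for (f in seq_len(nf)) {
      xyz <- matrix(coords[f, , ], ncol = 3)
      mov <- xyz[fit_idx, , drop = FALSE]
      mc <- colMeans(mov)
      rot <- kabsch_rotation(sweep(mov, 2, mc), ref0)
      fitted <- sweep(xyz, 2, mc) %*% t(rot)
      coords[f, , ] <- sweep(fitted, 2, ref_c, `+`)
    }
    # refined reference: mean structure over fitted frames
    ref <- apply(coords[, fit_idx, , drop = FALSE], c(2, 3), mean)
  }
  trajectory_ensemble(ens$topology, coords, ens$frame_times,
                      ens$replica_labels)
}
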