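# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately naive (loops, closed forms) and shares no
# code with the package internals it checks.

# all-pairs contact count
brute_contacts <- function(xyz, set_a, set_b, cutoff) {
  n <- 0L
  for (i in set_a) for (j in set_b) {
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff) n <- n + 1L
  }
  n
}

# element-by-element distance-fluctuation matrix
brute_df <- function(coords, idx) {
  nf <- dim(coords)[1]
  n <- length(idx)
  out <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    d <- vapply(seq_len(nf), function(f) {
      sqrt(sum((coords[f, idx[a], ] - coords[f, idx[b], ])^2))
    }, 0.0)
    out[a, b] <- mean(d^2) - mean(d)^2
  }
  out
}

# direct-formula cosine + spearman over the strict upper triangle
brute_similarity <- function(ma, mb) {
  va <- ma[upper.tri(ma)]
  vb <- mb[upper.tri(mb)]
  ra <- rank(va); rb <- rank(vb)
  c(cosine = sum(va * vb) / sqrt(sum(va^2) * sum(vb^2)),
    spearman = sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2)))
}

# a uniformly random rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a random rigid transform to every frame of an ensemble
rigidly_scramble <- function(ens) {
  for (f in seq_len(n_frames(ens))) {
    rot <- random_rotation()
    tr <- rnorm(3, sd = 20)
    xyz <- matrix(ens$coords[f, , ], ncol = 3) %*% t(rot)
    ens$coords[f, , ] <- sweep(xyz, 2, tr, `+`)
  }
  ens
}

# all-frames pairwise distance matrix of one frame
frame_distmat <- function(ens, f) {
  as.matrix(dist(matrix(ens$coords[f, , ], ncol = 3)))
}

# minimal CHARMM-format DCD writer (binary fixture built at test time)
write_dcd_fixture <- function(xyz, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- nrow(xyz)
  nat <- ncol(xyz) %/% 3L
  rec <- function(writer, size) {
    writeBin(as.integer(size), con, size = 4)
    writer()
    writeBin(as.integer(size), con, size = 4)
  }
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L
  rec(function() {
    writeChar("CORD", con, 4, eos = NULL)
    writeBin(icntrl, con, size = 4)
  }, 84)
  rec(function() {
    writeBin(1L, con, size = 4)
    writeChar(sprintf("%-80s", "fixture"), con, 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(nat), con, size = 4), 4)
  for (f in seq_len(nf)) for (ax in 1:3) {
    v <- xyz[f, seq(ax, 3 * nat, by = 3)]
    rec(function() writeBin(as.numeric(v), con, size = 4), 4 * nat)
  }
  invisible(path)
}

# small decorated two-chain complex reused in several files
toy2 <- function(seed = 1, n = 10, decorate = TRUE, spacing = 5.0) {
  make_toy_complex(list(c("A", n), c("B", n)), seed = seed,
                   chain_spacing = spacing, decorate = decorate)
}

# ensemble as frames x 3N flat matrix (x1 y1 z1 x2 ...)
flatten_frames <- function(ens) {
  nat <- dim(ens$coords)[2]
  flat <- matrix(0, n_frames(ens), 3 * nat)
  for (ax in 1:3) flat[, seq(ax, 3 * nat, by = 3)] <- ens$coords[, , ax]
  flat
}
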