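# topology / trajectory reading, pooling, superposition

test_that("PDB round trip preserves topology and coordinates", {
  top <- toy2(seed = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_trajectory(top, path)
  got <- load_topology(path)
  expect_equal(length(got$chains), 2)
  expect_equal(got$chains, c("A", "B"))
  expect_equal(nrow(residue_table(got)), 20)
  expect_equal(got$atoms$atom_name, top$atoms$atom_name)
  expect_equal(got$atoms$residue_index, top$atoms$residue_index)
  expect_equal(got$xyz, top$xyz, tolerance = 1e-2)
})

test_that("PDB without chain identifiers falls back to one default chain", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY     1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY     2       3.800   0.000   0.000  1.00  0.00           C",
    "END"), path)
  top <- load_topology(path)
  expect_equal(top$chains, "A")
  expect_equal(unique(top$atoms$chain_id), "A")
})

test_that("GRO and PDB readers agree on the same structure", {
  top <- toy2(seed = 5)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  gro <- withr::local_tempfile(fileext = ".gro")
  write_pdb_trajectory(top, pdb)
  trajcomp:::write_gro(top, top$xyz, gro)
  t_pdb <- load_topology(pdb)
  t_gro <- load_topology(gro)
  expect_equal(t_gro$atoms$atom_name, t_pdb$atoms$atom_name)
  expect_equal(t_gro$atoms$residue_index, t_pdb$atoms$residue_index)
  # GRO has no chains: single default chain, same atom count
  expect_equal(n_atoms(t_gro), n_atoms(t_pdb))
  expect_equal(t_gro$xyz, t_pdb$xyz, tolerance = 2e-2)
})

test_that("GRO coordinates written in nm come back as Angstrom (x10)", {
  top <- toy2(seed = 1, n = 3, decorate = FALSE)
  xyz_ang <- matrix(c(1.23, 4.56, -7.89,
                      10.1, -0.2, 0.3,
                      -5, 6, 7, 1, 2, 3, 4, 5, 6, 9, 8, 7),
                    ncol = 3, byrow = TRUE)
  path <- withr::local_tempfile(fileext = ".gro")
  trajcomp:::write_gro(top, xyz_ang, path)
  # independent check of the file contents: stored values are nm
  raw <- readLines(path)[3]
  expect_equal(as.numeric(substr(raw, 21, 28)), 1.23 / 10)
  ens <- load_trajectory(top, path)
  expect_equal(matrix(ens$coords[1, , ], ncol = 3), xyz_ang,
               tolerance = 6e-3)
})

test_that("multi-model PDB loading honours stride and assigns times", {
  top <- toy2(seed = 2, n = 5, decorate = FALSE)
  rec <- ensemble_recipe(top, n_frames = 10, seed = 4, base_variance = 0.2)
  ens <- sample_gaussian_ensemble(rec)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_trajectory(ens, path)
  full <- load_trajectory(top, path, stride = 1)
  expect_equal(n_frames(full), 10)
  half <- load_trajectory(top, path, stride = 2)
  expect_equal(n_frames(half), 5)
  expect_equal(half$frame_times, c(0, 2, 4, 6, 8))
  expect_equal(half$coords[2, , ], ens$coords[3, , ], tolerance = 1e-2)
})

test_that("DCD frames round-trip through the bio3d reader path", {
  top <- toy2(seed = 2, n = 4, decorate = FALSE)
  rec <- ensemble_recipe(top, n_frames = 6, seed = 9, base_variance = 0.3)
  ens <- sample_gaussian_ensemble(rec)
  path <- withr::local_tempfile(fileext = ".dcd")
  write_dcd_fixture(flatten_frames(ens), path)
  got <- load_trajectory(top, path)
  expect_equal(n_frames(got), 6)
  expect_equal(got$coords, ens$coords, tolerance = 1e-5)
})

test_that("atom-count mismatches and unsupported formats are rejected", {
  top <- toy2(seed = 2, n = 5, decorate = FALSE)
  ens <- sample_gaussian_ensemble(ensemble_recipe(top, n_frames = 3,
                                                  seed = 1))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_trajectory(ens, path)
  wrong <- toy2(seed = 2, n = 6, decorate = FALSE)
  expect_error(load_trajectory(wrong, path), "atoms")
  expect_error(load_trajectory(top, sub("pdb$", "xtc", path)),
               "not supported")
})

test_that("pooling drops the stated equilibration span per replica", {
  top <- toy2(seed = 1, n = 4, decorate = FALSE)
  nf <- 60L
  coords <- array(rnorm(nf * n_atoms(top) * 3), c(nf, n_atoms(top), 3))
  # three replicas of 2000 ns each (20 frames at 100 ns spacing)
  times <- rep(seq(0, 1900, by = 100), 3)
  labs <- rep(c("R1", "R2", "R3"), each = 20)
  ens <- trajectory_ensemble(top, coords, times, labs)
  pooled <- pool_equilibrated(ens, 500)
  # 3 x (2000 - 500) ns of retained sampling = 4500 ns
  retained <- vapply(unique(pooled$replica_labels), function(l) {
    tt <- pooled$frame_times[pooled$replica_labels == l]
    max(tt) - min(tt) + 100
  }, 0.0)
  expect_equal(sum(retained), 4500)
  expect_equal(n_frames(pooled), 45)
  # frame conservation per replica
  for (l in c("R1", "R2", "R3")) {
    kept <- sum(pooled$replica_labels == l)
    dropped <- sum(ens$replica_labels == l) - kept
    expect_equal(kept + dropped, 20)
    expect_equal(dropped, 5)
  }
  # discard 0 is the identity
  expect_equal(pool_equilibrated(ens, 0), ens)
  # one replica of 100 frames at 1 ns spacing, discard 10 -> 90 frames
  e1 <- trajectory_ensemble(top, coords[1:60, , , drop = FALSE],
                            0:59, rep("R1", 60))
  e1b <- trajectory_ensemble(
    top, array(rnorm(100 * n_atoms(top) * 3), c(100, n_atoms(top), 3)),
    0:99, rep("R1", 100))
  expect_equal(n_frames(pool_equilibrated(e1b, 10)), 90)
  # fully discarded replica is an error naming the replica
  expect_error(pool_equilibrated(e1, 1000), "R1")
})

test_that("superposition removes rigid motion and is idempotent", {
  top <- toy2(seed = 7, n = 8, decorate = FALSE)
  ref <- top$xyz
  nf <- 12L
  coords <- array(0, c(nf, nrow(ref), 3))
  set.seed(42)
  for (f in seq_len(nf)) {
    rot <- random_rotation()
    coords[f, , ] <- sweep(ref %*% t(rot), 2, rnorm(3, sd = 15), `+`)
  }
  ens <- trajectory_ensemble(top, coords)
  fit <- superpose(ens)
  for (f in seq_len(nf)) {
    rmsd <- sqrt(mean(rowSums((matrix(fit$coords[f, , ], ncol = 3) -
                                 matrix(fit$coords[1, , ], ncol = 3))^2)))
    expect_lt(rmsd, 1e-6)
  }
  again <- superpose(fit)
  expect_equal(again$coords, fit$coords, tolerance = 1e-8)
})

test_that("superposition preserves intra-frame geometry", {
  top <- toy2(seed = 7, n = 6, decorate = FALSE)
  ens <- sample_gaussian_ensemble(ensemble_recipe(top, n_frames = 8,
                                                  seed = 3,
                                                  base_variance = 0.5))
  scr <- rigidly_scramble(ens)
  fit <- superpose(scr)
  for (f in c(1, 4, 8)) {
    expect_equal(frame_distmat(fit, f), frame_distmat(scr, f),
                 tolerance = 1e-6)
  }
})

test_that("fitted RMSD matches the independent Kabsch oracle", {
  # 4-atom two-frame toy with a non-trivial optimal rotation
  top <- topology(data.frame(atom_id = 0:3, atom_name = "CA",
                             element = "C", residue_index = 1:4,
                             residue_name = "GLY", chain_id = "A"))
  f1 <- matrix(c(0, 0, 0, 3.8, 0, 0, 3.8, 3.8, 0, 0, 3.8, 1), 4, 3,
               byrow = TRUE)
  set.seed(11)
  f2 <- (f1 + matrix(rnorm(12, sd = 0.4), 4, 3)) %*% t(random_rotation())
  coords <- array(0, c(2, 4, 3))
  coords[1, , ] <- f1
  coords[2, , ] <- f2
  ens <- trajectory_ensemble(top, coords)
  fit <- superpose(ens, n_iter = 1)  # single pass: reference = frame 1
  ours <- sqrt(mean(rowSums((matrix(fit$coords[2, , ], ncol = 3) -
                               f1)^2)))
  fitted <- suppressWarnings(
    bio3d::fit.xyz(as.vector(t(f1)), as.vector(t(f2))))
  oracle <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) -
                                 f1)^2)))
  expect_equal(ours, oracle, tolerance = 1e-6)
})

test_that("degenerate superposition inputs are rejected", {
  top <- topology(data.frame(atom_id = 0:2, atom_name = "CA",
                             element = "C", residue_index = 1:3,
                             residue_name = "GLY", chain_id = "A"))
  line <- cbind(c(0, 3.8, 7.6), 0, 0)  # collinear
  coords <- array(rep(line, each = 2), c(2, 3, 3))
  ens <- trajectory_ensemble(top, coords)
  expect_error(superpose(ens), "collinear")
})
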