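# contact counts, buried areas, occupancies, vdW contact lists

test_that("contact counting matches simple geometric cases", {
  xyz <- rbind(c(0, 0, 0), c(4.9, 0, 0))
  expect_equal(count_contacts(xyz, 1, 2), 1L)
  xyz2 <- rbind(c(0, 0, 0), c(50, 0, 0))
  expect_equal(count_contacts(xyz2, 1, 2), 0L)
  expect_warning(n <- count_contacts(xyz, integer(0), 2), "empty")
  expect_equal(n, 0L)
  expect_error(count_contacts(xyz, 1:2, 2), "disjoint")
})

test_that("grid contact counts equal the all-pairs oracle", {
  set.seed(10)
  for (trial in 1:50) {
    n <- 200
    xyz <- matrix(runif(n * 3, 0, 30), n, 3)
    a <- sample(n, 100)
    b <- setdiff(seq_len(n), a)
    cutoff <- runif(1, 2, 8)
    expect_equal(count_contacts(xyz, a, b, cutoff),
                 brute_contacts(xyz, a, b, cutoff))
    # symmetry
    expect_equal(count_contacts(xyz, b, a, cutoff),
                 count_contacts(xyz, a, b, cutoff))
  }
})

test_that("contact counts are monotone in the cutoff", {
  set.seed(4)
  xyz <- matrix(runif(120, 0, 15), 40, 3)
  a <- 1:20; b <- 21:40
  counts <- vapply(c(2, 3.5, 5, 6.5), function(cc) {
    count_contacts(xyz, a, b, cc)
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("single-sphere SASA matches the closed form within 0.5%", {
  for (el in c("C", "N", "O", "S")) {
    r <- element_radii(el)
    got <- sasa(matrix(0, 1, 3), el, n_points = 960)
    expect_equal(got, 4 * pi * (r + 1.4)^2, tolerance = 5e-3)
  }
})

test_that("interface area is zero for separated groups and symmetric", {
  top <- toy2(seed = 1, n = 6)
  xyz <- top$xyz
  ia <- region_atoms(top, region_chain(top, "A"), "heavy")
  ib <- region_atoms(top, region_chain(top, "B"), "heavy")
  el <- top$atoms$element
  far <- xyz
  far[ib, 1] <- far[ib, 1] + 500
  expect_equal(interface_area(far, ia, ib, el), 0, tolerance = 0.5)
  a1 <- interface_area(xyz, ia, ib, el)
  a2 <- interface_area(xyz, ib, ia, el)
  expect_equal(a1, a2, tolerance = 1e-9)
  expect_gt(a1, 0)
})

test_that("two-group buried area matches the analytic sphere-cap value", {
  # groups {a1, a2} and {b1, b2}; only a2-b1 overlap, within-group atoms
  # far apart, so burial is exactly the two spherical caps
  d <- 4.0
  xyz <- rbind(c(-30, 0, 0), c(0, 0, 0), c(d, 0, 0), c(d + 30, 0, 0))
  el <- c("C", "C", "O", "C")
  r <- element_radii(el) + 1.4
  cap <- function(r1, r2, d) 2 * pi * r1 * (r1 - (d^2 + r1^2 - r2^2) / (2 * d))
  expected <- (cap(r[2], r[3], d) + cap(r[3], r[2], d)) / 2
  got <- interface_area(xyz, c(1, 2), c(3, 4), el, n_points = 4000)
  expect_equal(got, expected, tolerance = 0.01 * expected)
})

test_that("interface area shrinks monotonically as groups separate", {
  top <- toy2(seed = 3, n = 5)
  ia <- region_atoms(top, region_chain(top, "A"), "heavy")
  ib <- region_atoms(top, region_chain(top, "B"), "heavy")
  el <- top$atoms$element
  centre_line <- colMeans(top$xyz[ib, ]) - colMeans(top$xyz[ia, ])
  centre_line <- centre_line / sqrt(sum(centre_line^2))
  areas <- vapply(seq(0, 9), function(step) {
    xyz <- top$xyz
    xyz[ib, ] <- sweep(xyz[ib, ], 2, step * 1.0 * centre_line, `+`)
    interface_area(xyz, ia, ib, el, n_points = 960)
  }, 0.0)
  expect_true(all(diff(areas) <= 0.5))  # sampling noise allowance
  expect_lt(areas[10], areas[1])
})

test_that("interface time series pools per-frame values faithfully", {
  top <- toy2(seed = 2, n = 6)
  rA <- region_chain(top, "A")
  rB <- region_chain(top, "B")
  # static ensemble: zero spread
  coords <- array(rep(top$xyz, each = 5), c(5, n_atoms(top), 3))
  static <- trajectory_ensemble(top, coords)
  it <- interface_timeseries(static, rA, rB, n_points = 480)
  expect_equal(it$nc_sd, 0)
  expect_equal(it$area_sd, 0, tolerance = 1e-9)
  # 10-frame ensemble: means equal hand-pooled per-frame oracles
  ens <- sample_gaussian_ensemble(ensemble_recipe(top, n_frames = 10,
                                                  seed = 5,
                                                  base_variance = 0.3))
  it2 <- interface_timeseries(ens, rA, rB, n_points = 480)
  ia <- region_atoms(top, rA, "heavy")
  ib <- region_atoms(top, rB, "heavy")
  oracle_nc <- vapply(1:10, function(f) {
    brute_contacts(matrix(ens$coords[f, , ], ncol = 3), ia, ib, 5)
  }, 0L)
  expect_equal(it2$nc_series, oracle_nc)
  expect_equal(it2$nc_mean, mean(oracle_nc))
  expect_equal(it2$area_mean, mean(it2$area_series))
  expect_error(interface_timeseries(ens, rA, rA), "disjoint")
})

test_that("detachment halves mean contacts when half the frames detach", {
  top <- toy2(seed = 4, n = 8)
  rA <- region_chain(top, "A")
  rB <- region_chain(top, "B")
  base <- ensemble_recipe(top, n_frames = 200, seed = 2,
                          base_variance = 0.2)
  ens <- sample_detachment_ensemble(detachment_recipe(base, rA, 0.5, 50))
  it <- interface_timeseries(ens, rA, rB, area_stride = 200,
                             n_points = 60)
  attached <- !attr(ens, "detached")
  expect_equal(sum(attached), 100)
  expect_equal(it$nc_mean, 0.5 * mean(it$nc_series[attached]))
  expect_true(all(it$nc_series[!attached] == 0))
})

test_that("percent change follows the variant-minus-wild-type convention", {
  expect_equal(percent_change(830, 1000), -17)
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(104, 100), 4)
  expect_error(percent_change(5, 0), "0")
})

test_that("hydrogen-bond occupancy recovers programmed fixtures", {
  ens <- sample_hbond_series(0.84, 100, seed = 7)
  res <- hbond_occupancy(ens, donors = 1, acceptors = 3)
  expect_length(res, 1)
  expect_equal(res[[1]]$occupancy, 0.84)
  expect_identical(res[[1]]$per_frame, attr(ens, "bound"))

  res46 <- hbond_occupancy(sample_hbond_series(0.46, 200, seed = 2),
                           donors = 1, acceptors = 3)
  expect_equal(res46[[1]]$occupancy, 0.46)

  # never-bound pair is absent from the results
  res0 <- hbond_occupancy(sample_hbond_series(0, 50, seed = 1),
                          donors = 1, acceptors = 3)
  expect_length(res0, 0)

  # heavy mode works without hydrogens; strict mode refuses
  ens2 <- sample_hbond_series(0.3, 100, seed = 5)
  ens2$topology$atoms$element[2] <- "C"  # disguise the hydrogen
  expect_error(hbond_occupancy(ens2, donors = 1, acceptors = 3),
               "hydrogen")
  resh <- hbond_occupancy(ens2, donors = 1, acceptors = 3, mode = "heavy")
  expect_equal(resh[[1]]$occupancy, 0.3)
})

test_that("bernoulli occupancy lands within three binomial errors", {
  p <- 0.46
  n <- 1000
  ens <- sample_hbond_series(p, n, seed = 11, mode = "bernoulli")
  res <- hbond_occupancy(ens, donors = 1, acceptors = 3)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(res[[1]]$occupancy - p), 3 * se)
  expect_gte(res[[1]]$occupancy, 0)
  expect_lte(res[[1]]$occupancy, 1)
})

test_that("vdW contact lists match brute-force enumeration", {
  top <- toy2(seed = 5, n = 4)
  # residues 50 A apart: empty list
  far <- top
  bidx <- region_atoms(top, region_chain(top, "B"), "all")
  far$xyz[bidx, 1] <- far$xyz[bidx, 1] + 50
  ens_far <- trajectory_ensemble(far, array(far$xyz, c(1, n_atoms(far), 3)))
  expect_equal(nrow(vdw_contacts(ens_far, c("A", 1), c("B", 1))), 0)

  # constant single pair at 3.9 A
  top1 <- topology(data.frame(atom_id = 0:1, atom_name = c("CB", "CB"),
                              element = "C", residue_index = c(1L, 1L),
                              residue_name = "ALA",
                              chain_id = c("A", "B")))
  coords <- array(0, c(3, 2, 3))
  coords[, 2, 1] <- 3.9
  ens1 <- trajectory_ensemble(top1, coords)
  cp <- vdw_contacts(ens1, c("A", 1), c("B", 1))
  expect_equal(nrow(cp), 1)
  expect_equal(cp$min_distance, 3.9)
  expect_equal(cp$mean_distance, 3.9)

  # random 5-atom residues against the oracle, sort order stable
  set.seed(21)
  top5 <- topology(data.frame(
    atom_id = 0:9, atom_name = paste0("X", 1:10), element = "C",
    residue_index = rep(c(1L, 2L), each = 5), residue_name = "UNK",
    chain_id = rep(c("A", "B"), each = 5)))
  coords <- array(rnorm(5 * 10 * 3, sd = 3), c(5, 10, 3))
  ens5 <- trajectory_ensemble(top5, coords)
  got <- vdw_contacts(ens5, c("A", 1), c("B", 2), cutoff = 6)
  mins <- matrix(Inf, 5, 5)
  means <- matrix(NA_real_, 5, 5)
  for (i in 1:5) for (j in 6:10) {
    d <- vapply(1:5, function(f) {
      sqrt(sum((coords[f, i, ] - coords[f, j, ])^2))
    }, 0.0)
    mins[i, j - 5] <- min(d)
    if (any(d <= 6)) means[i, j - 5] <- mean(d[d <= 6])
  }
  keep <- which(mins <= 6, arr.ind = TRUE)
  keep <- keep[order(mins[keep]), , drop = FALSE]
  expect_equal(got$min_distance, mins[keep])
  expect_equal(got$mean_distance, means[keep])
  expect_false(is.unsorted(got$min_distance))
})
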