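# Stopping power, CSDA ranges, and the Monte Carlo deposition kernel.

water <- load_stopping_water()
at211 <- nuclide_at211()

test_that("CSDA ranges of the chain alphas match published water ranges", {
  expect_equal(csda_range(5.87, water), 48, tolerance = 0.5 / 48)
  expect_equal(csda_range(7.45, water), 70, tolerance = 0.5 / 70)
  expect_equal(csda_range(0.01, water), 0)
})

test_that("csda_range is strictly increasing and continuous in E0", {
  E <- seq(0.02, 9.5, length.out = 200)
  r <- csda_range(E, water)
  expect_true(all(diff(r) > 0))
  # continuity: small energy perturbations move the range proportionally
  eps <- 1e-6
  expect_lt(abs(csda_range(5 + eps, water) - csda_range(5, water)),
            eps / stopping_at(water, 5) * 1.01)
  expect_error(csda_range(20, water), "outside")
})

test_that("stopping model validates its invariants", {
  expect_error(stopping_power_model(c(1, 1), c(2, 2)), "ascending")
  expect_error(stopping_power_model(c(1, 2), c(-1, 2)), "positive")
  expect_error(nuclide_at211(branch_fractions = c(0.5, 0.4)), "sum to 1")
})

test_that("single-branch kernels conserve the initial energy exactly", {
  one <- nuclide_at211(branch_fractions = c(1, 0))
  k <- generate_kernel(one, water, n_events = 500, voxel_um = 2,
                       half_extent_um = 72, seed = 11)
  expect_equal(k$total_MeV, 5.87, tolerance = 1e-12)
  k2 <- generate_kernel(at211, water, n_events = 2000, voxel_um = 2,
                        half_extent_um = 72, seed = 3)
  expect_equal(k2$total_MeV, mean_alpha_energy(at211), tolerance = 1e-12)
})

test_that("a single event deposits along a single ray", {
  k <- generate_kernel(at211, water, n_events = 1, voxel_um = 1,
                       half_extent_um = 75, seed = 5)
  expect_equal(k$total_MeV, 7.45, tolerance = 1e-12)  # allocation gives Po branch
  nz <- which(k$values > 0, arr.ind = TRUE)
  ctr <- (dim(k$values) + 1) / 2
  off <- sweep(nz, 2, ctr)
  far <- off[which.max(rowSums(off^2)), ]
  u <- far / sqrt(sum(far^2))
  perp <- sqrt(pmax(0, rowSums(off^2) - (off %*% u)^2))
  expect_lt(max(perp), sqrt(3))  # every deposit within one voxel of the ray
})

test_that("compiled transport agrees per-voxel with the naive R step loop", {
  k <- generate_kernel(at211, water, n_events = 120, voxel_um = 2,
                       half_extent_um = 72, seed = 42)
  ref <- oracle_transport_kernel(at211, water, n_events = 120, voxel_um = 2,
                                 half_extent_um = 72, seed = 42)
  expect_lt(max(abs(k$values - ref)), 1e-10 * max(ref))
})

test_that("no deposition beyond the CSDA support bound", {
  k <- generate_kernel(at211, water, n_events = 3000, voxel_um = 2,
                       half_extent_um = 80, seed = 9)
  d <- dim(k$values); half <- (d - 1) / 2
  v <- k$voxel_xyz_um[1]
  r <- sqrt(outer(outer((((seq_len(d[1]) - 1) - half[1]) * v)^2,
                        (((seq_len(d[2]) - 1) - half[2]) * v)^2, "+"),
                  (((seq_len(d[3]) - 1) - half[3]) * v)^2, "+"))
  bound <- csda_range(max(at211$alpha_energies_MeV), water) + sqrt(3) * v
  expect_equal(sum(k$values[r > bound]), 0)
  # grid smaller than the range is refused unless truncation is explicit
  expect_error(generate_kernel(at211, water, 10, voxel_um = 2,
                               half_extent_um = 40), "truncate")
  expect_silent(generate_kernel(at211, water, 10, voxel_um = 2,
                                half_extent_um = 40, truncate = TRUE))
})

test_that("same seed reproduces the kernel bitwise", {
  a <- generate_kernel(at211, water, 400, voxel_um = 2, half_extent_um = 72,
                       seed = 77)
  b <- generate_kernel(at211, water, 400, voxel_um = 2, half_extent_um = 72,
                       seed = 77)
  expect_identical(a$values, b$values)
  expect_identical(a$rel_uncertainty, b$rel_uncertainty)
})

test_that("radial averaging matches the exhaustive group-by-distance oracle", {
  set.seed(1)
  vals <- array(runif(125), c(5, 5, 5))
  k <- alphadose:::new_dose_kernel(vals, c(1, 1, 1), 10, array(0.1, c(5, 5, 5)))
  ka <- radial_average(k)
  expect_equal(ka$values, oracle_radial_average(vals), tolerance = 1e-12)
  expect_equal(ka$total_MeV, k$total_MeV, tolerance = 1e-12)
  # a spherically symmetric kernel is a fixed point
  expect_equal(radial_average(ka)$values, ka$values, tolerance = 1e-12)
})

test_that("radially averaged kernels carry the octahedral grid symmetries", {
  k <- generate_kernel(at211, water, 2000, voxel_um = 2, half_extent_um = 72,
                       seed = 1)
  ka <- radial_average(k)
  v <- ka$values
  expect_equal(v, aperm(v, c(2, 1, 3)), tolerance = 1e-12)
  expect_equal(v, aperm(v, c(3, 2, 1)), tolerance = 1e-12)
  expect_equal(v, v[rev(seq_len(dim(v)[1])), , ], tolerance = 1e-12)
})

test_that("radial profile falls off and shows the two Bragg cutoffs", {
  k <- radial_average(generate_kernel(at211, water, 5e4, voxel_um = 1,
                                      half_extent_um = 75, seed = 2))
  prof <- kernel_radial_profile(k)
  p <- function(r) prof$mean_MeV[prof$r_um == r + 0.5]
  expect_gt(p(5), p(20))          # ~1/r^2 fall-off at small r
  expect_gt(p(20), p(45))
  expect_gt(p(60), p(69))         # beyond first cutoff, falling toward second
  expect_equal(p(71), 0)          # nothing beyond the 70-um range
})

test_that("rebinning sums energy, preserves totals, and keeps odd dims", {
  k <- radial_average(generate_kernel(at211, water, 5000, voxel_um = 2,
                                      half_extent_um = 72, seed = 4))
  same <- rebin_kernel(k, 2, 2)
  expect_equal(same$values, k$values, tolerance = 1e-12)
  ones <- alphadose:::new_dose_kernel(array(1, c(9, 9, 9)), c(1, 1, 1), 1,
                                      array(0, c(9, 9, 9)))
  r3 <- rebin_kernel(ones, 3, 3)
  expect_true(all(r3$values == 27))
  kr <- rebin_kernel(k, 26, 12)
  expect_equal(kr$total_MeV, k$total_MeV, tolerance = 1e-9)
  expect_true(all(dim(kr$values) %% 2 == 1))
  expect_error(rebin_kernel(k, 5, 5), "integer multiples")
})

test_that("12-um rebin confines energy to the six-slice neighbourhood", {
  k <- radial_average(generate_kernel(at211, water, 2e4, voxel_um = 1,
                                      half_extent_um = 75, seed = 6))
  kr <- rebin_kernel(k, 26, 12)
  nz <- dim(kr$values)[3]
  expect_equal(nz, 13)  # +/- 6 slices of 12 um around the source slice
  zsum <- apply(kr$values, 3, sum)
  expect_gt(zsum[7], max(zsum[c(1, 13)]) * 50)  # rapid fall-off off-centre
})

test_that("uncertainty summary averages relative errors of nonzero voxels", {
  vals <- array(0, c(3, 3, 3)); vals[2, 2, 2] <- 1; vals[1, 2, 2] <- 2
  rel <- array(0, c(3, 3, 3)); rel[2, 2, 2] <- 0.05; rel[1, 2, 2] <- 0.05
  k <- alphadose:::new_dose_kernel(vals, c(1, 1, 1), 10, rel)
  expect_equal(kernel_uncertainty_summary(k), 5)
  k0 <- alphadose:::new_dose_kernel(array(0, c(3, 3, 3)), c(1, 1, 1), 10,
                                    array(0, c(3, 3, 3)))
  expect_error(kernel_uncertainty_summary(k0), "undefined")
})

test_that("doubling the event count shrinks uncertainty like 1/sqrt(2)", {
  u1 <- kernel_uncertainty_summary(radial_average(
    generate_kernel(at211, water, 4000, voxel_um = 2, half_extent_um = 72,
                    seed = 10)))
  u2 <- kernel_uncertainty_summary(radial_average(
    generate_kernel(at211, water, 8000, voxel_um = 2, half_extent_um = 72,
                    seed = 20)))
  expect_equal(u1 / u2, sqrt(2), tolerance = 0.1)
})
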