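# DPK convolution, central slice, and limited-slice methods.

mk_kernel <- function(vals, vox = c(26, 26, 12))
  alphadose:::new_dose_kernel(vals, vox, 1, array(0, dim(vals)))

mk_stack <- function(vals, vox = c(26, 26, 12))
  activity_stack(vals, vox)

test_that("a delta kernel reproduces the closed-form voxel dose rate", {
  A <- array(0, c(7, 7, 5)); A[4, 4, 3] <- 1     # 1 Bq
  K <- array(0, c(3, 3, 3)); K[2, 2, 2] <- 6.79  # MeV per emission
  m <- convolve_dose_rate(mk_stack(A), mk_kernel(K))
  mass <- 1 * (26 * 26 * 12 * 1e-12) * 1e-3      # kg of a water voxel
  expected <- 6.79 * 1.602176634e-13 / mass * 3.6e6
  expect_equal(m$values[4, 4, 3], expected, tolerance = 1e-9)
  expect_equal(sum(m$values > 1e-12 * expected), 1)
})

test_that("FFT convolution matches the direct triple-loop sum", {
  set.seed(31)
  A <- array(runif(16 * 16 * 5), c(16, 16, 5))
  K <- array(runif(125), c(5, 5, 5))
  m <- convolve_dose_rate(mk_stack(A), mk_kernel(K))
  ref <- oracle_convolve(A, K)
  mass <- (26 * 26 * 12 * 1e-12) * 1e-3
  ref <- ref * 1.602176634e-13 / mass * 3.6e6
  expect_equal(m$values, ref, tolerance = 1e-9)
  # a second, asymmetric case
  A2 <- array(rpois(11 * 9 * 7, 2), c(11, 9, 7))
  K2 <- array(runif(27), c(3, 3, 3))
  m2 <- convolve_dose_rate(mk_stack(A2), mk_kernel(K2))
  ref2 <- oracle_convolve(A2, K2) * 1.602176634e-13 / mass * 3.6e6
  expect_equal(m2$values, ref2, tolerance = 1e-9)
})

test_that("convolution is linear in the activity", {
  set.seed(32)
  A1 <- array(runif(8 * 8 * 3), c(8, 8, 3))
  A2 <- array(runif(8 * 8 * 3), c(8, 8, 3))
  K <- array(runif(27), c(3, 3, 3))
  m1 <- convolve_dose_rate(mk_stack(A1), mk_kernel(K))$values
  m2 <- convolve_dose_rate(mk_stack(A2), mk_kernel(K))$values
  m12 <- convolve_dose_rate(mk_stack(2 * A1 + 3 * A2), mk_kernel(K))$values
  expect_equal(m12, 2 * m1 + 3 * m2, tolerance = 1e-9)
})

test_that("geometry mismatches and even kernels are refused", {
  A <- array(1, c(4, 4, 3)); K <- array(1, c(3, 3, 3))
  expect_error(convolve_dose_rate(mk_stack(A), mk_kernel(K, c(10, 10, 10))),
               "rebin")
  expect_error(convolve_dose_rate(mk_stack(A),
                                  mk_kernel(array(1, c(2, 3, 3)))),
               "odd")
})

test_that("uniform activity reaches the charged-particle-equilibrium limit", {
  water <- load_stopping_water()
  k <- radial_average(generate_kernel(nuclide_at211(), water, 2e4,
                                      voxel_um = 2, half_extent_um = 72,
                                      seed = 44))
  kr <- rebin_kernel(k, 26, 12)      # 7x7x13 at 26/12 um
  a <- 1e-4
  A <- array(a, c(21, 21, 17))
  m <- convolve_dose_rate(mk_stack(A), kr)
  mass <- (26 * 26 * 12 * 1e-12) * 1e-3
  expected <- a * kr$total_MeV * 1.602176634e-13 / mass * 3.6e6
  mid <- m$values[11, 11, 9]
  expect_equal(mid, expected, tolerance = 0.005)
})

test_that("central_slice picks the middle and rejects even depths", {
  A <- array(seq_len(4 * 4 * 21), c(4, 4, 21))
  m <- dose_rate_map(A, c(26, 26, 12))
  expect_equal(central_slice(m)$values, A[, , 11])
  expect_equal(central_slice(dose_rate_map(A[, , 1, drop = FALSE],
                                           c(26, 26, 12)))$values,
               A[, , 1])
  expect_error(central_slice(dose_rate_map(A[, , 1:2], c(26, 26, 12))),
               "even")
  # z-mirroring leaves the central slice of a symmetric computation alone
  set.seed(5)
  As <- array(runif(6 * 6 * 5), c(6, 6, 5))
  K <- array(runif(27), c(3, 3, 3)); K <- (K + K[, , 3:1]) / 2
  d1 <- central_slice(convolve_dose_rate(mk_stack(As), mk_kernel(K)))
  d2 <- central_slice(convolve_dose_rate(mk_stack(As[, , 5:1]),
                                         mk_kernel(K)))
  expect_equal(d1$values, d2$values, tolerance = 1e-9)
})

test_that("slice-contribution ratios are monotone and reach 1 at N_max", {
  set.seed(33)
  A <- array(runif(10 * 10 * 9), c(10, 10, 9))
  K <- array(runif(3 * 3 * 7), c(3, 3, 7))
  res <- slice_contribution_curve(mk_stack(A), mk_kernel(K))
  expect_equal(res$curve$N, c(1, 3, 5, 7, 9))
  expect_true(all(diff(res$curve$dose_rate_N) >= -1e-12))
  expect_equal(res$curve$ratio[5], 1)
  # a kernel with no z extent makes every slice self-sufficient
  Kflat <- array(runif(9), c(3, 3, 1))
  resf <- slice_contribution_curve(mk_stack(A), mk_kernel(Kflat))
  expect_equal(resf$curve$ratio, rep(1, 5), tolerance = 1e-12)
})

test_that("contribution ratios match manually zeroed direct convolutions", {
  set.seed(34)
  A <- array(runif(8 * 8 * 7), c(8, 8, 7))
  K <- array(runif(3 * 3 * 5), c(3, 3, 5))
  res <- slice_contribution_curve(mk_stack(A), mk_kernel(K))
  mass <- (26 * 26 * 12 * 1e-12) * 1e-3
  for (i in seq_along(res$curve$N)) {
    N <- res$curve$N[i]
    Az <- A * 0
    keep <- seq(4 - (N - 1) / 2, 4 + (N - 1) / 2)
    Az[, , keep] <- A[, , keep]
    ref <- oracle_convolve(Az, K)[, , 4] * 1.602176634e-13 / mass * 3.6e6
    expect_equal(res$curve$dose_rate_N[i], sum(ref), tolerance = 1e-9)
  }
})

test_that("correction-factor fit recovers exact exponential ratios", {
  N <- seq(1, 15, by = 2)
  alpha <- 0.35; beta <- 0.4
  curve <- tibble::tibble(N = N, ratio = 1 - alpha * exp(-beta * (N - 1)))
  fit <- fit_contribution_correction(curve)
  expect_equal(fit$alpha, alpha, tolerance = 1e-6)
  expect_equal(fit$beta, beta, tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-12)
  expect_equal(fit$C_N(1), 1 / (1 - alpha), tolerance = 1e-6)
  # flat ratios give a unit correction
  flat <- fit_contribution_correction(tibble::tibble(N = N, ratio = 1))
  expect_equal(flat$C_N(c(1, 5, 9)), rep(1, 3), tolerance = 1e-8)
  expect_error(fit_contribution_correction(curve[1:2, ]), "3")
  # chi-squared is reported when errors are given
  noisy <- curve; noisy$ratio <- noisy$ratio + c(0.01, -0.01)
  f2 <- fit_contribution_correction(noisy, errors = rep(0.01, nrow(noisy)))
  expect_true(is.finite(f2$chi2_nu))
})

test_that("corrected single-slice estimates land near the full answer", {
  tr <- build_truth_stack(phantom_spec(seed = 8))
  st <- tr$stack
  water <- load_stopping_water()
  kr <- rebin_kernel(radial_average(generate_kernel(
    nuclide_at211(), water, 2e4, voxel_um = 2, half_extent_um = 72,
    seed = 45)), 26, 12)
  res <- slice_contribution_curve(st, kr)
  fit <- fit_contribution_correction(res)
  D1 <- res$curve$dose_rate_N[1]
  De <- fit$C_N(1) * D1
  expect_lt(abs(De / res$dose_rate_full - 1), 0.1)
})

test_that("cloning is exact for depth-uniform stacks and at N = depth", {
  set.seed(36)
  sl <- matrix(runif(64), 8, 8)
  A <- array(rep(sl, 7), c(8, 8, 7))
  K <- array(runif(3 * 3 * 5), c(3, 3, 5))
  full <- central_slice(convolve_dose_rate(mk_stack(A), mk_kernel(K)))
  for (N in c(1, 3, 7)) {
    cl <- cloning_dose_rate(mk_stack(A), N, mk_kernel(K))
    expect_equal(cl$values, full$values, tolerance = 1e-9)
  }
  A2 <- array(runif(8 * 8 * 7), c(8, 8, 7))
  # N = depth clones only beyond the measured range: equality holds where
  # the kernel support stays inside the measured stack
  cl7 <- cloning_dose_rate(mk_stack(A2), 7, mk_kernel(K))
  full2 <- central_slice(convolve_dose_rate(mk_stack(A2), mk_kernel(K)))
  expect_equal(cl7$values, full2$values, tolerance = 1e-9)
})

test_that("single-slice cloning overemphasises central-slice features", {
  # hot blob only in the central slice: cloning copies it through depth
  A <- array(0, c(12, 12, 9))
  A[, , ] <- 0.01
  A[5:8, 5:8, 5] <- 1
  K <- array(runif(3 * 3 * 7, 0.5, 1), c(3, 3, 7))
  st <- mk_stack(A)
  kk <- mk_kernel(K)
  full <- central_slice(convolve_dose_rate(st, kk))
  cl <- cloning_dose_rate(st, 1, kk)
  hot <- A[, , 5] == 1
  expect_true(all(cl$values[hot] / full$values[hot] > 1))
  # direction check against the direct-summation oracle
  idx <- c(rep(5, 3), 5, rep(5, 3))
  ref <- oracle_convolve(A[, , idx], K)[, , 4]
  mass <- (26 * 26 * 12 * 1e-12) * 1e-3
  expect_equal(cl$values, ref * 1.602176634e-13 / mass * 3.6e6,
               tolerance = 1e-9)
  expect_error(cloning_dose_rate(st, 2, kk), "odd")
})
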