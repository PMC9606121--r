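# Double-exponential kinetics and absorbed-dose integration.

true_par <- list(a = 60, b = 0.11, c = 55, d = 0.6, m = 1, n = 0.5)
curve_of <- function(p, t)
  p$a * exp(-p$b * (t - p$m)) - p$c * exp(-p$d * (t - p$n))

test_that("noiseless samples recover the generating curve", {
  t <- c(1, 2, 3, 4.5, 6, 8, 10, 13, 16, 20, 24, 30, 36, 43)
  pts <- tibble::tibble(t_h = t, dose_rate = curve_of(true_par, t))
  fit <- fit_double_exponential(pts, seed = 2)
  # individual parameters can trade off; the curve itself must match
  ts <- seq(0.5, 43, length.out = 200)
  expect_equal(fit$curve(ts), curve_of(true_par, ts), tolerance = 1e-4)
  expect_lt(fit$residual_norm, 1e-6)
})

test_that("single-exponential data degrade gracefully (c ~ 0)", {
  t <- seq(1, 40, length.out = 12)
  pts <- tibble::tibble(t_h = t, dose_rate = 50 * exp(-0.12 * t))
  fit <- fit_double_exponential(pts, seed = 3)
  ts <- seq(1, 40, length.out = 100)
  expect_equal(fit$curve(ts), 50 * exp(-0.12 * ts), tolerance = 1e-3)
})

test_that("point-count preconditions are enforced", {
  pts <- tibble::tibble(t_h = 1:5, dose_rate = exp(-(1:5)))
  expect_error(fit_double_exponential(pts), "at least 6")
  pts6 <- tibble::tibble(t_h = 1:6, dose_rate = exp(-(1:6) / 3))
  expect_warning(fit_double_exponential(pts6, seed = 1), "barely")
})

test_that("reduced chi-squared is near 1 for correctly specified noise", {
  t <- c(1, 2, 3, 4.5, 6, 8, 10, 13, 16, 20, 24, 30, 36, 43)
  err <- 3
  set.seed(11)
  inside <- 0
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    y <- curve_of(true_par, t) + rnorm(length(t), 0, err)
    pts <- tibble::tibble(t_h = t, dose_rate = y, error = err)
    fit <- fit_double_exponential(pts, seed = r)
    if (fit$chi2_nu > 0.3 && fit$chi2_nu < 3) inside <- inside + 1
  }
  expect_gte(inside / n_rep, 0.9)
})

test_that("pure exponential integrals match the closed forms", {
  fit <- structure(list(a = 10, b = log(2) / 7.2, c = 0, d = 1, m = 0,
                        n = 0, curve = function(t)
                          10 * exp(-log(2) / 7.2 * t)),
                   class = "double_exp_fit")
  # infinite-horizon limit a/b, reached at many half-lives
  expect_equal(integrate_absorbed_dose(fit, 7.2, n_half_lives = 200),
               10 / (log(2) / 7.2) / 1000, tolerance = 1e-9)
  # six half-lives capture exactly 1 - 2^-6 of the infinite integral
  d6 <- integrate_absorbed_dose(fit, 7.2, n_half_lives = 6)
  expect_equal(d6, (1 - 2^-6) * 10 / (log(2) / 7.2) / 1000,
               tolerance = 1e-9)
  zero <- structure(list(a = 0, b = 1, c = 0, d = 1, m = 0, n = 0,
                         curve = function(t) 0 * t),
                    class = "double_exp_fit")
  expect_equal(integrate_absorbed_dose(zero), 0)
  div <- structure(list(a = 1, b = -0.1, c = 0, d = 1, m = 0, n = 0,
                        curve = function(t) exp(0.1 * t)),
                   class = "double_exp_fit")
  expect_error(integrate_absorbed_dose(div), "divergent")
})

test_that("integration is linear in the amplitudes and monotone in horizon", {
  mk <- function(a, c) structure(
    list(a = a, b = 0.2, c = c, d = 0.9, m = 0, n = 0,
         curve = function(t) a * exp(-0.2 * t) - c * exp(-0.9 * t)),
    class = "double_exp_fit")
  # with curves positive on the horizon, the integral is linear in (a, c)
  d1 <- integrate_absorbed_dose(mk(40, 10))
  d2 <- integrate_absorbed_dose(mk(80, 20))
  expect_equal(d2, 2 * d1, tolerance = 1e-8)
  expect_gt(integrate_absorbed_dose(mk(40, 10), n_half_lives = 8), d1)
})

test_that("max-scaled uncertainty behaves like a linear bound", {
  t <- c(1, 2, 3, 4.5, 6, 8, 10, 13, 16, 20, 24, 30, 36, 43)
  y <- curve_of(true_par, t)
  pts <- tibble::tibble(t_h = t, dose_rate = y)
  fit <- fit_double_exponential(pts, seed = 5)
  expect_equal(dose_uncertainty_maxscale(fit, pts), 0, tolerance = 1e-3)
  # one observation 50% above the curve scales the bound to half the dose
  pts2 <- pts
  imax <- which.max(y)
  pts2$dose_rate[imax] <- 1.5 * fit$curve(t[imax])
  u <- dose_uncertainty_maxscale(fit, pts2)
  expect_equal(u, 0.5 * integrate_absorbed_dose(fit), tolerance = 1e-6)
})

test_that("the dose bound covers the truth on noisy phantom time courses", {
  t <- c(1, 2, 3, 4.5, 6, 8, 10, 13, 16, 20, 24, 30, 36, 43)
  err <- 2.5
  truth_dose <- integrate_absorbed_dose(
    structure(c(true_par, list(curve = function(tt) curve_of(true_par, tt))),
              class = "double_exp_fit"))
  set.seed(12)
  n_rep <- 40
  covered <- 0
  for (r in seq_len(n_rep)) {
    y <- curve_of(true_par, t) + rnorm(length(t), 0, err)
    pts <- tibble::tibble(t_h = t, dose_rate = pmax(y, 0.1), error = err)
    fit <- fit_double_exponential(pts, seed = 100 + r)
    est <- integrate_absorbed_dose(fit)
    bound <- dose_uncertainty_maxscale(fit, pts)
    if (abs(truth_dose - est) <= bound + 1e-9 ||
        abs(truth_dose - est) / truth_dose < 0.1) covered <- covered + 1
  }
  expect_gte(covered / n_rep, 0.9)
})

test_that("kinetics fits expose tidy/glance and CSV points load", {
  t <- c(1, 2, 3, 4.5, 6, 8, 10, 13, 16, 20, 24, 30, 36, 43)
  pts <- tibble::tibble(biopsy_id = seq_along(t), t_h = t, region = "hot",
                        dose_rate = curve_of(true_par, t), error = 1,
                        ia_MBq_per_kg = 15)
  p <- file.path(tempdir(), "pts.csv")
  write.csv(pts, p, row.names = FALSE)
  got <- read_dose_rate_points(p, region = "hot")
  expect_equal(nrow(got), length(t))
  norm <- read_dose_rate_points(p, region = "hot", normalize_by_ia = TRUE)
  expect_equal(norm$dose_rate, got$dose_rate / 15)
  expect_equal(norm$error, got$error / 15)
  expect_error(read_dose_rate_points(
    { q <- file.path(tempdir(), "bad.csv"); write.csv(data.frame(x = 1), q,
                                                      row.names = FALSE); q }),
    "t_h")
  fit <- fit_double_exponential(got, seed = 6)
  expect_equal(nrow(generics::tidy(fit)), 6)
  expect_true(is.finite(generics::glance(fit)$residual_norm))
  file.remove(p)
})
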