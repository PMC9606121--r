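# Ground-truth generation and simulated acquisitions.

test_that("truth stacks integrate to the analytic activity total", {
  spec <- phantom_spec(seed = 81)
  tr <- build_truth_stack(spec)
  v <- prod(spec$voxel_xyz_um)
  # node volume within the sampled slab (the 17 sections cover |z| <= 102
  # um of the 120-um polar semi-axis): ellipsoid truncated at t = z0/c
  t <- min(1, spec$shape_xyz[3] / 2 * spec$voxel_xyz_um[3] /
             spec$semi_axes_um[3])
  ell <- pi * prod(spec$semi_axes_um) * (2 * t - 2 * t^3 / 3) / v
  bg <- spec$background_activity * ell
  foci <- sum(vapply(spec$hot_foci, function(f)
    f$amplitude * (2 * pi * f$sigma_um^2)^1.5 / v, 0))
  expect_equal(sum(tr$stack$values), bg + foci, tolerance = 0.01)
  expect_true(all(tr$stack$values >= 0))
})

test_that("truth generation is deterministic and validates foci", {
  a <- build_truth_stack(phantom_spec(seed = 7))
  b <- build_truth_stack(phantom_spec(seed = 7))
  expect_identical(a$stack$values, b$stack$values)
  expect_error(phantom_spec(hot_foci = list(
    list(center_um = c(1e4, 0, 0), sigma_um = 50, amplitude = 1e-4))),
    "outside")
  expect_error(phantom_spec(background_activity = -1), "non-negative")
  expect_error(phantom_spec(cut_fraction = 0), "cut_fraction")
  # zero foci give a plain (uniform-density) ellipsoid
  flat <- build_truth_stack(phantom_spec(hot_foci = list(), seed = 1))
  vals <- flat$stack$values[flat$stack$values > 0]
  expect_equal(length(unique(vals)), 1)
})

test_that("simulated event totals follow the Poisson expectation", {
  spec <- phantom_spec(seed = 83)
  tr <- build_truth_stack(spec)
  cfg <- acquisition_config()
  lam <- log(2) / (7.2 * 3600)
  lms <- simulate_acquisition(tr$stack, cfg, spec = spec, seed = 83)
  mu <- cfg$efficiency * sum(tr$stack$values) *
    (1 - exp(-lam * cfg$duration_s)) / lam
  tot <- sum(vapply(lms, nrow, 0L))
  expect_lt(abs(tot - mu), 4 * sqrt(mu))
  # zero activity gives zero events
  z <- tr$stack; z$values <- z$values * 0
  expect_equal(sum(vapply(simulate_acquisition(z, cfg, seed = 1), nrow, 0L)),
               0L)
})

test_that("event times reproduce the decay constant through fit_decay", {
  spec <- phantom_spec(seed = 85)
  tr <- build_truth_stack(spec)
  cfg <- acquisition_config()
  lms <- simulate_acquisition(tr$stack, cfg, spec = NULL, seed = 85)
  all_t <- unlist(lapply(lms, function(l) l$t_s))
  lm <- listmode_data(tibble::tibble(frame = 0L, t_s = all_t, x_px = 1,
                                     y_px = 1, area_px = 2L, intensity = 1),
                      cfg)
  fit <- fit_decay(bin_temporal(lm, 600))
  se <- fit$half_life_h / sqrt(length(all_t)) * 2
  expect_lt(abs(fit$half_life_h - 7.2), 3 * se + 0.05)
})

test_that("torn slices lose their wedge and carry the flag", {
  spec <- phantom_spec(torn_slices = 9, seed = 86)  # central slice torn
  tr <- build_truth_stack(spec)
  cfg <- acquisition_config()
  lms <- simulate_acquisition(tr$stack, cfg, spec = spec, seed = 86)
  expect_true(attr(lms[[9]], "torn"))
  expect_false(attr(lms[[8]], "torn"))
  # the torn slice lost events relative to its same-area neighbours
  expect_lt(nrow(lms[[9]]), 0.95 * mean(c(nrow(lms[[8]]),
                                           nrow(lms[[10]]))))
})

test_that("per-slice jitter is recorded and within the configured bounds", {
  spec <- phantom_spec(seed = 87)
  tr <- build_truth_stack(spec)
  lms <- simulate_acquisition(tr$stack, acquisition_config(), spec = spec,
                              seed = 87)
  js <- vapply(lms, function(l) attr(l, "jitter")$deg, 0)
  expect_true(all(abs(js) <= spec$jitter_deg))
  expect_gt(stats::sd(js), 0)  # jitters actually vary between slices
})

test_that("pseudo-H&E images carry the generating transform and scale", {
  tr <- build_truth_stack(phantom_spec(cut_fraction = 0.7, seed = 88))
  he <- render_pseudo_he(tr$stack, um_per_px = 5, seed = 88)
  tt <- attr(he, "truth_transform")
  expect_equal(tt$scale, 26 / 5)
  expect_equal(dim(he$rgb)[1:2],
               round(dim(tr$stack$values)[1:2] * 26 / 5))
  # tissue pixels are pink-ish (red > green), background is white
  mid <- tr$stack$values[, , 9] > 0
  big <- dim(he$rgb)[1:2]
  expect_gt(mean(he$rgb[, , 1] > he$rgb[, , 2]), 0.1)
  expect_gt(mean(he$rgb[1, , ] == 1), 0.95)  # top margin stays white
  he2 <- render_pseudo_he(tr$stack, um_per_px = 5, rotation_deg = 30,
                          seed = 88)
  expect_equal(attr(he2, "truth_transform")$rotation_deg, 30)
})

test_that("the full phantom pipeline reproduces the oracle dose map", {
  # phantom -> listmode -> activity -> register -> dose vs direct truth
  # convolution, on a small phantom without jitter so that comparison is
  # voxel-aligned
  spec <- phantom_spec(shape_xyz = c(48, 48, 9), jitter_deg = 0,
                       jitter_px = 0, semi_axes_um = c(450, 350, 70),
                       hot_foci = list(list(center_um = c(100, 50, 0),
                                            sigma_um = 60,
                                            amplitude = 5e-4)),
                       seed = 89)
  tr <- build_truth_stack(spec)
  cfg <- acquisition_config()
  lms <- simulate_acquisition(tr$stack, cfg, spec = spec, seed = 89)
  grid <- c(max(vapply(lms, function(l) floor(max(l$y_px)) + 2, 0)),
            max(vapply(lms, function(l) floor(max(l$x_px)) + 2, 0)))
  acts <- lapply(lms, function(lm)
    slice_activities(lm, grid_shape = grid, expected_n = 1,
                     fixed_half_life_h = 7.2)[[1]])
  st <- register_stack(acts, pad_px = 8)
  kr <- rebin_kernel(radial_average(generate_kernel(
    nuclide_at211(), load_stopping_water(), 2e4, voxel_um = 2,
    half_extent_um = 72, seed = 90)), 26, 12)
  got <- central_slice(convolve_dose_rate(st, kr))
  want <- central_slice(convolve_dose_rate(tr$stack, kr))
  # compare total central-slice dose rate (registration may shift the
  # canvas, totals are translation-invariant)
  expect_lt(abs(sum(got$values) - sum(want$values)) / sum(want$values),
            0.1)
})
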