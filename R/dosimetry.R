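#' Medium model for dose scoring
#'
#' @param density_g_per_cm3 scalar density (default 1.0, water).
#' @return Object of class `medium_model`.
#' @export
medium_model <- function(density_g_per_cm3 = 1.0) {
  if (density_g_per_cm3 <= 0) stop("density must be positive")
  structure(list(density_g_per_cm3 = density_g_per_cm3),
            class = "medium_model")
}

voxel_mass_kg <- function(voxel_xyz_um, medium) {
  vol_cm3 <- prod(voxel_xyz_um) * 1e-12
  medium$density_g_per_cm3 * vol_cm3 * 1e-3
}

#' 3D/2D dose-rate map
#'
#' @param values array (mGy/h per voxel).
#' @param voxel_xyz_um voxel geometry.
#' @param t_ref reference time (s).
#' @param provenance free-form list (kernel id, stack info).
#' @return Object of class `dose_rate_map`.
#' @export
dose_rate_map <- function(values, voxel_xyz_um, t_ref = 0,
                          provenance = list()) {
  if (any(!is.finite(values)) || any(values < 0))
    stop("dose-rate values must be finite and non-negative")
  structure(list(values = values, voxel_xyz_um = as.numeric(voxel_xyz_um),
                 t_ref = t_ref, provenance = provenance),
            class = "dose_rate_map")
}

#' @export
print.dose_rate_map <- function(x, ...) {
  d <- dim(x$values); if (is.null(d)) d <- length(x$values)
  cat("<dose_rate_map> ", paste(d, collapse = "x"), " voxels; mean ",
      signif(mean(x$values), 5), " mGy/h\n", sep = "")
  invisible(x)
}

# centred cross-correlation out[r] = sum_o A[r+o] K[o] via zero-padded FFT
fft_correlate3 <- function(A, K) {
  da <- dim(A); dk <- dim(K)
  p <- vapply(1:3, function(i) stats::nextn(da[i] + dk[i] - 1, c(2, 3, 5)), 0)
  Ap <- array(0, p); Ap[seq_len(da[1]), seq_len(da[2]), seq_len(da[3])] <- A
  Kr <- K[rev(seq_len(dk[1])), rev(seq_len(dk[2])), rev(seq_len(dk[3])),
          drop = FALSE]
  Kp <- array(0, p); Kp[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- Kr
  full <- Re(stats::fft(stats::fft(Ap) * stats::fft(Kp), inverse = TRUE)) /
    prod(p)
  ck <- (dk + 1) / 2
  off <- dk - ck  # = ck - 1 for odd kernels
  full[off[1] + seq_len(da[1]), off[2] + seq_len(da[2]),
       off[3] + seq_len(da[3]), drop = FALSE]
}

#' Dose-point-kernel convolution of an activity stack
#'
#' FFT cross-correlation of the activity stack (Bq/voxel) with the energy
#' deposition kernel (MeV per emission), divided by the mass of the scored
#' voxel: `Ddot(r) = sum_r' A(r') K(|r' - r|) / (rho V)`. One alpha
#' emission per parent decay is assumed (secular equilibrium). Output in
#' mGy/h. Tissue is zero-padded (surrounded by inactive medium).
#'
#' @param stack an [activity_stack()].
#' @param kernel a `dose_kernel` rebinned to the stack voxel geometry
#'   (odd-sized).
#' @param medium a [medium_model()].
#' @return A [dose_rate_map()] (3D, mGy/h).
#' @export
convolve_dose_rate <- function(stack, kernel, medium = medium_model()) {
  if (max(abs(kernel$voxel_xyz_um - stack$voxel_xyz_um)) >
      1e-6 * max(stack$voxel_xyz_um))
    stop("kernel voxel geometry does not match the stack; rebin first")
  if (any(dim(kernel$values) %% 2 == 0))
    stop("kernel must be odd-sized so a central voxel exists")
  e_rate <- fft_correlate3(stack$values, kernel$values)  # MeV/s
  e_rate[e_rate < 0] <- 0  # clip FFT round-off
  mass <- voxel_mass_kg(stack$voxel_xyz_um, medium)
  vals <- e_rate * MEV_TO_J / mass * GY_PER_S_TO_MGY_PER_H
  dose_rate_map(vals, stack$voxel_xyz_um, stack$t_ref,
                provenance = list(kernel_total_MeV = kernel$total_MeV,
                                  density_g_per_cm3 =
                                    medium$density_g_per_cm3))
}

#' Extract the central slice of a dose-rate map
#'
#' Peripheral slices lack measured tissue across the full alpha range on
#' both sides, so analyses use the central slice.
#'
#' @param map a 3D [dose_rate_map()] with odd depth.
#' @return A 2D [dose_rate_map()].
#' @export
central_slice <- function(map) {
  d <- dim(map$values)
  if (length(d) != 3) stop("central_slice needs a 3D map")
  if (d[3] %% 2 == 0)
    stop("even slice count: repair or drop a slice before central-slice ",
         "analysis")
  mid <- (d[3] + 1) / 2
  dose_rate_map(map$values[, , mid], map$voxel_xyz_um, map$t_ref,
                c(map$provenance, list(slice_index = mid)))
}

keep_central_slices <- function(values, N) {
  nz <- dim(values)[3]
  mid <- (nz + 1) / 2
  keep <- seq(mid - (N - 1) / 2, mid + (N - 1) / 2)
  out <- values * 0
  out[, , keep] <- values[, , keep]
  out
}

#' Central-slice dose rate as a function of slice count
#'
#' Emulates limited-slice studies: for each odd N only the central N slices
#' of the stack are kept (zeroing the rest), the dose-point-kernel
#' convolution is rerun, and the summed dose rate of all central-slice
#' voxels is recorded as `dose_rate_N`. `dose_rate_N` at `N = N_max` equals
#' the full-data value `dose_rate_full`.
#'
#' @param stack an [activity_stack()] with odd depth.
#' @param kernel,medium as in [convolve_dose_rate()].
#' @param N_values odd slice counts; default `1, 3, ..., depth`.
#' @return A `slice_minimization` result: tibble `curve` with `N`,
#'   `dose_rate_N`, `ratio`; fields `dose_rate_full`, `method`.
#' @export
slice_contribution_curve <- function(stack, kernel,
                                     medium = medium_model(),
                                     N_values = NULL) {
  nz <- dim(stack$values)[3]
  if (nz %% 2 == 0) stop("odd slice count required")
  if (is.null(N_values)) N_values <- seq(1, nz, by = 2)
  if (any(N_values %% 2 == 0)) stop("N_values must be odd")
  dN <- vapply(N_values, function(N) {
    sub <- stack
    sub$values <- keep_central_slices(stack$values, N)
    sum(central_slice(convolve_dose_rate(sub, kernel, medium))$values)
  }, 0)
  d0 <- dN[which.max(N_values)]
  structure(list(curve = tibble::tibble(N = N_values, dose_rate_N = dN,
                                        ratio = dN / d0),
                 dose_rate_full = d0, N_max = max(N_values),
                 method = "contribution"),
            class = "slice_minimization")
}

#' @export
print.slice_minimization <- function(x, ...) {
  cat("<slice_minimization:", x$method, "> N_max ", x$N_max,
      "; full central-slice dose rate ", signif(x$dose_rate_full, 5),
      " mGy/h\n", sep = "")
  print(x$curve)
  invisible(x)
}

#' Fit the empirical slice-contribution correction factor
#'
#' Least-squares fit of the ratio `dose_rate_N / dose_rate_full` against N
#' with the asymptotic exponential model
#' `ratio(N) = 1 - alpha * exp(-beta (N - 1))`, chosen so the ratio tends
#' to 1 for large N and the single-slice correction stays finite. The
#' scalar correction is `C_N = 1 / ratio_fit(N)` and the corrected
#' estimate is `Ddot_e = C_N * Ddot_N`. Because the model is asymptotic
#' while the measured ratio reaches exactly 1 at `N = N_max`, accuracy
#' degrades for large N.
#'
#' @param result a `slice_minimization` (or a data frame with `N` and
#'   `ratio`), needing at least 3 points; several stacks may be pooled by
#'   row-binding their curves.
#' @param errors optional per-point standard deviations of the ratio; when
#'   given, the fit is weighted and a reduced chi-squared is reported.
#' @return A `contribution_fit`: `alpha`, `beta`, `chi2_nu` (NA unless
#'   errors given), and functions `ratio_fit(N)`, `C_N(N)`.
#' @export
fit_contribution_correction <- function(result, errors = NULL) {
  curve <- if (inherits(result, "slice_minimization")) result$curve
           else tibble::as_tibble(result)
  if (nrow(curve) < 3) stop("need at least 3 (N, ratio) points")
  w <- if (is.null(errors)) rep(1, nrow(curve)) else 1 / errors^2
  if (max(abs(curve$ratio - 1)) < 1e-9) {
    # already converged at every N: no correction needed (flat fit would
    # make the exponential's gradient singular)
    p <- c(alpha = 0, beta = 1)
    chi2 <- sum(w * (curve$ratio - 1)^2)
  } else {
    start <- list(alpha = max(1 - curve$ratio[1], 1e-3), beta = 0.3)
    fit <- minpack.lm::nlsLM(ratio ~ 1 - alpha * exp(-beta * (N - 1)),
                             data = curve, start = start, weights = w,
                             lower = c(0, 0))
    p <- stats::coef(fit)
    chi2 <- sum(w * stats::resid(fit)^2)
  }
  nu <- nrow(curve) - 2
  ratio_fit <- function(N) 1 - p[["alpha"]] * exp(-p[["beta"]] * (N - 1))
  structure(list(alpha = p[["alpha"]], beta = p[["beta"]],
                 chi2_nu = if (is.null(errors)) NA_real_ else chi2 / nu,
                 residual_norm = sum((curve$ratio - ratio_fit(curve$N))^2),
                 ratio_fit = ratio_fit,
                 C_N = function(N) 1 / ratio_fit(N)),
            class = "contribution_fit")
}

#' @export
print.contribution_fit <- function(x, ...) {
  cat("<contribution_fit> ratio(N) = 1 - ", signif(x$alpha, 4),
      " exp(-", signif(x$beta, 4), " (N-1)); C_1 = ",
      signif(x$C_N(1), 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.contribution_fit <- function(x, ...)
  tibble::tibble(term = c("alpha", "beta"), estimate = c(x$alpha, x$beta))

#' @export
glance.contribution_fit <- function(x, ...)
  tibble::tibble(chi2_nu = x$chi2_nu, residual_norm = x$residual_norm,
                 C_1 = x$C_N(1))

#' Cloning estimate of the central-slice dose rate
#'
#' The unmeasured tissue of a limited-slice study is digitally replaced by
#' clones of the outermost measured slices: the central N slices are kept
#' and each side is padded with copies of its outermost kept slice until
#' the stack spans the alpha range (N + 2H slices, H the kernel z
#' half-extent), then the dose-point-kernel convolution is run and the
#' central slice returned. Assumes hotspot patterns vary little with
#' depth; features of the measured slice are overemphasised where that
#' fails.
#'
#' @param stack an [activity_stack()].
#' @param N odd number of measured central slices.
#' @param kernel,medium as in [convolve_dose_rate()].
#' @return A 2D [dose_rate_map()] of the central slice.
#' @export
cloning_dose_rate <- function(stack, N, kernel, medium = medium_model()) {
  nz <- dim(stack$values)[3]
  if (N %% 2 == 0) stop("N must be odd")
  if (N > nz) stop("N exceeds stack depth")
  H <- (dim(kernel$values)[3] - 1) / 2
  mid <- (nz + 1) / 2
  keep <- seq(mid - (N - 1) / 2, mid + (N - 1) / 2)
  pad <- H  # clone slices per side, spanning the kernel z half-extent
  idx <- c(rep(keep[1], pad), keep, rep(keep[length(keep)], pad))
  sub <- stack
  sub$values <- stack$values[, , idx, drop = FALSE]
  central_slice(convolve_dose_rate(sub, kernel, medium))
}
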