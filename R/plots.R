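# ggplot2 views of the pipeline's result types.

#' Plot the radial profile of a kernel (semi-log)
#'
#' @param kernel a cubic `dose_kernel`.
#' @param bin_um radial bin width.
#' @return A ggplot.
#' @export
plot_kernel_profile <- function(kernel, bin_um = 1) {
  prof <- kernel_radial_profile(kernel, bin_um)
  prof <- prof[prof$mean_MeV > 0, ]
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$r_um, y = .data$mean_MeV)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "radial distance (µm)",
                  y = "mean energy per voxel (MeV / emission)",
                  title = "Alpha energy-deposition kernel, radial profile")
}

#' @export
autoplot.dose_kernel <- function(object, ...) plot_kernel_profile(object, ...)

#' Plot a 2D dose-rate map
#'
#' @param map a 2D [dose_rate_map()] (or the central slice of a 3D one).
#' @return A ggplot raster.
#' @export
plot_dose_rate_map <- function(map) {
  vals <- map$values
  if (length(dim(vals)) == 3) vals <- central_slice(map)$values
  df <- data.frame(x = as.vector(col(vals)) * map$voxel_xyz_um[1] / 1000,
                   y = as.vector(row(vals)) * map$voxel_xyz_um[2] / 1000,
                   dose_rate = as.vector(vals))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$dose_rate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = "mGy/h") +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = "Instantaneous dose rate at biopsy")
}

#' @export
autoplot.dose_rate_map <- function(object, ...) plot_dose_rate_map(object)

#' Plot a dose-rate-area histogram with sigma annotations
#'
#' @param hist tibble from [dose_rate_area_histogram()].
#' @return A ggplot.
#' @export
plot_dose_rate_histogram <- function(hist) {
  mu <- attr(hist, "mean"); sig <- attr(hist, "sigma")
  ggplot2::ggplot(hist, ggplot2::aes(.data$dose_rate, .data$area_mm2)) +
    ggplot2::geom_col(width = diff(hist$dose_rate[1:2]),
                      fill = "steelblue") +
    ggplot2::geom_vline(xintercept = mu, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = mu + c(1, 2) * sig,
                        linetype = "dotted") +
    ggplot2::labs(x = "dose rate (mGy/h)", y = "tissue area (mm²)",
                  title = "Dose-rate-area histogram",
                  subtitle = "dashed: mean; dotted: +1σ, +2σ")
}

#' Plot a slice-minimization curve and its correction fit
#'
#' @param result a `slice_minimization`.
#' @param fit optional `contribution_fit` overlay.
#' @return A ggplot.
#' @export
plot_contribution_curve <- function(result, fit = NULL) {
  p <- ggplot2::ggplot(result$curve, ggplot2::aes(.data$N, .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "measured slices N",
                  y = expression(dot(D)[N] / dot(D)[0]),
                  title = paste0("Limited-slice convergence (",
                                 result$method, ")"))
  if (!is.null(fit)) {
    Ns <- seq(min(result$curve$N), max(result$curve$N), length.out = 100)
    p <- p + ggplot2::geom_line(
      data = data.frame(N = Ns, ratio = fit$ratio_fit(Ns)),
      colour = "black")
  }
  p
}

#' @export
autoplot.slice_minimization <- function(object, ...)
  plot_contribution_curve(object, ...)

#' Plot dose-rate kinetics points and a double-exponential fit
#'
#' @param points tibble with `t_h`, `dose_rate`, optional `error`,
#'   optional `region`.
#' @param fit optional `double_exp_fit` (or named list of fits per region).
#' @return A ggplot.
#' @export
plot_dose_rate_curve <- function(points, fit = NULL) {
  pts <- tibble::as_tibble(points)
  if (!"region" %in% names(pts)) pts$region <- "all"
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$t_h, .data$dose_rate,
                                         colour = .data$region)) +
    ggplot2::geom_point()
  if ("error" %in% names(pts))
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$dose_rate - .data$error,
                   ymax = .data$dose_rate + .data$error), width = 0.5)
  if (!is.null(fit)) {
    fits <- if (inherits(fit, "double_exp_fit")) list(all = fit) else fit
    ts <- seq(0, max(pts$t_h) * 1.1, length.out = 200)
    curves <- do.call(rbind, lapply(names(fits), function(nm)
      data.frame(t_h = ts, dose_rate = pmax(fits[[nm]]$curve(ts), 0),
                 region = nm)))
    p <- p + ggplot2::geom_line(data = curves)
  }
  p + ggplot2::labs(x = "time post injection (h)", y = "dose rate (mGy/h)",
                    title = "Dose-rate kinetics")
}

#' @export
autoplot.double_exp_fit <- function(object, points, ...)
  plot_dose_rate_curve(points, object)

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
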