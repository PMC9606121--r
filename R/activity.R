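#' Per-slice activity image
#'
#' 2D array of activity (Bq per pixel) referenced to the biopsy time, with
#' pixel and slice geometry.
#'
#' @param values non-negative matrix of Bq per pixel at `t_ref`.
#' @param pixel_size_um pixel pitch (um).
#' @param slice_thickness_um cryosection thickness (um), default 12.
#' @param t_ref reference (biopsy) timestamp, seconds.
#' @param roi_id identifier of the tissue slice ROI.
#' @return Object of class `activity_image`.
#' @export
activity_image <- function(values, pixel_size_um, slice_thickness_um = 12,
                           t_ref = 0, roi_id = NA) {
  if (any(values < 0)) stop("activity values must be non-negative")
  structure(list(values = values, pixel_size_um = pixel_size_um,
                 slice_thickness_um = slice_thickness_um, t_ref = t_ref,
                 roi_id = roi_id),
            class = "activity_image")
}

#' @export
print.activity_image <- function(x, ...) {
  cat("<activity_image> ", nrow(x$values), "x", ncol(x$values),
      " px @ ", x$pixel_size_um, " um; total ",
      signif(sum(x$values), 5), " Bq (roi ", x$roi_id, ")\n", sep = "")
  invisible(x)
}

#' Segment a multi-slice autoradiograph into tissue ROIs
#'
#' Gaussian smoothing, Otsu threshold over the nonzero pixels, morphological
#' closing and hole filling, 8-connected components, small-component
#' rejection, and reading-order sorting (rows of slices top to bottom, then
#' left to right; ties broken by x-centroid).
#'
#' @param image counts matrix containing spatially separated tissue blobs.
#' @param expected_n number of tissue slices expected; `NULL` returns all
#'   components found. When given, the `expected_n` largest components are
#'   returned and a shortfall raises an error.
#' @param smooth_sigma Gaussian sigma in pixels (default 2).
#' @param min_area_frac reject components smaller than this fraction of the
#'   largest component (default 0.05).
#' @return List of ROIs, each `list(mask, bbox = c(r0, r1, c0, c1),
#'   centroid_px = c(x, y))`, reading-order sorted.
#' @export
segment_rois <- function(image, expected_n = NULL, smooth_sigma = 2,
                         min_area_frac = 0.05) {
  mask <- smooth_halfcore_mask(image, smooth_sigma)
  if (is.null(mask)) {
    if (!is.null(expected_n))
      stop("segmentation shortfall: found 0 ROIs, expected ", expected_n)
    return(list())
  }
  lab <- cpp_label8(mask * 1)
  n <- max(lab)
  if (n == 0) {
    if (!is.null(expected_n))
      stop("segmentation shortfall: found 0 ROIs, expected ", expected_n)
    return(list())
  }
  areas <- tabulate(lab[lab > 0], n)
  keep <- which(areas >= min_area_frac * max(areas))
  if (!is.null(expected_n)) {
    if (length(keep) < expected_n)
      stop("segmentation shortfall: found ", length(keep),
           " ROIs, expected ", expected_n)
    keep <- keep[order(areas[keep], decreasing = TRUE)][seq_len(expected_n)]
  }
  rois <- lapply(keep, function(l) {
    m <- lab == l
    ai <- which(m, arr.ind = TRUE)
    w <- image[m]
    if (sum(w) == 0) w <- rep(1, nrow(ai))
    list(mask = m,
         bbox = c(min(ai[, 1]), max(ai[, 1]), min(ai[, 2]), max(ai[, 2])),
         centroid_px = c(x = sum((ai[, 2] - 1) * w) / sum(w),
                         y = sum((ai[, 1] - 1) * w) / sum(w)))
  })
  # reading order: group into rows of slices, then sort by x within a row
  cy <- vapply(rois, function(r) r$centroid_px[["y"]], 0)
  cx <- vapply(rois, function(r) r$centroid_px[["x"]], 0)
  hgt <- stats::median(vapply(rois, function(r) r$bbox[2] - r$bbox[1] + 1, 0))
  row_id <- integer(length(rois))
  for (i in order(cy)) {
    prev <- which(row_id > 0)
    same <- prev[abs(cy[prev] - cy[i]) < 0.5 * hgt]
    row_id[i] <- if (length(same)) row_id[same[1]] else max(row_id) + 1L
  }
  ord <- order(row_id, cx)
  rois <- rois[ord]
  for (i in seq_along(rois)) rois[[i]]$roi_id <- i
  rois
}

# Smooth, threshold at half the tissue-core level, close and fill.
# A blurred step crosses half-height at the true boundary, so this neither
# erodes sparse Poisson-textured slices (as a plain Otsu cut does) nor
# dilates them into the smoothing halo (as a very low cut does). The core
# level is located by Otsu, making the whole rule scale-invariant.
# Returns NULL for an all-zero image.
smooth_halfcore_mask <- function(image, smooth_sigma = 2) {
  sm <- as.matrix(EBImage::gblur(EBImage::Image(image), sigma = smooth_sigma))
  nz <- sm[sm > 0]
  if (!length(nz)) return(NULL)
  core <- sm >= otsu_threshold(nz)
  thr <- mean(sm[core]) / 2
  mask <- sm >= thr
  mask <- as.matrix(EBImage::closing(EBImage::Image(mask * 1),
                                     EBImage::makeBrush(5, "disc"))) > 0
  as.matrix(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
}

#' Fit an exponential decay to a temporal count histogram
#'
#' Least-squares fit of `counts = amplitude * exp(-lambda * t)`. With a
#' fixed half-life only the amplitude is fitted (closed form). A best-fit
#' decay constant at or below zero is flagged non-physical but the fit is
#' still returned.
#'
#' @param t_s bin centres (seconds) or a tibble from [bin_temporal()].
#' @param counts event counts per bin (omit when `t_s` is a tibble).
#' @param fixed_half_life_h optional fixed half-life in hours.
#' @return Object of class `decay_fit`: `rate_per_s`, `amplitude`,
#'   `half_life_h`, `residual_norm`, `physical`, `n_bins`.
#' @export
fit_decay <- function(t_s, counts = NULL, fixed_half_life_h = NULL) {
  if (is.data.frame(t_s)) { counts <- t_s$counts; t_s <- t_s$t_s }
  nonempty <- sum(counts > 0)
  if (is.null(fixed_half_life_h) && nonempty < 3)
    stop("need at least 3 non-empty bins to fit rate and amplitude")
  if (!is.null(fixed_half_life_h) && nonempty < 1)
    stop("need at least 1 non-empty bin")
  if (!is.null(fixed_half_life_h)) {
    lam <- log(2) / (fixed_half_life_h * 3600)
    e <- exp(-lam * t_s)
    A <- sum(counts * e) / sum(e^2)
    res <- sum((counts - A * e)^2)
    return(new_decay_fit(lam, A, res, length(counts), physical = TRUE))
  }
  pos <- counts > 0
  sl <- stats::coef(stats::lm(log(counts[pos]) ~ t_s[pos]))
  start <- list(A = exp(sl[[1]]), lam = max(-sl[[2]], 1e-9))
  fit <- minpack.lm::nlsLM(counts ~ A * exp(-lam * t_s), start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- stats::coef(fit)
  new_decay_fit(p[["lam"]], p[["A"]], sum(stats::resid(fit)^2),
                length(counts),
                physical = p[["lam"]] > 1e-12)
}

new_decay_fit <- function(rate_per_s, amplitude, residual_norm, n_bins,
                          physical) {
  if (!physical)
    warning("non-decaying temporal histogram: fitted rate <= 0", call. = FALSE)
  structure(list(rate_per_s = rate_per_s, amplitude = amplitude,
                 half_life_h = log(2) / rate_per_s / 3600,
                 residual_norm = residual_norm, n_bins = n_bins,
                 physical = physical),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> half-life ", signif(x$half_life_h, 4), " h; amplitude ",
      signif(x$amplitude, 4), " counts/bin",
      if (!x$physical) " [non-physical]", "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("amplitude", "rate_per_s", "half_life_h"),
                 estimate = c(x$amplitude, x$rate_per_s, x$half_life_h))
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(half_life_h = x$half_life_h, residual_norm = x$residual_norm,
                 n_bins = x$n_bins, physical = x$physical)
}

#' Convert a counts image to activity at the reference time
#'
#' Inverts radioactive decay over the acquisition window and the detection
#' efficiency: `A = N * lambda * exp(lambda * t_start) /
#' (efficiency * (1 - exp(-lambda * T)))`, per pixel, giving the activity
#' at the reference (biopsy) time.
#'
#' @param counts 2D counts image (events per pixel over the acquisition).
#' @param fit a [fit_decay()] result, or a bare decay constant in 1/s.
#' @param config an [acquisition_config()] (efficiency, start time,
#'   duration).
#' @param slice_thickness_um,roi_id metadata for the output.
#' @return An [activity_image()] in Bq per pixel at `t_ref`.
#' @export
decay_correct <- function(counts, fit, config, slice_thickness_um = 12,
                          roi_id = NA) {
  lam <- if (inherits(fit, "decay_fit")) fit$rate_per_s else fit
  T <- config$duration_s
  eps <- config$efficiency
  if (T <= 0) stop("acquisition duration must be positive")
  if (eps <= 0 || eps > 1) stop("efficiency must be in (0, 1]")
  scale <- lam * exp(lam * config$t_start_s) / (eps * (1 - exp(-lam * T)))
  activity_image(counts * scale, config$pixel_size_um, slice_thickness_um,
                 t_ref = config$t_ref, roi_id = roi_id)
}

#' Listmode to per-slice activity images
#'
#' Segments the binned event image into tissue ROIs, builds each ROI's
#' temporal histogram, fits (or fixes) the decay constant per ROI, and
#' decay-corrects the per-pixel counts into activity snapshots at biopsy
#' time. Pixels outside the ROI mask are zero; no background subtraction.
#'
#' @param lm a `listmode` table.
#' @param grid_shape counts-image shape `c(nrow, ncol)`; default covers all
#'   events.
#' @param expected_n expected number of tissue slices (optional).
#' @param fixed_half_life_h fix the decay half-life (hours) instead of
#'   fitting per ROI -- useful at low counts.
#' @param bin_width_s temporal bin width for the per-ROI decay fit.
#' @return List of [activity_image()] objects in reading order, with each
#'   ROI's `decay_fit` attached as attribute `fit`.
#' @export
slice_activities <- function(lm, grid_shape = NULL, expected_n = NULL,
                             fixed_half_life_h = NULL, bin_width_s = 600) {
  cfg <- attr(lm, "config")
  if (is.null(grid_shape))
    grid_shape <- c(floor(max(lm$y_px)) + 1, floor(max(lm$x_px)) + 1)
  img <- bin_spatial(lm, grid_shape)
  rois <- segment_rois(img, expected_n = expected_n)
  lapply(rois, function(roi) {
    px <- cbind(floor(lm$y_px) + 1, floor(lm$x_px) + 1)
    inside <- roi$mask[px]
    sub <- lm[inside, , drop = FALSE]
    attr(sub, "config") <- cfg
    fit <- if (is.null(fixed_half_life_h))
      fit_decay(bin_temporal(sub, bin_width_s))
    else
      fit_decay(bin_temporal(sub, bin_width_s),
                fixed_half_life_h = fixed_half_life_h)
    counts <- img * 0
    counts[roi$mask] <- img[roi$mask]
    ai <- decay_correct(counts, fit, cfg, roi_id = roi$roi_id)
    attr(ai, "fit") <- fit
    ai
  })
}
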