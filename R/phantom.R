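#' Digital lymph-node phantom specification
#'
#' Ground-truth generator emulating the study conditions: an ellipsoidal
#' node of low-background activity with focal Gaussian hotspots, imaged as
#' 12-um sections with a ~20 um FWHM detector blur, per-slice rigid
#' mounting jitter, and optionally torn slices. Default activities put the
#' phantom in the regime of sparse single-alpha-event autoradiographs with
#' background dose rates of a few tens of mGy/h.
#'
#' @param shape_xyz voxel grid `(nx, ny, nz)`; default `c(64, 64, 17)`
#'   (17 sections of 12 um straddling the node centre; outer sections
#'   keep a substantial tissue cross-section).
#' @param voxel_xyz_um voxel edges, default `c(26, 26, 12)`.
#' @param semi_axes_um ellipsoid semi-axes (um), default
#'   `c(650, 500, 120)`.
#' @param background_activity background Bq/voxel inside the node
#'   (default 1e-4).
#' @param hot_foci list of `list(center_um = c(x, y, z), sigma_um,
#'   amplitude)` isotropic Gaussian foci (centres relative to the node
#'   centre, amplitudes in Bq/voxel). Default: two follicle-scale foci
#'   (sigma 50 um) at 5x background, near the central plane so their
#'   Gaussian mass is contained in the flat node.
#' @param cut_fraction fraction of the node extent along x retained by the
#'   biopsy cut (1 = whole node; smaller values emulate the part-node
#'   sections seen in practice and give the section an asymmetric
#'   outline).
#' @param psf_fwhm_um detector blur FWHM (default 20).
#' @param jitter_deg,jitter_px half-widths of the uniform per-slice
#'   mounting misalignment (default 10 deg, 20 px).
#' @param torn_slices slice indices corrupted by a zeroed wedge.
#' @param seed RNG seed recorded in the spec.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_xyz = c(64, 64, 17),
                         voxel_xyz_um = c(26, 26, 12),
                         semi_axes_um = c(650, 500, 120),
                         background_activity = 1e-4,
                         hot_foci = list(
                           list(center_um = c(-200, -100, -12),
                                sigma_um = 50, amplitude = 5e-4),
                           list(center_um = c(250, 150, 12),
                                sigma_um = 50, amplitude = 5e-4)),
                         cut_fraction = 1,
                         psf_fwhm_um = 20, jitter_deg = 10, jitter_px = 20,
                         torn_slices = integer(), seed = 1L) {
  if (cut_fraction <= 0 || cut_fraction > 1)
    stop("cut_fraction must be in (0, 1]")
  if (background_activity < 0) stop("activities must be non-negative")
  for (f in hot_foci) {
    if (f$amplitude < 0) stop("activities must be non-negative")
    if (any(abs(f$center_um) > semi_axes_um))
      stop("focus centre outside the node ellipsoid")
  }
  structure(list(shape_xyz = shape_xyz, voxel_xyz_um = voxel_xyz_um,
                 semi_axes_um = semi_axes_um,
                 background_activity = background_activity,
                 hot_foci = hot_foci, cut_fraction = cut_fraction,
                 psf_fwhm_um = psf_fwhm_um,
                 jitter_deg = jitter_deg, jitter_px = jitter_px,
                 torn_slices = torn_slices, seed = seed),
            class = "phantom_spec")
}

#' Voxelise the phantom ground truth
#'
#' Activity is the background inside the ellipsoid plus the Gaussian foci
#' (foci truncated at the node boundary). Deterministic given the spec.
#'
#' @param spec a [phantom_spec()].
#' @return `list(stack, focus_masks)`: an [activity_stack()] of true
#'   activity and per-focus logical masks (within 2 sigma of each centre).
#' @export
build_truth_stack <- function(spec) {
  d <- spec$shape_xyz
  v <- spec$voxel_xyz_um
  # voxel-centre coordinates relative to the grid centre, in um
  xs <- (seq_len(d[1]) - (d[1] + 1) / 2) * v[1]
  ys <- (seq_len(d[2]) - (d[2] + 1) / 2) * v[2]
  zs <- (seq_len(d[3]) - (d[3] + 1) / 2) * v[3]
  # arrays indexed (y, x, z) to match image row/col conventions
  X <- array(rep(xs, each = d[2]), c(d[2], d[1], d[3]))
  Y <- array(rep(ys, times = d[1] * d[3]), c(d[2], d[1], d[3]))
  Z <- array(rep(zs, each = d[1] * d[2]), c(d[2], d[1], d[3]))
  inside <- (X / spec$semi_axes_um[1])^2 + (Y / spec$semi_axes_um[2])^2 +
    (Z / spec$semi_axes_um[3])^2 <= 1
  if (spec$cut_fraction < 1)  # part-node biopsy cut along x
    inside <- inside &
      (X <= spec$semi_axes_um[1] * (2 * spec$cut_fraction - 1))
  act <- array(0, dim(inside))
  act[inside] <- spec$background_activity
  focus_masks <- vector("list", length(spec$hot_foci))
  for (i in seq_along(spec$hot_foci)) {
    f <- spec$hot_foci[[i]]
    r2 <- (X - f$center_um[1])^2 + (Y - f$center_um[2])^2 +
      (Z - f$center_um[3])^2
    act <- act + inside * f$amplitude * exp(-r2 / (2 * f$sigma_um^2))
    focus_masks[[i]] <- inside & (r2 <= (2 * f$sigma_um)^2)
  }
  list(stack = activity_stack(act, v, t_ref = 0),
       focus_masks = focus_masks)
}

#' Simulate a listmode acquisition of a phantom
#'
#' Event-by-event simulation of each slice: per voxel the expected number
#' of detections over the acquisition window is
#' `efficiency * A * (1 - exp(-lambda T)) / lambda`; realised counts are
#' Poisson; event times are inverse-CDF samples of the window-truncated
#' exponential; positions are the voxel position blurred with the detector
#' PSF; each slice receives a rigid mounting jitter; torn slices have a
#' wedge of events removed.
#'
#' @param truth an [activity_stack()] of true activity (Bq/voxel).
#' @param config an [acquisition_config()].
#' @param nuclide a [nuclide_at211()]-style object.
#' @param spec optional [phantom_spec()] supplying PSF/jitter/tears; when
#'   omitted, no jitter or tears and a 20 um PSF are used.
#' @param seed RNG seed.
#' @return List of per-slice `listmode` tables, with each slice's true
#'   jitter attached as attribute `jitter` (`list(deg, dx, dy)`) and torn
#'   flag `torn`.
#' @export
simulate_acquisition <- function(truth, config, nuclide = nuclide_at211(),
                                 spec = NULL, seed = 1L) {
  lam <- decay_constant(nuclide)
  T <- config$duration_s
  if (T <= 0) stop("duration must be positive")
  px_um <- config$pixel_size_um
  vox <- truth$voxel_xyz_um
  d <- dim(truth$values)
  psf_fwhm <- if (is.null(spec)) 20 else spec$psf_fwhm_um
  sigma_px <- psf_fwhm / 2.3548200450309493 / px_um
  jit_deg <- if (is.null(spec)) 0 else spec$jitter_deg
  jit_px <- if (is.null(spec)) 0 else spec$jitter_px
  torn <- if (is.null(spec)) integer() else spec$torn_slices
  frame_dt <- 1 / config$frame_rate_hz
  # margin so jittered/blurred events keep positive detector coordinates
  margin <- jit_px + ceiling(4 * sigma_px) + 2
  set.seed(seed)
  out <- vector("list", d[3])
  for (k in seq_len(d[3])) {
    sl <- truth$values[, , k]
    mu <- config$efficiency * sl * (1 - exp(-lam * T)) / lam
    n_vox <- stats::rpois(length(mu), mu)
    tot <- sum(n_vox)
    idx <- rep.int(seq_along(mu), n_vox)
    rr <- (idx - 1) %% d[1] + 1          # row (y)
    cc <- (idx - 1) %/% d[1] + 1         # col (x)
    # voxel position in detector pixels (pixel pitch px_um, voxel vox um)
    x <- (cc - 0.5) * vox[1] / px_um
    y <- (rr - 0.5) * vox[2] / px_um
    x <- x + stats::rnorm(tot, 0, sigma_px)
    y <- y + stats::rnorm(tot, 0, sigma_px)
    u <- stats::runif(tot)
    t_s <- -log(1 - u * (1 - exp(-lam * T))) / lam
    # per-slice mounting jitter about the slice centre
    th <- stats::runif(1, -jit_deg, jit_deg) * pi / 180
    dx <- stats::runif(1, -jit_px, jit_px)
    dy <- stats::runif(1, -jit_px, jit_px)
    ctr <- c(d[2] * vox[1], d[1] * vox[2]) / px_um / 2  # (x, y)
    xr <- cos(th) * (x - ctr[1]) - sin(th) * (y - ctr[2]) + ctr[1] + dx +
      margin
    yr <- sin(th) * (x - ctr[1]) + cos(th) * (y - ctr[2]) + ctr[2] + dy +
      margin
    keep <- rep(TRUE, tot)
    if (k %in% torn && tot > 0) {
      ang <- atan2(yr - ctr[2] - margin, xr - ctr[1] - margin)
      keep <- !(ang > 0 & ang < pi / 3)  # zeroed wedge
    }
    lm <- listmode_data(
      tibble::tibble(frame = as.integer(floor(t_s[keep] / frame_dt)),
                     t_s = t_s[keep], x_px = xr[keep], y_px = yr[keep],
                     area_px = 4L, intensity = 1),
      config)
    attr(lm, "jitter") <- list(deg = th * 180 / pi, dx = dx, dy = dy)
    attr(lm, "torn") <- k %in% torn
    out[[k]] <- lm
  }
  out
}

#' Render a pseudo-H&E image of the phantom central slice
#'
#' The tissue mask of the truth central slice is painted as a pink/purple
#' stain texture on a white background, then mapped through a known
#' scale/rotation/shear so fusion can be tested against a ground-truth
#' transform.
#'
#' @param truth an [activity_stack()].
#' @param um_per_px output pixel size (um); smaller than the map's pixel
#'   size, as histology scans outresolve autoradiographs.
#' @param rotation_deg,shear known transform components applied to the
#'   rendered image.
#' @param seed texture seed.
#' @return A [histology_image()] with attribute `truth_transform`.
#' @export
render_pseudo_he <- function(truth, um_per_px = 5, rotation_deg = 0,
                             shear = 0, seed = 1L) {
  mid <- (dim(truth$values)[3] + 1) %/% 2
  sl <- truth$values[, , mid]
  s <- truth$voxel_xyz_um[1] / um_per_px
  big <- resize_bilinear(sl, max(2, round(nrow(sl) * s)),
                         max(2, round(ncol(sl) * s)))
  mask <- big > max(big) * 0.01
  nr <- nrow(mask); nc <- ncol(mask)
  set.seed(seed)
  tex <- matrix(stats::runif(nr * nc, 0, 1), nr, nc)
  tex <- as.matrix(EBImage::gblur(EBImage::Image(tex), sigma = 2))
  tex <- (tex - min(tex)) / diff(range(tex))
  rgb <- array(1, c(nr, nc, 3))
  rgb[, , 1][mask] <- 0.85 - 0.15 * tex[mask]   # pink/purple tissue
  rgb[, , 2][mask] <- 0.35 + 0.25 * tex[mask]
  rgb[, , 3][mask] <- 0.65 + 0.2 * tex[mask]
  if (rotation_deg != 0 || shear != 0) {
    T <- rigid_transform(rotation_deg)
    for (ch in 1:3) {
      pl <- rgb[, , ch]
      bg <- 1 - pl  # warp tissue signal, keep background white
      rgb[, , ch] <- 1 - apply_rigid(bg, T, shear)
    }
  }
  out <- histology_image(rgb, um_per_px)
  attr(out, "truth_transform") <- list(scale = s,
                                       rotation_deg = rotation_deg,
                                       shear = shear)
  out
}
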