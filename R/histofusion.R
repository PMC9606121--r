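#' Otsu threshold and binary mask
#'
#' Threshold maximizing the between-class variance of the 256-bin intensity
#' histogram (delegated to EBImage's implementation); the mask keeps pixels
#' at or above the threshold. Foreground is defined per modality: H&E uses
#' inverted luminance so that tissue (darker than the white background) is
#' foreground.
#'
#' @param image 2D grayscale matrix (or numeric vector) with at least two
#'   distinct values.
#' @param levels histogram bins (default 256).
#' @return `otsu_binary`: `list(threshold, mask)`. `otsu_threshold` returns
#'   just the number.
#' @export
otsu_binary <- function(image, levels = 256) {
  thr <- otsu_threshold(image, levels)
  list(threshold = thr, mask = image >= thr)
}

#' @rdname otsu_binary
#' @export
otsu_threshold <- function(image, levels = 256) {
  x <- as.numeric(image)
  rng <- range(x)
  if (rng[1] == rng[2]) stop("constant image: Otsu threshold undefined")
  br <- seq(rng[1], rng[2], length.out = levels + 1)
  h <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), levels),
                levels)
  mids <- (br[-1] + br[-(levels + 1)]) / 2
  w1 <- cumsum(h)
  m1 <- cumsum(h * mids)
  w2 <- w1[levels] - w1
  m2 <- m1[levels] - m1
  between <- w1 * w2 * (m1 / w1 - m2 / pmax(w2, 1))^2
  between[w1 == 0 | w2 == 0] <- -Inf
  t <- which.max(between)  # classes split after bin t (first max on ties)
  br[t + 1]                # threshold at the upper edge of bin t
}

#' Binary mask for sparse autoradiographs
#'
#' Sparse dose-rate/event images need a lower cut than Otsu's to cover the
#' whole tissue extent: the threshold is one tenth of the Otsu threshold.
#' Scale-invariant (thresholds are relative to the image histogram).
#'
#' @param map 2D [dose_rate_map()] or matrix, not all zero.
#' @return Logical mask.
#' @export
iqid_binary <- function(map) {
  vals <- if (inherits(map, "dose_rate_map")) map$values else map
  vals >= otsu_threshold(vals) / 10
}

#' Histology image container
#'
#' @param rgb array `(rows, cols, 3)` with values in `[0, 1]`.
#' @param um_per_px physical pixel size from the scale bar.
#' @param stain stain label (default "H&E").
#' @return Object of class `histology_image`.
#' @export
histology_image <- function(rgb, um_per_px, stain = "H&E") {
  if (um_per_px <= 0) stop("um_per_px must be positive")
  if (length(dim(rgb)) != 3 || dim(rgb)[3] < 3)
    stop("rgb must be an (rows, cols, 3) array")
  structure(list(rgb = rgb, um_per_px = um_per_px, stain = stain),
            class = "histology_image")
}

#' @export
print.histology_image <- function(x, ...) {
  cat("<histology_image> ", dim(x$rgb)[1], "x", dim(x$rgb)[2], " px @ ",
      x$um_per_px, " um/px (", x$stain, ")\n", sep = "")
  invisible(x)
}

he_inverted_luminance <- function(hist) {
  rgb <- hist$rgb
  lum <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  max(lum) - lum
}

resize_bilinear <- function(m, nr, nc)
  as.matrix(EBImage::resize(EBImage::Image(m), w = nr, h = nc))

hom <- function(m23) rbind(m23, c(0, 0, 1))

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

#' Co-register a dose-rate map with an H&E image
#'
#' The high-resolution H&E image is down-sampled (factor 20 by default) and
#' cast to a tissue binary by Otsu on inverted luminance; the sparser
#' dose-rate map is binarised at one tenth of its Otsu threshold and
#' rescaled by the known pixel-size ratio so both binaries share a
#' micrometre scale. The binaries are then co-registered by coarse MSE
#' rotation search plus rigid refinement, optionally followed by a small
#' shear refinement (|shear| <= 0.2), and the transform is composed back to
#' full-resolution H&E coordinates. Reflections (sections impressed
#' face-down) are a manual flag.
#'
#' @param iqid_map 2D [dose_rate_map()].
#' @param hist a [histology_image()].
#' @param allow_shear refine a shear term after the rigid stage.
#' @param reflect mirror the map horizontally before registration.
#' @param downsample H&E down-sampling factor (default 20).
#' @param angle_step_deg coarse rotation granularity.
#' @return A `fusion_transform`: `matrix_fwd` (2x3, map pixel -> full-res
#'   H&E pixel), components (`scale`, `rotation_deg`, `dx`, `dy`, `shear`,
#'   `reflect`), `dice` overlap in the down-sampled frame, and
#'   `low_confidence` flag (Dice < 0.5).
#' @export
fuse <- function(iqid_map, hist, allow_shear = FALSE, reflect = FALSE,
                 downsample = 20, angle_step_deg = 1) {
  stopifnot(inherits(iqid_map, "dose_rate_map"),
            inherits(hist, "histology_image"))
  ds <- downsample
  he_px_um <- hist$um_per_px * ds
  he_g <- he_inverted_luminance(hist)
  he_small <- resize_bilinear(he_g, max(2, round(nrow(he_g) / ds)),
                              max(2, round(ncol(he_g) / ds)))
  he_mask <- otsu_binary(he_small)$mask

  iq_px_um <- iqid_map$voxel_xyz_um[1]
  s <- iq_px_um / he_px_um
  iq <- iqid_map$values
  iq_rs <- resize_bilinear(iq, max(2, round(nrow(iq) * s)),
                           max(2, round(ncol(iq) * s)))
  if (reflect) iq_rs <- iq_rs[, rev(seq_len(ncol(iq_rs))), drop = FALSE]
  iq_mask <- iqid_binary(iq_rs)

  nr <- max(nrow(he_mask), nrow(iq_mask)) + 16L
  nc <- max(ncol(he_mask), ncol(iq_mask)) + 16L
  # light smoothing anti-aliases the binary edges, removing the
  # quantisation plateaus that bias sub-degree rotation estimates
  soften <- function(m)
    as.matrix(EBImage::gblur(EBImage::Image(m * 1), sigma = 1))
  he_c <- pad_to_canvas(soften(he_mask), nr, nc)
  iq_c <- pad_to_canvas(soften(iq_mask), nr, nc)
  off_iq <- c((nc - ncol(iq_mask)) %/% 2, (nr - nrow(iq_mask)) %/% 2)  # x, y
  off_he <- c((nc - ncol(he_mask)) %/% 2, (nr - nrow(he_mask)) %/% 2)

  th0 <- coarse_align(iq_c, he_c, angle_step_deg)
  T <- refine_rigid(iq_c, he_c, th0)
  shear <- 0
  ctr <- c((nc - 1) / 2, (nr - 1) / 2)
  if (allow_shear) {
    # profile search: shear (applied before the rigid part) is scanned in
    # 1D with the rigid refiner as inner solver -- a joint simplex stalls
    # in the curved rotation-shear valley of binary-mask MSE
    shear_warp <- function(sh)
      cpp_affine_warp(iq_c, rigid_inverse_matrix(0, 0, 0, ctr, sh), nr, nc)
    best <- list(s = 0, T = T, mse = T$mse)
    prof <- function(sh) {
      Ts <- refine_rigid(shear_warp(sh), he_c, T$rotation_deg)
      if (Ts$mse < best$mse) best <<- list(s = sh, T = Ts, mse = Ts$mse)
      Ts$mse
    }
    opt <- stats::optimize(prof, c(-0.2, 0.2), tol = 1e-3)
    prof(opt$minimum)
    T <- best$T
    shear <- best$s
  }
  warped <- if (shear == 0) apply_rigid(iq_c, T)
            else apply_rigid(cpp_affine_warp(
              iq_c, rigid_inverse_matrix(0, 0, 0, ctr, shear), nr, nc), T)
  dice <- dice_coef(warped >= 0.5, he_c >= 0.5)

  # forward map: iqid map pixel -> full-resolution H&E pixel
  A <- hom(cbind(diag(c(s, s)), c(0, 0)))                 # rescale to um frame
  if (reflect)
    A <- hom(cbind(matrix(c(-1, 0, 0, 1), 2, 2),
                   c(ncol(iq_rs) - 1, 0))) %*% A
  B <- hom(cbind(diag(2), off_iq))                        # pad offset
  C <- solve(hom(rigid_inverse_matrix(T$rotation_deg, T$dx, T$dy, ctr))) %*%
    solve(hom(rigid_inverse_matrix(0, 0, 0, ctr, shear)))  # shear then rigid
  D <- hom(cbind(diag(c(ds, ds)), c(0, 0))) %*%
    hom(cbind(diag(2), -off_he))                          # back to full res
  F <- (D %*% C %*% B %*% A)[1:2, , drop = FALSE]
  structure(list(matrix_fwd = F,
                 scale = iq_px_um / hist$um_per_px,
                 rotation_deg = T$rotation_deg, dx = T$dx, dy = T$dy,
                 shear = shear, reflect = reflect, dice = dice,
                 low_confidence = dice < 0.5, downsample = ds),
            class = "fusion_transform")
}

#' @export
print.fusion_transform <- function(x, ...) {
  cat("<fusion_transform> scale ", signif(x$scale, 4), "x; rotation ",
      signif(x$rotation_deg, 4), " deg; shear ", signif(x$shear, 3),
      "; Dice ", signif(x$dice, 3),
      if (x$low_confidence) " [low confidence]", "\n", sep = "")
  invisible(x)
}

#' Overlay dose-region contours on the H&E image
#'
#' The hot-region mask (in dose-rate-map pixel coordinates) is mapped
#' through the fusion transform into full-resolution H&E coordinates,
#' its boundary contour is rasterised in red over the RGB image, and a
#' 1 mm scale bar is drawn.
#'
#' @param hist a [histology_image()].
#' @param partition a [partition_by_sigma()] result (its `hot` mask is
#'   drawn) or a logical mask.
#' @param T a `fusion_transform` from [fuse()].
#' @param colour contour RGB, default red.
#' @return RGB array with the dimensions of the H&E image.
#' @export
overlay_contours <- function(hist, partition, T, colour = c(1, 0, 0)) {
  mask <- if (inherits(partition, "region_partition"))
    partition$region_masks$hot else partition
  he <- hist$rgb
  nr <- dim(he)[1]; nc <- dim(he)[2]
  Finv <- solve(hom(T$matrix_fwd))[1:2, , drop = FALSE]
  m_he <- cpp_affine_warp(mask * 1, Finv, nr, nc) >= 0.5
  if (!any(m_he))
    stop("transform maps the mask outside the histology image")
  er <- as.matrix(EBImage::erode(EBImage::Image(m_he * 1),
                                 EBImage::makeBrush(3, "box"))) > 0
  edge <- m_he & !er
  out <- he
  for (ch in 1:3) {
    pl <- out[, , ch]
    pl[edge] <- colour[ch]
    out[, , ch] <- pl
  }
  # 1 mm scale bar, bottom left
  bar_px <- max(2L, round(1000 / hist$um_per_px))
  r0 <- max(1, nr - round(nr * 0.05)); rr <- r0:min(nr, r0 + 4)
  cc <- 10:min(nc, 10 + bar_px - 1)
  for (ch in 1:3) out[rr, cc, ch] <- 0
  out
}
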