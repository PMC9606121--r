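#' 2D rigid transform
#'
#' Forward map `p' = R(theta) (p - c) + c + t` in 0-based pixel coordinates
#' (x = column, y = row).
#'
#' @param rotation_deg rotation angle (degrees).
#' @param dx,dy translation (pixels).
#' @param center_px rotation centre `c(x, y)`; defaults to the image centre
#'   at application time.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation_deg = 0, dx = 0, dy = 0,
                            center_px = NULL) {
  structure(list(rotation_deg = rotation_deg, dx = dx, dy = dy,
                 center_px = center_px, converged = TRUE),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> theta ", signif(x$rotation_deg, 4), " deg; t (",
      signif(x$dx, 4), ", ", signif(x$dy, 4), ") px\n", sep = "")
  invisible(x)
}

transform_center <- function(T, img) {
  if (!is.null(T$center_px)) T$center_px else c((ncol(img) - 1) / 2,
                                                (nrow(img) - 1) / 2)
}

# 2x3 inverse map (input coords from output coords) for cpp_affine_warp,
# optionally with shear (applied after rotation) and output offset.
rigid_inverse_matrix <- function(theta_deg, dx, dy, center, shear = 0) {
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- matrix(c(1, 0, shear, 1), 2, 2)
  M <- S %*% R                     # forward linear part
  Mi <- solve(M)
  off <- center - Mi %*% (center + c(dx, dy))
  cbind(Mi, off)
}

#' Apply a rigid (or sheared) transform to an image
#'
#' Bilinear interpolation, zero fill outside the canvas.
#'
#' @param img matrix.
#' @param T a [rigid_transform()].
#' @param shear optional shear coefficient (x' gains `shear * y`).
#' @return Warped matrix of the same size.
#' @export
apply_rigid <- function(img, T, shear = 0) {
  ctr <- transform_center(T, img)
  minv <- rigid_inverse_matrix(T$rotation_deg, T$dx, T$dy, ctr, shear)
  cpp_affine_warp(img, minv, nrow(img), ncol(img))
}

rotate_about_center <- function(img, theta_deg)
  apply_rigid(img, rigid_transform(theta_deg))

img_mse <- function(a, b) mean((a - b)^2)

#' Coarse rotational alignment by exhaustive MSE search
#'
#' Returns the angle on `[-180, 180)` at `angle_step_deg` granularity that
#' minimizes the mean-squared error between the rotated moving image and
#' the reference; ties are broken by the smallest absolute angle.
#'
#' @param moving,reference same-shape matrices, both nonzero.
#' @param angle_step_deg search granularity (default 1 degree).
#' @return Rotation angle in degrees.
#' @export
coarse_align <- function(moving, reference, angle_step_deg = 1) {
  if (sum(abs(moving)) == 0 || sum(abs(reference)) == 0)
    stop("degenerate alignment: all-zero image")
  stopifnot(all(dim(moving) == dim(reference)))
  angles <- seq(-180, 180 - angle_step_deg, by = angle_step_deg)
  mse <- vapply(angles, function(a)
    img_mse(rotate_about_center(moving, a), reference), 0)
  cand <- which(mse <= min(mse) + 1e-15)
  angles[cand[which.min(abs(angles[cand]))]]
}

down2 <- function(m) {
  nr <- 2 * (nrow(m) %/% 2); nc <- 2 * (ncol(m) %/% 2)
  m <- m[seq_len(nr), seq_len(nc)]
  (m[seq(1, nr, 2), seq(1, nc, 2)] + m[seq(2, nr, 2), seq(1, nc, 2)] +
   m[seq(1, nr, 2), seq(2, nc, 2)] + m[seq(2, nr, 2), seq(2, nc, 2)]) / 4
}

intensity_centroid <- function(img) {
  s <- sum(img)
  c(sum(t(img) * (seq_len(ncol(img)) - 1)) / s,   # x (column)
    sum(img * (seq_len(nrow(img)) - 1)) / s)      # y (row)
}

#' Rigid-body refinement of a coarse alignment
#'
#' Intensity least-squares refinement of (rotation, dx, dy) with bilinear
#' interpolation. The translation is initialised from the intensity
#' centroids, the rotation is re-scanned at that translation (a
#' rotation-only scan is biased when the pair is also shifted), and the
#' joint optimum is found by Nelder-Mead within `angle_bound_deg` of the
#' re-scanned angle. Guaranteed not to worsen the starting MSE: if the
#' search fails, the initial transform is returned with
#' `converged = FALSE`.
#'
#' @param moving,reference same-shape matrices.
#' @param init_deg initial rotation from [coarse_align()].
#' @param angle_bound_deg joint-refinement bound around the re-scanned
#'   angle (default 5).
#' @param angle_step_deg granularity of the internal rotation re-scan.
#' @param max_shift_px translation bound (default half of the canvas).
#' @return A `rigid_transform` with a `converged` flag and final `mse`.
#' @export
refine_rigid <- function(moving, reference, init_deg = 0,
                         angle_bound_deg = 5, angle_step_deg = 1,
                         max_shift_px = NULL) {
  stopifnot(all(dim(moving) == dim(reference)))
  if (is.null(max_shift_px)) max_shift_px <- max(dim(moving)) / 2
  ctr <- c((ncol(moving) - 1) / 2, (nrow(moving) - 1) / 2)
  mse_at <- function(p) {
    minv <- rigid_inverse_matrix(p[1], p[2], p[3], ctr)
    img_mse(cpp_affine_warp(moving, minv, nrow(moving), ncol(moving)),
            reference)
  }
  # translation seed: match intensity centroids at the initial rotation
  rot0 <- rotate_about_center(moving, init_deg)
  t0 <- if (sum(rot0) > 0 && sum(reference) > 0)
    intensity_centroid(reference) - intensity_centroid(rot0) else c(0, 0)
  t0 <- pmin(pmax(t0, -max_shift_px), max_shift_px)
  # rotation and translation are strongly coupled (a curved valley where a
  # joint simplex stalls), so alternate a global rotation scan at the
  # current translation with a translation-only fit until the angle
  # settles, then polish the angle by profile (min-over-translation)
  # golden search
  angles <- seq(-180, 180 - angle_step_deg, by = angle_step_deg)
  cur_t <- t0
  inner_t <- function(th) {
    o <- stats::optim(cur_t, function(t) {
      if (max(abs(t)) > max_shift_px) return(Inf)
      mse_at(c(th, t))
    }, method = "Nelder-Mead",
    control = list(maxit = 300, reltol = 1e-12))
    cur_t <<- o$par
    o$value
  }
  scan <- vapply(angles, function(a) mse_at(c(a, t0)), 0)
  th <- angles[which.min(scan)]
  for (round in 1:5) {
    inner_t(th)
    rescan <- vapply(angles, function(a) mse_at(c(a, cur_t)), 0)
    th_new <- angles[which.min(rescan)]
    if (th_new == th) break
    th <- th_new
  }
  opt <- stats::optimize(inner_t,
                         c(th - min(angle_bound_deg, 2.5),
                           th + min(angle_bound_deg, 2.5)), tol = 1e-4)
  inner_t(opt$minimum)  # refresh cur_t at the optimum
  par <- c(opt$minimum, cur_t)
  T <- rigid_transform(par[1], par[2], par[3])
  mse0 <- img_mse(rotate_about_center(moving, init_deg), reference)
  mse1 <- mse_at(par)
  if (!is.finite(mse1) || mse1 > mse0) {
    T <- rigid_transform(init_deg, 0, 0)
    T$converged <- FALSE
    T$mse <- mse0
  } else T$mse <- mse1
  T
}

#' Apply a transform with scalar activity compensation
#'
#' Bilinear interpolation loses or gains a little cumulative intensity at
#' the canvas edges and through resampling; the returned image is rescaled
#' by `sum(before) / sum(after)` so cumulative activity is preserved
#' exactly, and the factor is reported.
#'
#' @param image matrix or [activity_image()] with positive total.
#' @param T a [rigid_transform()].
#' @return `list(image, compensation)`.
#' @export
apply_with_compensation <- function(image, T) {
  vals <- if (inherits(image, "activity_image")) image$values else image
  s0 <- sum(vals)
  if (s0 <= 0) stop("cannot compensate an image with non-positive total")
  out <- apply_rigid(vals, T)
  s1 <- sum(out)
  if (s1 <= 0) stop("transform pushed all activity off the canvas")
  comp <- s0 / s1
  out <- out * comp
  if (inherits(image, "activity_image")) {
    image$values <- out
    list(image = image, compensation = comp)
  } else list(image = out, compensation = comp)
}

#' Registered 3D activity stack
#'
#' @param values 3D array (rows, cols, slices) of Bq/voxel at `t_ref`.
#' @param voxel_xyz_um voxel edges `(x, y, z)`; z is the slice thickness.
#' @param t_ref reference time (s).
#' @param transforms per-slice [rigid_transform()] list.
#' @param compensation_factors per-slice scalars.
#' @param replaced_slices indices replaced during repair.
#' @return Object of class `activity_stack`.
#' @export
activity_stack <- function(values, voxel_xyz_um, t_ref = 0,
                           transforms = NULL, compensation_factors = NULL,
                           replaced_slices = integer()) {
  if (any(values < 0)) stop("activity must be non-negative")
  structure(list(values = values, voxel_xyz_um = as.numeric(voxel_xyz_um),
                 t_ref = t_ref, transforms = transforms,
                 compensation_factors = compensation_factors,
                 replaced_slices = replaced_slices),
            class = "activity_stack")
}

#' @export
print.activity_stack <- function(x, ...) {
  d <- dim(x$values)
  cat("<activity_stack> ", d[1], "x", d[2], " px x ", d[3], " slices; voxel ",
      paste(signif(x$voxel_xyz_um, 4), collapse = "x"), " um; total ",
      signif(sum(x$values), 5), " Bq\n", sep = "")
  invisible(x)
}

pad_to_canvas <- function(m, nr, nc) {
  out <- matrix(0, nr, nc)
  r0 <- (nr - nrow(m)) %/% 2
  c0 <- (nc - ncol(m)) %/% 2
  out[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))] <- m
  out
}

#' Register consecutive slice activity images into a 3D stack
#'
#' Neighbour-chained registration: slice 1 is fixed; each subsequent slice
#' is aligned to its already-transformed predecessor by coarse MSE rotation
#' search plus rigid refinement, then resampled with scalar activity
#' compensation. All slices are first zero-padded onto a common canvas.
#' For central-slice dosimetry the slice count is forced odd by dropping
#' the last slice (with a warning).
#'
#' @param images ordered list of [activity_image()] (or matrices) sharing a
#'   pixel size.
#' @param angle_step_deg coarse search granularity.
#' @param pad_px extra canvas margin (pixels) for expected displacement.
#' @param force_odd drop a trailing slice to keep the count odd
#'   (default TRUE).
#' @return An [activity_stack()].
#' @export
register_stack <- function(images, angle_step_deg = 1, pad_px = 32,
                           force_odd = TRUE) {
  stopifnot(length(images) >= 1)
  mats <- lapply(images, function(im)
    if (inherits(im, "activity_image")) im$values else im)
  px <- if (inherits(images[[1]], "activity_image"))
    images[[1]]$pixel_size_um else 1
  t_ref <- if (inherits(images[[1]], "activity_image"))
    images[[1]]$t_ref else 0
  thick <- if (inherits(images[[1]], "activity_image"))
    images[[1]]$slice_thickness_um else 12
  nr <- max(vapply(mats, nrow, 0L)) + 2L * pad_px
  nc <- max(vapply(mats, ncol, 0L)) + 2L * pad_px
  mats <- lapply(mats, pad_to_canvas, nr = nr, nc = nc)
  nz <- length(mats)
  vals <- array(0, c(nr, nc, nz))
  transforms <- vector("list", nz)
  comp <- rep(1, nz)
  vals[, , 1] <- mats[[1]]
  transforms[[1]] <- rigid_transform(0, 0, 0)
  if (nz > 1) for (k in 2:nz) {
    ref <- vals[, , k - 1]
    th0 <- coarse_align(mats[[k]], ref, angle_step_deg)
    T <- refine_rigid(mats[[k]], ref, th0)
    res <- apply_with_compensation(mats[[k]], T)
    vals[, , k] <- res$image
    transforms[[k]] <- T
    comp[k] <- res$compensation
  }
  if (force_odd && nz %% 2 == 0) {
    warning("dropping last slice to keep an odd slice count", call. = FALSE)
    vals <- vals[, , -nz, drop = FALSE]
    transforms <- transforms[-nz]
    comp <- comp[-nz]
  }
  activity_stack(vals, c(px, px, thick), t_ref, transforms, comp)
}

#' Replace torn or discarded slices with neighbouring duplicates
#'
#' Each bad slice is replaced by a copy of its nearest good slice (ties go
#' to the lower index); replacements are recorded in the stack provenance.
#'
#' @param stack an [activity_stack()].
#' @param bad_indices slice indices to replace (1-based).
#' @return The repaired [activity_stack()].
#' @export
repair_stack <- function(stack, bad_indices) {
  nz <- dim(stack$values)[3]
  bad_indices <- sort(unique(as.integer(bad_indices)))
  if (!length(bad_indices)) return(stack)
  if (any(bad_indices < 1 | bad_indices > nz))
    stop("bad_indices outside 1..", nz)
  good <- setdiff(seq_len(nz), bad_indices)
  if (!length(good)) stop("all slices bad: stack unrecoverable")
  for (b in bad_indices) {
    d <- abs(good - b)
    src <- good[which.min(d)]  # which.min takes the first (lower) on ties
    stack$values[, , b] <- stack$values[, , src]
  }
  stack$replaced_slices <- union(stack$replaced_slices, bad_indices)
  stack
}
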