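# Float TIFF + JSON sidecar IO. TIFF float storage is defined on [0, 1],
# so arrays are written normalized with the scale recorded in the sidecar;
# round-trips are exact to float32 precision.

write_pages <- function(arr, path, scale_max) {
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  pages <- lapply(seq_len(dim(arr)[3]), function(k)
    arr[, , k] / scale_max)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none")
}

read_pages <- function(path, scale_max) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    arr[, , k] <- p * scale_max
  }
  arr
}

write_sidecar <- function(meta, path)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)

read_sidecar <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing JSON sidecar: ", side)
  jsonlite::read_json(side, simplifyVector = TRUE)
}

#' Write/read an activity stack as multi-page float TIFF + JSON sidecar
#'
#' @param stack an [activity_stack()].
#' @param path TIFF path; the sidecar is `<path>.json`.
#' @return `read_activity_stack` returns the [activity_stack()].
#' @export
write_activity_stack <- function(stack, path) {
  smax <- max(stack$values, 1e-300)
  write_pages(stack$values, path, smax)
  write_sidecar(list(kind = "activity_stack", units = "Bq",
                     scale_max = smax,
                     voxel_xyz_um = stack$voxel_xyz_um, t_ref = stack$t_ref,
                     compensation_factors = stack$compensation_factors,
                     transforms = lapply(stack$transforms, function(T)
                       if (is.null(T)) NULL else
                         T[c("rotation_deg", "dx", "dy")]),
                     replaced_slices = stack$replaced_slices,
                     total_Bq = sum(stack$values)),
                path)
  invisible(path)
}

#' @rdname write_activity_stack
#' @export
read_activity_stack <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$kind, "activity_stack"))
    stop("sidecar kind mismatch: expected activity_stack, got ", meta$kind)
  vals <- read_pages(path, meta$scale_max)
  tr <- meta$transforms
  transforms <- if (is.data.frame(tr))  # jsonlite simplifies uniform lists
    lapply(seq_len(nrow(tr)), function(i)
      rigid_transform(tr$rotation_deg[i], tr$dx[i], tr$dy[i]))
  else if (!is.null(tr))
    lapply(tr, function(p) rigid_transform(p$rotation_deg, p$dx, p$dy))
  activity_stack(vals, meta$voxel_xyz_um, meta$t_ref, transforms,
                 meta$compensation_factors,
                 as.integer(unlist(meta$replaced_slices)))
}

#' Write/read a dose kernel as multi-page float TIFF + JSON sidecar
#'
#' The reader validates the array total against the sidecar's recorded
#' total. Per-voxel uncertainties are stored alongside in
#' `<path base>_unc.tif` and restored when present.
#'
#' @param kernel a `dose_kernel`.
#' @param path TIFF path.
#' @return `read_kernel` returns the `dose_kernel`.
#' @export
write_kernel <- function(kernel, path) {
  smax <- max(kernel$values, 1e-300)
  write_pages(kernel$values, path, smax)
  unc_path <- sub("\\.tiff?$", "_unc.tif", path)
  write_pages(kernel$rel_uncertainty, unc_path,
              max(kernel$rel_uncertainty, 1e-300))
  write_sidecar(c(list(kind = "dose_kernel", units = "MeV_per_emission",
                       scale_max = smax,
                       unc_scale_max = max(kernel$rel_uncertainty, 1e-300),
                       voxel_xyz_um = kernel$voxel_xyz_um,
                       n_events = kernel$n_events,
                       total_MeV = kernel$total_MeV),
                  kernel$provenance),
                path)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$kind, "dose_kernel"))
    stop("sidecar kind mismatch: expected dose_kernel, got ", meta$kind)
  vals <- read_pages(path, meta$scale_max)
  if (abs(sum(vals) - meta$total_MeV) > 1e-4 * meta$total_MeV)
    stop("kernel total ", sum(vals), " MeV does not match sidecar total ",
         meta$total_MeV, " MeV")
  unc_path <- sub("\\.tiff?$", "_unc.tif", path)
  rel <- if (file.exists(unc_path))
    read_pages(unc_path, meta$unc_scale_max) else array(0, dim(vals))
  prov <- meta[setdiff(names(meta),
                       c("kind", "units", "scale_max", "unc_scale_max",
                         "voxel_xyz_um", "n_events", "total_MeV"))]
  new_dose_kernel(vals, meta$voxel_xyz_um, meta$n_events, rel, prov)
}

#' Write/read a dose-rate map as float TIFF + JSON sidecar
#'
#' @param map a [dose_rate_map()] (2D or 3D).
#' @param path TIFF path.
#' @return `read_dose_rate_map` returns the [dose_rate_map()].
#' @export
write_dose_rate_map <- function(map, path) {
  smax <- max(map$values, 1e-300)
  write_pages(map$values, path, smax)
  write_sidecar(list(kind = "dose_rate_map", units = "mGy/h",
                     scale_max = smax, voxel_xyz_um = map$voxel_xyz_um,
                     t_ref = map$t_ref, ndim = length(dim(map$values)),
                     provenance = map$provenance),
                path)
  invisible(path)
}

#' @rdname write_dose_rate_map
#' @export
read_dose_rate_map <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$kind, "dose_rate_map"))
    stop("sidecar kind mismatch: expected dose_rate_map, got ", meta$kind)
  vals <- read_pages(path, meta$scale_max)
  if (!is.null(meta$ndim) && meta$ndim == 2) vals <- vals[, , 1]
  dose_rate_map(vals, meta$voxel_xyz_um, meta$t_ref,
                as.list(meta$provenance))
}

#' Read camera frames from a multi-page TIFF
#'
#' Page order is time order; values are returned as acquired (16-bit
#' integer TIFFs read as [0,1] are rescaled back to integer counts).
#'
#' @param path TIFF path.
#' @param as_integer rescale [0,1]-coded 16-bit data back to DN.
#' @return List of frame matrices.
#' @export
read_frames_tiff <- function(path, as_integer = TRUE) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = as_integer)
  lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
}
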