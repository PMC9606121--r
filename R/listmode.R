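#' Acquisition configuration
#'
#' Camera parameters of a listmode acquisition. The default efficiency is
#' 0.49: half of the measured 98% 4-pi alpha detection efficiency, for the
#' 2-pi source-on-scintillator geometry.
#'
#' @param pixel_size_um effective pixel pitch (10-30 um typical).
#' @param frame_rate_hz frame rate (20-30 typical).
#' @param efficiency detected fraction of decays, in (0, 1].
#' @param t_ref biopsy/reference timestamp in seconds; acquisition times are
#'   measured from acquisition start, which is `t_start_s` after `t_ref`.
#' @param t_start_s acquisition start relative to `t_ref` (s).
#' @param duration_s total imaging time (s), default 15 h.
#' @return Object of class `acquisition_config`.
#' @export
acquisition_config <- function(pixel_size_um = 26, frame_rate_hz = 25,
                               efficiency = 0.49, t_ref = 0, t_start_s = 0,
                               duration_s = 15 * 3600) {
  if (efficiency <= 0 || efficiency > 1) stop("efficiency must be in (0, 1]")
  if (pixel_size_um <= 0 || frame_rate_hz <= 0 || duration_s <= 0)
    stop("pixel size, frame rate and duration must be positive")
  structure(list(pixel_size_um = pixel_size_um, frame_rate_hz = frame_rate_hz,
                 efficiency = efficiency, t_ref = t_ref,
                 t_start_s = t_start_s, duration_s = duration_s),
            class = "acquisition_config")
}

#' Build a listmode event table
#'
#' @param events tibble/data.frame with columns `frame`, `t_s`, `x_px`,
#'   `y_px`, `area_px`, `intensity` (0-based pixel coordinates, origin
#'   top-left, x = column, y = row).
#' @param config an [acquisition_config()].
#' @return A `listmode` tibble with the config attached as an attribute.
#' @export
listmode_data <- function(events, config) {
  need <- c("frame", "t_s", "x_px", "y_px", "area_px", "intensity")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("missing listmode columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(events) && any(events$area_px < 1)) stop("area_px must be >= 1")
  out <- tibble::as_tibble(events[need])
  attr(out, "config") <- config
  class(out) <- c("listmode", class(out))
  out
}

#' @export
print.listmode <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<listmode> ", nrow(x), " events; pixel ", cfg$pixel_size_um,
      " um; efficiency ", cfg$efficiency, "\n", sep = "")
  NextMethod()
}

#' Detect alpha events in a camera frame
#'
#' Pixels at or above `threshold` are grouped into 8-connected components;
#' each component with at least `min_area` pixels yields one event at its
#' intensity-weighted centroid, with its pixel count and summed intensity.
#' Overlapping clusters are not split: they are counted as one event.
#'
#' @param frame 2D intensity matrix (rows = y, cols = x).
#' @param threshold detection threshold (must exceed background).
#' @param min_area minimum cluster size in pixels (default 2, rejecting
#'   single-pixel noise).
#' @return Tibble with `x_px`, `y_px` (0-based centroids), `area_px`,
#'   `intensity`; zero rows when nothing is above threshold.
#' @export
detect_events <- function(frame, threshold, min_area = 2) {
  if (!is.matrix(frame) || !length(frame)) stop("frame must be a non-empty matrix")
  if (min_area < 1) stop("min_area must be >= 1")
  mask <- frame >= threshold
  if (!any(mask))
    return(tibble::tibble(x_px = numeric(), y_px = numeric(),
                          area_px = integer(), intensity = numeric()))
  lab <- cpp_label8(mask * 1)
  sel <- lab != 0
  labs <- lab[sel]
  w <- frame[sel]
  rows <- row(frame)[sel] - 1  # 0-based y
  cols <- col(frame)[sel] - 1  # 0-based x
  wsum <- as.vector(rowsum(w, labs))
  area <- as.vector(table(labs))
  xc <- as.vector(rowsum(w * cols, labs)) / wsum
  yc <- as.vector(rowsum(w * rows, labs)) / wsum
  keep <- area >= min_area
  tibble::tibble(x_px = xc[keep], y_px = yc[keep],
                 area_px = as.integer(area[keep]), intensity = wsum[keep])
}

#' Bin listmode events into a counts image
#'
#' Events are assigned to pixels by flooring their centroid coordinates
#' (half-open pixels, 0-based): pixel (i, j) covers x in [j, j+1) and
#' y in [i, i+1).
#'
#' @param lm a `listmode` table (or any data frame with `x_px`, `y_px`).
#' @param grid_shape `c(nrow, ncol)` of the output image; must cover all
#'   events.
#' @return Integer counts matrix; `sum(counts) == nrow(lm)`.
#' @export
bin_spatial <- function(lm, grid_shape) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  i <- floor(lm$y_px); j <- floor(lm$x_px)
  bad <- which(i < 0 | i >= nr | j < 0 | j >= nc)
  if (length(bad))
    stop("events outside grid at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  counts <- matrix(0L, nr, nc)
  if (nrow(lm)) {
    t <- table(factor(i * nc + j, levels = 0:(nr * nc - 1)))
    counts <- matrix(as.integer(t), nr, nc, byrow = TRUE)
  }
  counts
}

#' Temporal histogram of listmode events
#'
#' @param lm a `listmode` table (column `t_s`).
#' @param bin_width_s bin width in seconds (default 600 s).
#' @param duration_s histogram span; defaults to the acquisition duration
#'   attached to `lm`, else the last event time.
#' @return Tibble with `t_s` (bin centres) and `counts`.
#' @export
bin_temporal <- function(lm, bin_width_s = 600, duration_s = NULL) {
  if (bin_width_s <= 0) stop("bin_width_s must be positive")
  if (is.null(duration_s)) {
    cfg <- attr(lm, "config")
    duration_s <- if (!is.null(cfg)) cfg$duration_s else max(lm$t_s, 1)
  }
  edges <- seq(0, duration_s + bin_width_s * 1e-9, by = bin_width_s)
  if (edges[length(edges)] < duration_s) edges <- c(edges, duration_s)
  b <- findInterval(lm$t_s, edges, rightmost.closed = TRUE)
  b <- pmin(pmax(b, 1L), length(edges) - 1L)
  counts <- tabulate(b, length(edges) - 1L)
  tibble::tibble(t_s = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts)
}

#' Convert a stack of camera frames to listmode events
#'
#' Runs [detect_events()] on every frame (page order = time order) and
#' assembles the events into a `listmode` table with event times at the
#' frame midpoints.
#'
#' @param frames list of frame matrices (e.g. from [read_frames_tiff()]).
#' @param config an [acquisition_config()] (frame rate, pixel size).
#' @param threshold,min_area cluster detection parameters.
#' @return A `listmode` table.
#' @export
frames_to_listmode <- function(frames, config, threshold, min_area = 2) {
  dt <- 1 / config$frame_rate_hz
  evs <- lapply(seq_along(frames), function(k) {
    ev <- detect_events(frames[[k]], threshold, min_area)
    if (nrow(ev)) {
      ev$frame <- k - 1L
      ev$t_s <- (k - 0.5) * dt
    } else {
      ev$frame <- integer(); ev$t_s <- numeric()
    }
    ev
  })
  all <- do.call(rbind, evs)
  listmode_data(all[c("frame", "t_s", "x_px", "y_px", "area_px",
                      "intensity")], config)
}

#' Read/write listmode CSV with its JSON acquisition sidecar
#'
#' CSV header: `frame,t_s,x_px,y_px,area_px,intensity`; the sidecar
#' `<file>.json` stores the [acquisition_config()].
#'
#' @param lm a `listmode` table.
#' @param path CSV path.
#' @return `read_listmode` returns a `listmode` table.
#' @export
write_listmode <- function(lm, path) {
  utils::write.csv(as.data.frame(unclass(lm))[, c("frame", "t_s", "x_px",
                                                  "y_px", "area_px",
                                                  "intensity")],
                   path, row.names = FALSE, quote = FALSE)
  cfg <- attr(lm, "config")
  jsonlite::write_json(unclass(cfg), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_listmode
#' @export
read_listmode <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing acquisition sidecar: ", side)
  cfg <- do.call(acquisition_config, jsonlite::read_json(side,
                                                         simplifyVector = TRUE))
  listmode_data(utils::read.csv(path), cfg)
}
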