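# Fluorescence time-lapse rendering and stack / ROI file I/O.
#
# A `timelapse_stack` holds frames as an n_frames x rows x cols numeric
# array (au), the frame times (min) and a channel label. ROIs are named
# rectangles in 0-based, row-major, half-open coordinates
# [row_start, row_stop) x [col_start, col_stop), matching the on-disk JSON
# format.

#' Imaging model
#'
#' Noise and gain model of the fluorescence acquisition. Expected pixel
#' intensity is `gain * concentration + background_level`; if
#' `shot_noise = TRUE` a Poisson draw on the expectation is taken, then
#' Gaussian read noise of SD `read_noise_sd` is added. Defaults give an
#' ROI-sum signal-to-noise ratio of roughly 20 at the BBB-preset plateau.
#'
#' @param frame_shape Frame size, `c(rows, cols)` pixels.
#' @param gain Intensity per unit concentration per pixel, au.
#' @param background_level Autofluorescence background per pixel, au.
#' @param shot_noise Apply Poisson shot noise?
#' @param read_noise_sd SD of additive Gaussian read noise, au.
#' @param seed Integer seed for the renderer; identical seeds give
#'   bit-identical stacks.
#' @return An object of class `imaging_model`.
#' @export
imaging_model <- function(frame_shape = c(64, 96), gain = 0.1,
                          background_level = 10, shot_noise = TRUE,
                          read_noise_sd = 2, seed = 1L) {
  stop_if(length(frame_shape) != 2 || any(frame_shape < 1) ||
            any(frame_shape != round(frame_shape)),
          "`frame_shape` must be two positive integers c(rows, cols)")
  check_positive(gain, "gain")
  check_non_negative(background_level, "background_level")
  check_non_negative(read_noise_sd, "read_noise_sd")
  stop_if(!is.logical(shot_noise) || length(shot_noise) != 1 ||
            is.na(shot_noise), "`shot_noise` must be TRUE/FALSE")
  stop_if(!is.numeric(seed) || length(seed) != 1 || is.na(seed),
          "`seed` must be an integer")
  structure(
    list(frame_shape = as.integer(frame_shape), gain = gain,
         background_level = background_level, shot_noise = shot_noise,
         read_noise_sd = read_noise_sd, seed = as.integer(seed)),
    class = "imaging_model")
}

#' ROI set
#'
#' Three named rectangular regions (outer channel, central compartment,
#' background) in 0-based, half-open pixel coordinates
#' `c(row_start, row_stop, col_start, col_stop)`.
#'
#' @param outer,central,background Integer vectors of length 4.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(outer, central, background) {
  rois <- list(outer = outer, central = central, background = background)
  for (nm in names(rois)) {
    r <- rois[[nm]]
    stop_if(length(r) != 4 || any(r != round(r)) || any(r < 0) ||
              r[2] <= r[1] || r[4] <= r[3],
            sprintf("ROI `%s` must be a non-empty rectangle [row_start, row_stop, col_start, col_stop)", nm))
    rois[[nm]] <- as.integer(r)
  }
  # pairwise disjoint
  pairs <- combn(names(rois), 2)
  for (j in seq_len(ncol(pairs))) {
    a <- rois[[pairs[1, j]]]; b <- rois[[pairs[2, j]]]
    overlap <- a[1] < b[2] && b[1] < a[2] && a[3] < b[4] && b[3] < a[4]
    stop_if(overlap, sprintf("ROIs `%s` and `%s` overlap",
                             pairs[1, j], pairs[2, j]))
  }
  structure(rois, class = "roi_set")
}

roi_pixel_count <- function(r) (r[2] - r[1]) * (r[4] - r[3])

# 1-based R index ranges of a 0-based half-open rectangle
roi_rows <- function(r) (r[1] + 1L):r[2]
roi_cols <- function(r) (r[3] + 1L):r[4]

#' Default ROI layout for a frame
#'
#' Places the outer channel and central compartment as two equal-sized
#' horizontal bands (so their pixel counts match) with a thinner background
#' band below, mirroring where a user would draw ROIs on the chip image.
#'
#' @param frame_shape `c(rows, cols)`.
#' @return A [roi_set()].
#' @export
roi_layout <- function(frame_shape = c(64, 96)) {
  rows <- frame_shape[1]; cols <- frame_shape[2]
  stop_if(rows < 24 || cols < 10,
          "frame too small to hold three disjoint regions (need >= 24 x 10)")
  band <- max(4L, as.integer(floor(0.28 * rows)))
  gap <- max(1L, as.integer(floor(0.04 * rows)))
  r0 <- max(1L, as.integer(floor(0.05 * rows)))
  bg_band <- max(2L, as.integer(floor(0.10 * rows)))
  c0 <- as.integer(floor(0.08 * cols))
  c1 <- as.integer(ceiling(0.92 * cols))
  bg0 <- r0 + 2L * (band + gap)
  stop_if(bg0 + bg_band > rows,
          "frame too small to hold three disjoint regions")
  roi_set(outer = c(r0, r0 + band, c0, c1),
          central = c(r0 + band + gap, r0 + 2L * band + gap, c0, c1),
          background = c(bg0, bg0 + bg_band, c0, c1))
}

#' Render a fluorescence time-lapse from concentration traces
#'
#' One frame per timepoint. Pixels inside the outer ROI have expected value
#' `gain * C_PF(t) + background_level`, inside the central ROI
#' `gain * C_CC(t) + background_level`, elsewhere `background_level`. Shot
#' (Poisson) and read (Gaussian) noise are applied per the imaging model;
#' with noise disabled the frames are exactly the expectations. Frames are
#' kept as doubles in memory and quantized to 16-bit only on write
#' ([write_stack()]).
#'
#' @param traces A `concentration_traces` tibble from [simulate_transport()].
#' @param imaging An [imaging_model()].
#' @param rois A [roi_set()]; default [roi_layout()] for the frame shape.
#' @param channel Channel label stored with the stack.
#' @return An object of class `timelapse_stack`: list with `frames`
#'   (n x rows x cols array), `times`, `channel` and `rois`.
#' @export
render_timelapse <- function(traces, imaging, rois = NULL,
                             channel = "fluorescence") {
  stopifnot(inherits(traces, "concentration_traces"),
            inherits(imaging, "imaging_model"))
  shape <- imaging$frame_shape
  if (is.null(rois)) rois <- roi_layout(shape)
  stopifnot(inherits(rois, "roi_set"))
  validate_rois_in_frame(rois, shape)

  n <- nrow(traces)
  frames <- array(imaging$background_level, dim = c(n, shape[1], shape[2]))
  for (i in seq_len(n)) {
    frames[i, roi_rows(rois$outer), roi_cols(rois$outer)] <-
      imaging$gain * traces$outer_conc[i] + imaging$background_level
    frames[i, roi_rows(rois$central), roi_cols(rois$central)] <-
      imaging$gain * traces$central_conc[i] + imaging$background_level
  }
  if (imaging$shot_noise || imaging$read_noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(imaging$seed)
    if (imaging$shot_noise)
      frames[] <- rpois(length(frames), lambda = frames)
    if (imaging$read_noise_sd > 0)
      frames[] <- frames + rnorm(length(frames), sd = imaging$read_noise_sd)
    frames[frames < 0] <- 0
  }
  structure(list(frames = frames, times = traces$time_min, channel = channel,
                 rois = rois),
            class = "timelapse_stack")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

validate_rois_in_frame <- function(rois, shape) {
  for (nm in names(rois)) {
    r <- rois[[nm]]
    stop_if(r[2] > shape[1] || r[4] > shape[2],
            sprintf("ROI `%s` exceeds the %d x %d frame", nm,
                    shape[1], shape[2]))
  }
  invisible(rois)
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<timelapse_stack> %d frames of %d x %d px, t = %g..%g min (%s)\n",
              d[1], d[2], d[3], min(x$times), max(x$times), x$channel))
  invisible(x)
}

#' Write / read a time-lapse stack
#'
#' Stacks are written as multi-page 16-bit unsigned TIFF (one page per
#' timepoint, pages in time order; intensities rounded and clamped to
#' 0..65535) with a JSON sidecar `<path>.json` holding `frame_interval_min`,
#' `time_start_min` and `channel`. Reading restores the times from the
#' sidecar, or from `frame_interval` when no sidecar exists. 16-bit
#' integer-valued data round-trips losslessly.
#'
#' @param stack A `timelapse_stack`.
#' @param path TIFF file path.
#' @return `write_stack()`: the path, invisibly. `read_stack()`: a
#'   `timelapse_stack` (without ROIs; see [read_rois()]).
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "timelapse_stack"))
  d <- dim(stack$frames)
  pages <- lapply(seq_len(d[1]), function(i) {
    m <- round(stack$frames[i, , , drop = TRUE])
    m[m < 0] <- 0; m[m > 65535] <- 65535
    m / 65535
  })
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  stop_if(ok != d[1], sprintf("failed to write %d pages to '%s'", d[1], path))
  dt <- unique(round(diff(stack$times), 9))
  sidecar <- list(frame_interval_min = dt[1], time_start_min = stack$times[1],
                  n_frames = d[1], channel = stack$channel)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @param frame_interval Frame interval (min) used when no JSON sidecar is
#'   present.
#' @export
read_stack <- function(path, frame_interval = NULL) {
  stop_if(!file.exists(path), sprintf("stack file '%s' does not exist", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stop_if(length(pages) < 2,
          sprintf("'%s' has %d page(s); a time-lapse needs at least 2",
                  path, length(pages)))
  sidecar_path <- paste0(path, ".json")
  t0 <- 0; channel <- "fluorescence"
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    frame_interval <- sc$frame_interval_min
    if (!is.null(sc$time_start_min)) t0 <- sc$time_start_min
    if (!is.null(sc$channel)) channel <- sc$channel
  }
  stop_if(is.null(frame_interval),
          sprintf("no timing sidecar '%s'; supply `frame_interval`",
                  sidecar_path))
  check_positive(frame_interval, "frame_interval")
  n <- length(pages)
  frames <- array(0, dim = c(n, nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_len(n)) frames[i, , ] <- pages[[i]]
  structure(list(frames = frames,
                 times = t0 + frame_interval * (seq_len(n) - 1),
                 channel = channel, rois = NULL),
            class = "timelapse_stack")
}

#' Write / read an ROI definition file
#'
#' JSON file of named rectangles `[row_start, row_stop, col_start,
#' col_stop]`, 0-based, half-open.
#'
#' @param rois A [roi_set()].
#' @param path JSON file path.
#' @return `write_rois()`: the path, invisibly. `read_rois()`: a
#'   [roi_set()].
#' @export
write_rois <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  jsonlite::write_json(unclass(rois), path, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  stop_if(!file.exists(path), sprintf("ROI file '%s' does not exist", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stop_if(!all(c("outer", "central", "background") %in% names(x)),
          "ROI file must define outer, central and background regions")
  roi_set(x$outer, x$central, x$background)
}
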