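# ROI quantification: per-frame sum intensities and the background
# significance check.

#' Extract per-frame ROI sum-intensity traces
#'
#' Sums pixel intensities over the outer, central and background regions of
#' every frame. The raw background sum is reported but not subtracted by
#' default, matching the assay's use of the background ROI as a
#' significance check only; see `background_subtract`.
#'
#' @param stack A `timelapse_stack`.
#' @param rois A [roi_set()]; defaults to the ROIs carried by the stack.
#' @param background_subtract If `TRUE`, subtract the per-pixel background
#'   mean times the region pixel count from the outer and central sums,
#'   flooring at 0.
#' @return A tibble of class `intensity_trace` with columns `time_min`,
#'   `s_outer`, `s_central`, `s_background`, `n_px_outer`, `n_px_central`,
#'   `n_px_background`.
#' @export
extract_traces <- function(stack, rois = NULL, background_subtract = FALSE) {
  stopifnot(inherits(stack, "timelapse_stack"))
  if (is.null(rois)) rois <- stack$rois
  stop_if(is.null(rois), "no ROIs supplied and none stored with the stack")
  stopifnot(inherits(rois, "roi_set"))
  d <- dim(stack$frames)
  validate_rois_in_frame(rois, d[2:3])

  roi_sum <- function(r) {
    apply(stack$frames[, roi_rows(r), roi_cols(r), drop = FALSE], 1, sum)
  }
  out <- tibble::tibble(
    time_min = stack$times,
    s_outer = roi_sum(rois$outer),
    s_central = roi_sum(rois$central),
    s_background = roi_sum(rois$background),
    n_px_outer = roi_pixel_count(rois$outer),
    n_px_central = roi_pixel_count(rois$central),
    n_px_background = roi_pixel_count(rois$background))
  if (background_subtract) {
    bg_per_px <- out$s_background / out$n_px_background
    out$s_outer <- pmax(out$s_outer - bg_per_px * out$n_px_outer, 0)
    out$s_central <- pmax(out$s_central - bg_per_px * out$n_px_central, 0)
  }
  class(out) <- c("intensity_trace", class(out))
  out
}

#' Background significance assessment
#'
#' Checks that each compartment's signal is significant relative to the
#' background ROI. Intensities are normalized per pixel (regions need not be
#' equal-sized). A compartment PASSes iff its per-pixel mean over the final
#' quartile of frames strictly exceeds the background per-pixel mean plus
#' `k_sd` background per-pixel standard deviations (both taken over all
#' frames). A zero-variance background with equal means is flagged
#' indeterminate rather than failed.
#'
#' @param trace An `intensity_trace` tibble (from [extract_traces()] or read
#'   from CSV with the same columns).
#' @param k_sd Significance multiplier (default 3).
#' @return A tibble with one row per compartment: `compartment`,
#'   `signal_mean` (per-pixel, final quartile), `background_mean`,
#'   `background_sd`, `margin` (signal - threshold), `pass`,
#'   `indeterminate`.
#' @export
background_assessment <- function(trace, k_sd = 3) {
  trace <- validate_trace(trace)
  n <- nrow(trace)
  last_q <- seq.int(max(1L, n - floor(n / 4) + 1L), n)

  bg <- trace$s_background / trace$n_px_background
  bg_mean <- mean(bg)
  bg_sd <- sd(bg)
  threshold <- bg_mean + k_sd * bg_sd

  one <- function(label, s, n_px) {
    sig <- mean(s[last_q] / n_px)
    indeterminate <- bg_sd == 0 && sig == bg_mean
    tibble::tibble(compartment = label, signal_mean = sig,
                   background_mean = bg_mean, background_sd = bg_sd,
                   margin = sig - threshold,
                   pass = !indeterminate && sig > threshold,
                   indeterminate = indeterminate)
  }
  dplyr::bind_rows(
    one("outer", trace$s_outer, trace$n_px_outer[1]),
    one("central", trace$s_central, trace$n_px_central[1]))
}

validate_trace <- function(trace) {
  need <- c("time_min", "s_outer", "s_central", "s_background")
  stop_if(!is.data.frame(trace) || !all(need %in% names(trace)),
          paste("trace must contain columns", paste(need, collapse = ", ")))
  stop_if(nrow(trace) < 2, "trace must have at least 2 frames")
  stop_if(any(diff(trace$time_min) <= 0), "times must be strictly increasing")
  for (col in c("n_px_outer", "n_px_central", "n_px_background"))
    if (!col %in% names(trace)) trace[[col]] <- 1L
  trace
}
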