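# Uptake kinetics: the ratio series, linear-zone selection, and the k_in
# estimator.
#
# The unidirectional uptake transfer constant k_in is the slope of
#
#   (C_CC + C_PF) / C_PF = k_in * t + O_C
#
# fitted by ordinary least squares over the linear uptake zone, where C_CC
# and C_PF are the per-frame ROI sum intensities of the central and outer
# compartments and O_C is the extrapolated intercept. k_in is a relative
# rate in 1/min (conventionally displayed x 10^-3).

#' Build the uptake ratio series
#'
#' Computes `y(t) = (s_central(t) + s_outer(t)) / s_outer(t)` per frame,
#' after optional background subtraction. Frames with `s_outer <= 0`
#' (possible after subtraction) are dropped, never clamped; dropped times
#' are recorded in attribute `excluded`.
#'
#' @param trace An `intensity_trace` tibble (columns `time_min`, `s_outer`,
#'   `s_central`, `s_background`; pixel-count columns required for
#'   `background_mode = "subtract"`). A `concentration_traces` tibble from
#'   [simulate_transport()] is also accepted (concentrations are used
#'   directly as noiseless sum intensities).
#' @param background_mode `"none"` (default; the assay does not subtract
#'   background before kinetic analysis) or `"subtract"` (per-pixel
#'   background mean times region pixel count, floored at 0).
#' @return A tibble of class `ratio_series` with columns `time_min`, `y`.
#' @examples
#' tr <- simulate_transport(default_geometry(),
#'                          condition_preset("BBB", "free_trd"),
#'                          tracer_preset("free_trd"), perfusion_protocol())
#' head(ratio_series(tr))
#' @export
ratio_series <- function(trace, background_mode = c("none", "subtract")) {
  background_mode <- match.arg(background_mode)
  if (inherits(trace, "concentration_traces"))
    trace <- tibble::tibble(time_min = trace$time_min,
                            s_outer = trace$outer_conc,
                            s_central = trace$central_conc,
                            s_background = 0)
  trace <- validate_trace(trace)
  s_outer <- trace$s_outer
  s_central <- trace$s_central
  if (background_mode == "subtract") {
    bg_per_px <- trace$s_background / trace$n_px_background
    s_outer <- s_outer - bg_per_px * trace$n_px_outer
    s_central <- pmax(s_central - bg_per_px * trace$n_px_central, 0)
  }
  usable <- is.finite(s_outer) & is.finite(s_central) & s_outer > 0
  stop_if(sum(usable) < 3,
          sprintf("only %d frames with positive outer signal; need >= 3",
                  sum(usable)))
  out <- tibble::tibble(time_min = trace$time_min[usable],
                        y = (s_central[usable] + s_outer[usable]) /
                          s_outer[usable])
  attr(out, "excluded") <- trace$time_min[!usable]
  class(out) <- c("ratio_series", class(out))
  out
}

#' Select the linear uptake zone
#'
#' `method = "full"` returns the whole series (the default analysis; uptake
#' under tight barriers stays linear over the full perfusion). For
#' saturating conditions (cell-free chips, efflux-inhibited runs),
#' `method = "auto"` searches all windows starting at the first frame with
#' at least `min_points` frames and returns the one whose ordinary
#' least-squares fit maximizes adjusted R-squared, preferring the longest
#' window on ties.
#'
#' @param series A `ratio_series` tibble.
#' @param method `"full"` or `"auto"`.
#' @param min_points Minimum window length (frames).
#' @return Integer vector `c(first, last)` of window frame indices.
#' @export
linear_zone <- function(series, method = c("full", "auto"), min_points = 10) {
  method <- match.arg(method)
  stopifnot(inherits(series, "ratio_series"))
  n <- nrow(series)
  stop_if(n < min_points,
          sprintf("series has %d frames; need >= min_points = %d",
                  n, min_points))
  if (method == "full") return(c(1L, n))

  t <- series$time_min; y <- series$y
  best_end <- n; best_r2 <- -Inf
  for (end in seq.int(min_points, n)) {
    r2 <- adj_r_squared(t[1:end], y[1:end])
    if (is.nan(r2)) r2 <- -Inf          # zero-variance y: no linear signal
    # strict improvement wins; ties go to the longer window
    tie <- (r2 == best_r2) ||
      (is.finite(r2) && is.finite(best_r2) && abs(r2 - best_r2) <= 1e-12)
    if (tie) {
      best_end <- end
    } else if (r2 > best_r2) {
      best_r2 <- r2; best_end <- end
    }
  }
  if (!is.finite(best_r2)) best_end <- n  # flat series: keep everything
  c(1L, best_end)
}

adj_r_squared <- function(t, y) {
  n <- length(t)
  fit <- ols_line(t, y)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NaN)
  r2 <- 1 - fit$sse / sst
  1 - (1 - r2) * (n - 1) / (n - 2)
}

# closed-form simple linear regression; returned sse/sxx reused by fit_kin
ols_line <- function(t, y) {
  n <- length(t)
  tbar <- mean(t); ybar <- mean(y)
  sxx <- sum((t - tbar)^2)
  slope <- sum((t - tbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * tbar
  resid <- y - intercept - slope * t
  list(slope = slope, intercept = intercept, sse = sum(resid^2),
       sxx = sxx, n = n)
}

#' Fit the uptake transfer constant k_in
#'
#' Ordinary least squares of the ratio series on time over the fitting
#' window: `k_in` is the slope (1/min), `o_c` the intercept. Standard
#' errors and R-squared are reported; R-squared is `NA` for a constant
#' series (zero total variation).
#'
#' @param series A `ratio_series` tibble (or an `intensity_trace` /
#'   `concentration_traces`, converted via [ratio_series()] with default
#'   background mode).
#' @param window Integer `c(first, last)` frame window; default the window
#'   chosen by [linear_zone()] with `zone`.
#' @param zone Passed to [linear_zone()] when `window` is `NULL`.
#' @param min_points Passed to [linear_zone()].
#' @return An object of class `kin_fit`.
#' @examples
#' tr <- simulate_transport(default_geometry(),
#'                          condition_preset("BBB", "free_trd"),
#'                          tracer_preset("free_trd"), perfusion_protocol())
#' fit <- fit_kin(ratio_series(tr))
#' glance(fit)
#' @export
fit_kin <- function(series, window = NULL, zone = c("full", "auto"),
                    min_points = 10) {
  if (!inherits(series, "ratio_series")) series <- ratio_series(series)
  if (is.null(window)) window <- linear_zone(series, match.arg(zone),
                                             min_points)
  stop_if(length(window) != 2 || window[1] < 1 || window[2] > nrow(series) ||
            window[2] < window[1], "invalid fitting window")
  idx <- seq.int(window[1], window[2])
  stop_if(length(idx) < 3, "fitting window must contain at least 3 points")
  t <- series$time_min[idx]; y <- series$y[idx]
  stop_if(var(t) == 0, "zero time-variance in fitting window")

  f <- ols_line(t, y)
  dfree <- f$n - 2
  sigma2 <- if (dfree > 0) f$sse / dfree else NA_real_
  se_slope <- sqrt(sigma2 / f$sxx)
  se_intercept <- sqrt(sigma2 * (1 / f$n + mean(t)^2 / f$sxx))
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - f$sse / sst

  structure(
    list(k_in = f$slope, o_c = f$intercept, se_k_in = se_slope,
         se_o_c = se_intercept, r_squared = r2,
         window = c(first = window[1], last = window[2]),
         n_points = f$n, series = series),
    class = "kin_fit")
}

#' @export
print.kin_fit <- function(x, ...) {
  cat("<kin_fit>\n")
  cat(sprintf("  k_in = %.3f x 10^-3 /min (SE %.3f), O_C = %.4f\n",
              x$k_in * 1e3, x$se_k_in * 1e3, x$o_c))
  cat(sprintf("  R^2 = %s over frames %d..%d (%d points)\n",
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
              x$window[1], x$window[2], x$n_points))
  invisible(x)
}

#' Tidiers for `kin_fit` objects
#'
#' `tidy()` returns one row per regression term; `glance()` returns a
#' one-row model summary (with `k_in` on both the natural and the
#' display (x 10^3) scale).
#'
#' @param x A `kin_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy kin_fit
#' @export
tidy.kin_fit <- function(x, ...) {
  tibble::tibble(term = c("o_c", "k_in"),
                 estimate = c(x$o_c, x$k_in),
                 std.error = c(x$se_o_c, x$se_k_in))
}

#' @rdname tidy.kin_fit
#' @method glance kin_fit
#' @export
glance.kin_fit <- function(x, ...) {
  tibble::tibble(k_in = x$k_in, k_in_milli = x$k_in * 1e3,
                 se_k_in = x$se_k_in, o_c = x$o_c,
                 r_squared = x$r_squared, n_points = x$n_points,
                 window_first = x$window[1], window_last = x$window[2])
}

#' Fit k_in for every chip in a long trace table
#'
#' Convenience wrapper for cohort analysis: groups a long table of traces
#' by chip, builds each ratio series and fits k_in.
#'
#' @param traces Tibble with columns `chip_id`, `group`, `time_min`,
#'   `s_outer`, `s_central`, `s_background` (plus optional pixel counts).
#' @param zone,min_points,background_mode Passed to [ratio_series()] /
#'   [fit_kin()].
#' @return A tibble with one row per chip: `chip_id`, `group`, `k_in`,
#'   `k_in_milli`, `se_k_in`, `o_c`, `r_squared`, `window_first`,
#'   `window_last`, `n_frames_used`.
#' @export
fit_cohort <- function(traces, zone = c("full", "auto"), min_points = 10,
                       background_mode = c("none", "subtract")) {
  zone <- match.arg(zone)
  background_mode <- match.arg(background_mode)
  stop_if(!all(c("chip_id", "group") %in% names(traces)),
          "`traces` must contain chip_id and group columns")
  traces |>
    dplyr::group_by(.data$chip_id, .data$group) |>
    dplyr::group_modify(function(df, key) {
      fit <- fit_kin(ratio_series(df, background_mode), zone = zone,
                     min_points = min_points)
      g <- glance(fit)
      tibble::tibble(k_in = g$k_in, k_in_milli = g$k_in_milli,
                     se_k_in = g$se_k_in, o_c = g$o_c,
                     r_squared = g$r_squared,
                     window_first = g$window_first,
                     window_last = g$window_last,
                     n_frames_used = g$n_points)
    }) |>
    dplyr::ungroup()
}
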