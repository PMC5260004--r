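# ggplot2 graphics for traces, fits and group comparisons.

#' Plot intensity or concentration traces
#'
#' @param trace An `intensity_trace` or `concentration_traces` tibble.
#' @return A ggplot.
#' @export
plot_traces <- function(trace) {
  if (inherits(trace, "concentration_traces")) {
    long <- tidyr::pivot_longer(
      tibble::as_tibble(trace)[, c("time_min", "outer_conc", "central_conc")],
      -"time_min", names_to = "compartment", values_to = "value")
    ylab <- "concentration (au)"
  } else {
    trace <- validate_trace(trace)
    long <- tidyr::pivot_longer(
      tibble::as_tibble(trace)[, c("time_min", "s_outer", "s_central",
                                   "s_background")],
      -"time_min", names_to = "compartment", values_to = "value")
    ylab <- "ROI sum intensity (au)"
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$value,
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot a fitted ratio series
#'
#' Ratio series with the fitted line; the fitting window is shaded.
#'
#' @param object A `kin_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kin_fit
#' @export
autoplot.kin_fit <- function(object, ...) {
  s <- object$series
  win <- s$time_min[object$window]
  ggplot2::ggplot(s, ggplot2::aes(.data$time_min, .data$y)) +
    ggplot2::annotate("rect", xmin = win[1], xmax = win[2], ymin = -Inf,
                      ymax = Inf, alpha = 0.1, fill = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_abline(intercept = object$o_c, slope = object$k_in,
                         colour = "firebrick") +
    ggplot2::labs(x = "time (min)",
                  y = "(C_CC + C_PF) / C_PF",
                  subtitle = sprintf("k_in = %.2f x 10^-3 /min, O_C = %.3f",
                                     object$k_in * 1e3, object$o_c)) +
    ggplot2::theme_minimal()
}

#' Plot group means with SEM error bars
#'
#' Group means +/- SEM on the conventional x 10^-3 display scale.
#'
#' @param object A `kin_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kin_comparison
#' @export
autoplot.kin_comparison <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(.data$label, .data$mean * 1e3)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = (.data$mean - .data$sem) * 1e3,
      ymax = (.data$mean + .data$sem) * 1e3), width = 0.2) +
    ggplot2::labs(x = NULL, y = "k_in (x 10^-3 / min)") +
    ggplot2::theme_minimal()
}
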