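# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the full suite runs quickly.

small_imaging <- function(...) {
  imaging_model(frame_shape = c(32, 48), ...)
}

short_protocol <- function(duration = 20, frame_interval = 2, ...) {
  perfusion_protocol(duration = duration, frame_interval = frame_interval,
                     ...)
}

# constant-lumen simulation: huge perfusion rate pins the outer channel at
# the inlet concentration almost instantly
constant_lumen_traces <- function(condition, tracer = tracer_preset("free_trd"),
                                  geometry = default_geometry(),
                                  protocol = perfusion_protocol()) {
  protocol$flow_rate <- 1e4   # uL/min; fill time V_PF/Q = 2e-5 min
  simulate_transport(geometry, condition, tracer, protocol,
                     outer_conc0 = tracer$inlet_concentration)
}

# hand-built intensity trace
make_trace <- function(time_min, s_outer, s_central, s_background = 0,
                       n_px = c(1L, 1L, 1L)) {
  structure(
    tibble::tibble(time_min = time_min, s_outer = s_outer,
                   s_central = s_central, s_background = s_background,
                   n_px_outer = n_px[1], n_px_central = n_px[2],
                   n_px_background = n_px[3]),
    class = c("intensity_trace", class(tibble::tibble())))
}

# independent OLS via the normal equations (QR-free, textbook form)
normal_equation_ols <- function(t, y) {
  X <- cbind(1, t)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}
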