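# Mechanistic two-compartment transport model.
#
# State (concentrations, au): C_PF in the outer perfused channel, C_CC in
# the central compartment. With Q the perfusion rate (nL/min), C_in the
# syringe concentration, PS the passive exchange coefficient, and
# E = CL_eff * (1 - I) the effective efflux clearance (substrates only):
#
#   dC_PF/dt = (Q/V_PF) (C_in - C_PF) - (PS/V_PF) (C_PF - C_CC) + (E/V_PF) C_CC
#   dC_CC/dt = (PS/V_CC) (C_PF - C_CC) - (E/V_CC) C_CC
#
# Both compartments are treated as well mixed; the measured quantity is an
# ROI sum, which integrates over space.

#' Simulate tracer transport across the barrier chip
#'
#' Integrates the two-compartment mass-balance model (see Details) with
#' `deSolve::lsoda` at absolute/relative tolerance 1e-10 and samples the
#' solution at the protocol's frame times. Deterministic given its inputs.
#'
#' @details The outer channel receives tracer by perfusion (a concentration
#' step `C_in` at t = 0) and exchanges passively with the central
#' compartment through the porous interface at rate PS. For efflux
#' substrates, a linear clearance `E = CL_eff * (1 - I)` pumps tracer from
#' the central compartment back to the lumen; for non-substrates efflux has
#' no effect. Both initial concentrations default to 0.
#'
#' @param geometry A [chip_geometry()].
#' @param condition A [barrier_condition()].
#' @param tracer A [tracer()].
#' @param protocol A [perfusion_protocol()].
#' @param outer_conc0 Initial outer-channel concentration, au (default 0;
#'   set to the inlet concentration to start from a pre-filled lumen).
#' @return A tibble of class `concentration_traces` with columns `time_min`,
#'   `outer_conc`, `central_conc` (au) and the model parameters stored in
#'   attribute `params`.
#' @examples
#' tr <- simulate_transport(default_geometry(),
#'                          condition_preset("BBB", "free_trd"),
#'                          tracer_preset("free_trd"),
#'                          perfusion_protocol())
#' head(tr)
#' @export
simulate_transport <- function(geometry, condition, tracer, protocol,
                               outer_conc0 = 0) {
  stopifnot(inherits(geometry, "chip_geometry"),
            inherits(condition, "barrier_condition"),
            inherits(tracer, "tracer"),
            inherits(protocol, "perfusion_protocol"))
  check_non_negative(outer_conc0, "outer_conc0")

  v_pf <- geometry$outer_volume
  v_cc <- geometry$central_volume
  q <- protocol$flow_rate * 1000            # uL/min -> nL/min
  ps <- condition$ps_product
  eff <- if (tracer$efflux_substrate)
    condition$efflux_clearance * (1 - condition$inhibition_fraction) else 0
  c_in <- tracer$inlet_concentration
  times <- frame_times(protocol)

  rhs <- function(t, y, p) {
    list(c(
      (q * (c_in - y[1]) - ps * (y[1] - y[2]) + eff * y[2]) / v_pf,
      (ps * (y[1] - y[2]) - eff * y[2]) / v_cc))
  }
  sol <- deSolve::lsoda(c(outer_conc0, 0), times, rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf(paste0("transport solver failed to converge ",
                        "(PS = %g, CL_eff = %g, I = %g, Q = %g nL/min)"),
                 ps, eff, condition$inhibition_fraction, q), call. = FALSE)
  conc <- unname(sol[, 2:3, drop = FALSE])
  if (any(conc < -1e-8))
    stop(sprintf(paste0("transport solver produced negative concentrations ",
                        "beyond tolerance (min %.3g; PS = %g, CL_eff = %g)"),
                 min(conc), ps, eff), call. = FALSE)
  conc[conc < 0] <- 0

  out <- tibble::tibble(time_min = times,
                        outer_conc = conc[, 1],
                        central_conc = conc[, 2])
  attr(out, "params") <- list(geometry = geometry, condition = condition,
                              tracer = tracer, protocol = protocol,
                              effective_efflux = eff)
  class(out) <- c("concentration_traces", class(out))
  out
}

#' Closed-form central-compartment concentration (constant-lumen limit)
#'
#' Analytic solution of the central-compartment balance when the lumen is
#' held at the inlet concentration (the high-flow limit):
#' `C_CC(t) = C_in * PS/(PS + E) * (1 - exp(-(PS + E) t / V_CC))` with
#' `E = CL_eff * (1 - I)`. By convention returns 0 for all t when
#' `PS = E = 0`.
#'
#' @param ps_product PS, nL/min.
#' @param efflux_clearance CL_eff, nL/min.
#' @param inhibition_fraction I in \[0, 1\].
#' @param central_volume V_CC, nL.
#' @param inlet_concentration C_in, au.
#' @param t Time(s), min.
#' @return Central concentration(s), au.
#' @examples
#' closed_form_central(0.5, 0, 0, 200, 100, c(0, 45, 90))
#' @export
closed_form_central <- function(ps_product, efflux_clearance = 0,
                                inhibition_fraction = 0, central_volume,
                                inlet_concentration, t) {
  check_non_negative(ps_product, "ps_product")
  check_non_negative(efflux_clearance, "efflux_clearance")
  stop_if(inhibition_fraction < 0 || inhibition_fraction > 1,
          "`inhibition_fraction` must be in [0, 1]")
  check_positive(central_volume, "central_volume")
  check_non_negative(inlet_concentration, "inlet_concentration")
  stop_if(any(t < 0), "`t` must be non-negative")
  eff <- efflux_clearance * (1 - inhibition_fraction)
  k <- ps_product + eff
  if (k == 0) return(rep(0, length(t)))
  inlet_concentration * ps_product / k * (1 - exp(-k * t / central_volume))
}
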