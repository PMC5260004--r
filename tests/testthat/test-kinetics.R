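times <- seq(0, 90, by = 2)

test_that("ratio series algebraic identities hold", {
  # no central signal -> y = 1
  tr <- make_trace(times, s_outer = rep(10, 46), s_central = rep(0, 46))
  expect_equal(ratio_series(tr)$y, rep(1, 46))
  # central equals outer -> y = 2
  tr <- make_trace(times, s_outer = rep(10, 46), s_central = rep(10, 46))
  expect_equal(ratio_series(tr)$y, rep(2, 46))
  # s_central = c * (a t) over constant s_outer = c -> y = 1 + a t exactly
  a <- 0.0025; c0 <- 7
  tr <- make_trace(times, s_outer = rep(c0, 46), s_central = c0 * a * times)
  expect_equal(ratio_series(tr)$y, 1 + a * times, tolerance = 1e-15)
})

test_that("frames without positive outer signal are dropped, not clamped", {
  s_outer <- c(0, -1, rep(5, 8))
  tr <- make_trace(seq(0, 18, by = 2), s_outer = s_outer,
                   s_central = rep(1, 10))
  rs <- ratio_series(tr)
  expect_equal(nrow(rs), 8)
  expect_equal(attr(rs, "excluded"), c(0, 2))
  # fewer than 3 usable frames is an error
  tr_bad <- make_trace(c(0, 2, 4), s_outer = c(0, 0, 1),
                       s_central = c(0, 0, 1))
  expect_error(ratio_series(tr_bad), "positive outer signal")
})

test_that("background subtraction feeds the ratio correctly", {
  # outer 12, central 7, background 2 per pixel, equal 1-px regions
  tr <- make_trace(times, s_outer = rep(12, 46), s_central = rep(7, 46),
                   s_background = rep(2, 46))
  rs <- ratio_series(tr, background_mode = "subtract")
  expect_equal(rs$y, rep((5 + 10) / 10, 46))
})

test_that("y, k_in and O_C are invariant under common rescaling", {
  set.seed(7)
  s_outer <- 100 + rnorm(46)
  s_central <- 5 + 0.3 * times + rnorm(46, sd = 0.2)
  tr1 <- make_trace(times, s_outer, s_central)
  tr2 <- make_trace(times, 137.5 * s_outer, 137.5 * s_central)
  rs1 <- ratio_series(tr1); rs2 <- ratio_series(tr2)
  expect_equal(rs1$y, rs2$y, tolerance = 1e-12)
  f1 <- fit_kin(rs1); f2 <- fit_kin(rs2)
  expect_equal(f1$k_in, f2$k_in, tolerance = 1e-12)
  expect_equal(f1$o_c, f2$o_c, tolerance = 1e-12)
})

test_that("an exact line is recovered to machine precision", {
  rs <- ratio_series(make_trace(times, rep(4, 46), 4 * 0.0025 * times))
  fit <- fit_kin(rs)  # default zone: full series
  expect_equal(fit$k_in, 2.5e-3, tolerance = 1e-12)
  expect_equal(fit$o_c, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(fit$window), c(1, 46))
  # exactly linear series: auto selects the full window (all ties at R2 = 1)
  expect_equal(linear_zone(rs, "auto"), c(1L, 46L))
})

test_that("a constant series has zero slope and undefined R-squared", {
  rs <- ratio_series(make_trace(times, rep(4, 46), rep(2, 46)))
  fit <- fit_kin(rs)
  expect_equal(fit$k_in, 0)
  expect_true(is.na(fit$r_squared))
})

test_that("OLS agrees with an independent normal-equation oracle", {
  set.seed(8)
  for (rep in 1:5) {
    y <- 1 + 0.002 * times + rnorm(46, sd = 0.01)
    tr <- make_trace(times, rep(1, 46), y - 1)
    fit <- fit_kin(ratio_series(tr))
    oracle <- normal_equation_ols(times, y)
    expect_equal(fit$k_in, unname(oracle["slope"]), tolerance = 1e-10)
    expect_equal(fit$o_c, unname(oracle["intercept"]), tolerance = 1e-10)
    # standard errors and R2 against stats::lm
    lmfit <- summary(lm(y ~ times))
    expect_equal(fit$se_k_in, lmfit$coefficients["times", "Std. Error"],
                 tolerance = 1e-10)
    expect_equal(fit$r_squared, lmfit$r.squared, tolerance = 1e-10)
  }
})

test_that("auto zone finds the bend of a linear-then-flat series", {
  # linear for 20 frames, then saturated flat
  y <- c(1 + 0.005 * times[1:20], rep(1 + 0.005 * times[20], 26))
  rs <- ratio_series(make_trace(times, rep(1, 46), y - 1))
  win <- linear_zone(rs, "auto")
  # oracle: exhaustive search over end frames with stats::lm, using the
  # documented tie rule (longest window within 1e-12 of the maximum)
  adj <- vapply(10:46, function(end) {
    suppressWarnings(summary(lm(y[1:end] ~ times[1:end]))$adj.r.squared)
  }, 1.0)
  oracle_end <- max((10:46)[adj >= max(adj) - 1e-12])
  expect_equal(win[1], 1L)
  expect_lte(abs(win[2] - oracle_end), 2)
  expect_lt(win[2], 25)   # well before the flat tail ends
})

test_that("window validation errors are raised", {
  short <- ratio_series(make_trace(seq(0, 8, by = 2), rep(1, 5),
                                   0.01 * seq(0, 8, by = 2)))
  expect_error(linear_zone(short, "auto", min_points = 10), "min_points")
  rs <- ratio_series(make_trace(times, rep(1, 46), 0.001 * times))
  expect_error(fit_kin(rs, window = c(1, 2)), "at least 3")
  expect_error(fit_kin(rs, window = c(1, 100)), "invalid")
})

test_that("early-window fits recover PS / V_CC in the constant-lumen limit", {
  geom <- default_geometry()
  for (ps in c(0.2, 0.5, 1)) {
    cnd <- barrier_condition("BBB", ps)
    tr <- constant_lumen_traces(cnd)
    fit <- fit_kin(ratio_series(tr), window = c(1, 10))
    expect_equal(fit$k_in, ps / geom$central_volume, tolerance = 0.05)
  }
})

test_that("efflux inhibition strictly increases fitted k_in", {
  geom <- default_geometry()
  rho <- tracer_preset("rho123")
  prot <- perfusion_protocol()
  for (zone in c("full", "auto")) {
    fits <- vapply(c(0, 1), function(inh) {
      cnd <- barrier_condition("BBB", 2.94, efflux_clearance = 155.6,
                               inhibition_fraction = inh)
      tr <- simulate_transport(geom, cnd, rho, prot,
                               outer_conc0 = rho$inlet_concentration)
      fit_kin(ratio_series(tr), zone = zone)$k_in
    }, 1.0)
    expect_gt(fits[2], fits[1])
  }
})

test_that("fit_cohort returns one tidy row per chip", {
  traces <- dplyr::bind_rows(
    dplyr::mutate(make_trace(times, rep(2, 46), 2 * 0.001 * times),
                  chip_id = "a", group = "g1"),
    dplyr::mutate(make_trace(times, rep(2, 46), 2 * 0.004 * times),
                  chip_id = "b", group = "g2"))
  est <- fit_cohort(traces)
  expect_equal(nrow(est), 2)
  expect_equal(est$k_in[est$chip_id == "a"], 0.001, tolerance = 1e-10)
  expect_equal(est$k_in[est$chip_id == "b"], 0.004, tolerance = 1e-10)
  expect_equal(est$k_in_milli, est$k_in * 1e3)
})

test_that("tidy and glance return the documented shapes", {
  fit <- fit_kin(ratio_series(make_trace(times, rep(1, 46),
                                         0.002 * times)))
  td <- tidy(fit)
  expect_equal(td$term, c("o_c", "k_in"))
  gl <- glance(fit)
  expect_equal(gl$k_in_milli, gl$k_in * 1e3)
  expect_s3_class(autoplot(fit), "ggplot")
})
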