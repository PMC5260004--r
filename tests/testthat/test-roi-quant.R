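make_stack <- function(frames, times = seq(0, by = 2,
                                           length.out = dim(frames)[1]),
                       rois = roi_layout(dim(frames)[2:3])) {
  structure(list(frames = frames, times = times, channel = "fluorescence",
                 rois = rois), class = "timelapse_stack")
}

test_that("region sums are exact on constant frames", {
  frames <- array(3, dim = c(4, 32, 48))
  st <- make_stack(frames)
  q <- extract_traces(st)
  expect_equal(q$s_outer, rep(3 * q$n_px_outer[1], 4))
  expect_equal(q$s_central, rep(3 * q$n_px_central[1], 4))
  expect_equal(q$s_background, rep(3 * q$n_px_background[1], 4))
})

test_that("a single-pixel region reproduces that pixel's time series", {
  set.seed(4)
  frames <- array(runif(5 * 32 * 48), dim = c(5, 32, 48))
  rois <- roi_set(outer = c(2, 3, 2, 3), central = c(10, 11, 10, 11),
                  background = c(20, 21, 20, 21))
  q <- extract_traces(make_stack(frames, rois = rois))
  expect_equal(q$s_outer, frames[, 3, 3])
  expect_equal(q$s_central, frames[, 11, 11])
  expect_equal(q$n_px_outer[1], 1)
})

test_that("sum extraction is linear in the stack", {
  set.seed(5)
  f1 <- array(runif(3 * 32 * 48), dim = c(3, 32, 48))
  f2 <- array(runif(3 * 32 * 48), dim = c(3, 32, 48))
  a <- 2.5; b <- 0.7
  qa <- extract_traces(make_stack(f1))
  qb <- extract_traces(make_stack(f2))
  qc <- extract_traces(make_stack(a * f1 + b * f2))
  for (col in c("s_outer", "s_central", "s_background"))
    expect_equal(qc[[col]], a * qa[[col]] + b * qb[[col]], tolerance = 1e-12)
})

test_that("out-of-bounds regions are rejected", {
  frames <- array(1, dim = c(3, 32, 48))
  bad <- roi_set(outer = c(0, 40, 0, 8), central = c(41, 45, 0, 8),
                 background = c(46, 48, 0, 8))
  expect_error(extract_traces(make_stack(frames, rois = bad)), "exceeds")
})

test_that("background subtraction floors at zero", {
  frames <- array(2, dim = c(3, 32, 48))
  st <- make_stack(frames)
  q <- extract_traces(st, background_subtract = TRUE)
  expect_equal(q$s_outer, rep(0, 3))   # signal equals background level
  expect_equal(q$s_central, rep(0, 3))
})

test_that("background assessment passes strong signal and fails equal signal", {
  set.seed(6)
  n <- 20
  bg <- 100 + rnorm(n)
  # signal identical to background -> FAIL
  tr <- make_trace(seq(0, by = 2, length.out = n), s_outer = bg,
                   s_central = bg, s_background = bg)
  rep1 <- background_assessment(tr)
  expect_false(any(rep1$pass))
  expect_false(any(rep1$indeterminate))
  # signal far above background -> PASS
  tr2 <- make_trace(seq(0, by = 2, length.out = n),
                    s_outer = bg + 100 * sd(bg),
                    s_central = bg + 100 * sd(bg), s_background = bg)
  expect_true(all(background_assessment(tr2)$pass))
})

test_that("the significance threshold is strict at mean + 3 SD", {
  # constructed background with exact mean 10 and SD 1
  bg <- c(9, 11, 9, 11, 9, 11, 9, 11)
  stopifnot(abs(mean(bg) - 10) < 1e-12, abs(sd(bg) - 1.0690) < 1e-3)
  thr <- mean(bg) + 3 * sd(bg)
  tr <- make_trace(seq(0, by = 2, length.out = 8),
                   s_outer = rep(thr, 8),          # exactly at threshold
                   s_central = rep(thr + 1e-9, 8), # just above
                   s_background = bg)
  rep <- background_assessment(tr, k_sd = 3)
  expect_false(rep$pass[rep$compartment == "outer"])
  expect_true(rep$pass[rep$compartment == "central"])
})

test_that("zero background variance with equal means is indeterminate", {
  tr <- make_trace(seq(0, by = 2, length.out = 8), s_outer = rep(5, 8),
                   s_central = rep(5, 8), s_background = rep(5, 8))
  rep <- background_assessment(tr)
  expect_true(all(rep$indeterminate))
  expect_false(any(rep$pass))
})

test_that("per-pixel normalization handles unequal region sizes", {
  # background region twice the compartment size, same per-pixel intensity
  tr <- make_trace(seq(0, by = 2, length.out = 8),
                   s_outer = rep(50, 8), s_central = rep(50, 8),
                   s_background = rep(100 + c(-1, 1), 4) * 2,
                   n_px = c(10L, 10L, 20L))
  rep <- background_assessment(tr)
  # per pixel: signal 5, background ~10 -> clearly not significant
  expect_false(any(rep$pass))
  expect_equal(rep$signal_mean, c(5, 5))
})
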