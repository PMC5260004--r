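geom <- default_geometry()
trd <- tracer_preset("free_trd")
bbb <- condition_preset("BBB", "free_trd")

noiseless <- function(...) small_imaging(shot_noise = FALSE,
                                         read_noise_sd = 0, ...)

test_that("a 90-min acquisition at 2-min intervals yields 46 frames", {
  tr <- simulate_transport(geom, bbb, trd, perfusion_protocol())
  st <- render_timelapse(tr, small_imaging())
  expect_equal(dim(st$frames)[1], 46)
  expect_equal(st$times, seq(0, 90, by = 2))
})

test_that("zero concentration and zero background render all-zero frames", {
  tr <- simulate_transport(geom, barrier_condition("BBB", 0), trd,
                           short_protocol())
  tr$outer_conc[] <- 0
  st <- render_timelapse(tr, noiseless(background_level = 0))
  expect_true(all(st$frames == 0))
})

test_that("noiseless rendering is exact region-wise bookkeeping", {
  tr <- simulate_transport(geom, bbb, trd, short_protocol(),
                           outer_conc0 = trd$inlet_concentration)
  img <- noiseless(gain = 0.06, background_level = 0.5)
  st <- render_timelapse(tr, img)
  q <- extract_traces(st)
  m <- q$n_px_outer[1]
  expect_identical(q$n_px_outer, q$n_px_central)
  expect_equal(q$s_outer, img$gain * tr$outer_conc * m + 0.5 * m,
               tolerance = 1e-12)
  expect_equal(q$s_central, img$gain * tr$central_conc * m + 0.5 * m,
               tolerance = 1e-12)
  expect_equal(q$s_background, rep(0.5 * q$n_px_background[1], nrow(q)),
               tolerance = 1e-12)
})

test_that("rendering is deterministic in the seed", {
  tr <- simulate_transport(geom, bbb, trd, short_protocol())
  a <- render_timelapse(tr, small_imaging(seed = 11))
  b <- render_timelapse(tr, small_imaging(seed = 11))
  c <- render_timelapse(tr, small_imaging(seed = 12))
  expect_identical(a$frames, b$frames)
  expect_false(identical(a$frames, c$frames))
})

test_that("rendering does not disturb the caller's RNG stream", {
  tr <- simulate_transport(geom, bbb, trd, short_protocol())
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(render_timelapse(tr, small_imaging(seed = 5)))
  expect_identical(runif(1), before)
})

test_that("frames too small for three disjoint regions are rejected", {
  tr <- simulate_transport(geom, bbb, trd, short_protocol())
  expect_error(render_timelapse(tr, imaging_model(frame_shape = c(10, 10))),
               "too small")
  expect_error(roi_set(outer = c(0, 5, 0, 5), central = c(3, 8, 3, 8),
                       background = c(20, 25, 0, 5)), "overlap")
  expect_error(roi_set(outer = c(0, 0, 0, 5), central = c(3, 8, 3, 8),
                       background = c(20, 25, 0, 5)), "non-empty")
})

test_that("stack and ROI files round-trip losslessly", {
  tr <- simulate_transport(geom, bbb, trd, short_protocol(),
                           outer_conc0 = trd$inlet_concentration)
  st <- render_timelapse(tr, small_imaging(seed = 3))
  st$frames[] <- round(st$frames)          # 16-bit integer-valued data
  dir <- withr::local_tempdir()
  path <- file.path(dir, "stack.tif")
  write_stack(st, path)
  back <- read_stack(path)
  expect_identical(back$frames, st$frames)
  expect_equal(back$times, st$times)

  roi_path <- file.path(dir, "rois.json")
  write_rois(st$rois, roi_path)
  expect_identical(read_rois(roi_path), st$rois)
})

test_that("reading stacks validates pages and timing metadata", {
  dir <- withr::local_tempdir()
  one_page <- file.path(dir, "one.tif")
  tiff::writeTIFF(matrix(0.5, 8, 8), one_page, bits.per.sample = 16L)
  expect_error(read_stack(one_page), "at least 2")

  two_pages <- file.path(dir, "two.tif")
  tiff::writeTIFF(list(matrix(0.1, 8, 8), matrix(0.2, 8, 8)), two_pages,
                  bits.per.sample = 16L)
  expect_error(read_stack(two_pages), "sidecar")
  st <- read_stack(two_pages, frame_interval = 2)
  expect_equal(st$times, c(0, 2))
  expect_error(read_stack(file.path(dir, "absent.tif")), "does not exist")
})

test_that("ROI-sum mean and variance follow the Poisson noise model", {
  # constant-concentration frames: expected pixel value lambda, ROI sum
  # expectation m * lambda and (pure shot noise) variance m * lambda
  tr <- simulate_transport(geom, barrier_condition("BBB", 0), trd,
                           short_protocol(duration = 2),
                           outer_conc0 = trd$inlet_concentration)
  img <- small_imaging(gain = 0.06, background_level = 0.5,
                       read_noise_sd = 0)
  lambda <- img$gain * tr$outer_conc[1] + img$background_level
  sums <- vapply(1:150, function(s) {
    img$seed <- s
    extract_traces(render_timelapse(tr, img))$s_outer[1]
  }, 1.0)
  m <- roi_layout(img$frame_shape)
  m <- (m$outer[2] - m$outer[1]) * (m$outer[4] - m$outer[3])
  expect_equal(mean(sums), m * lambda,
               tolerance = 3 * sqrt(m * lambda / 150) / (m * lambda))
  var_se <- m * lambda * sqrt(2 / 149)
  expect_lt(abs(var(sums) - m * lambda), 3 * var_se)
})
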