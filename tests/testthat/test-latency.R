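test_that("HSV pixel counting matches constructed blobs and a per-pixel oracle", {
  specs <- default_mask_specs("gaze_contingent")
  black <- array(0, dim = c(40, 40, 3))
  expect_equal(hsv_pixel_count(black, specs$green_dot), 0)
  expect_equal(hsv_pixel_count(black, specs$first_led), 0)

  img <- array(0.02, dim = c(60, 60, 3))
  img[11:30, 11:30, 1] <- 0.1; img[11:30, 11:30, 2] <- 0.9
  img[11:30, 11:30, 3] <- 0.1
  expect_equal(hsv_pixel_count(img, specs$green_dot), 400)

  # red wrap window: hues just below 1 and just above 0 both count
  red1 <- array(0, dim = c(10, 10, 3))
  red1[, , 1] <- 1; red1[, , 3] <- 0.2          # hue ~ 0.97
  red2 <- array(0, dim = c(10, 10, 3))
  red2[, , 1] <- 1; red2[, , 2] <- 0.2          # hue ~ 0.03
  expect_equal(hsv_pixel_count(red1, specs$red_dot), 100)
  expect_equal(hsv_pixel_count(red2, specs$red_dot), 100)

  # brute-force oracle with grDevices::rgb2hsv over a random image
  set.seed(21)
  rnd <- array(runif(30 * 20 * 3), dim = c(20, 30, 3))
  for (spec in specs) {
    hsv <- grDevices::rgb2hsv(rbind(as.vector(rnd[, , 1]),
                                    as.vector(rnd[, , 2]),
                                    as.vector(rnd[, , 3])), maxColorValue = 1)
    h <- hsv[1, ]; s <- hsv[2, ]; v <- hsv[3, ]
    in_h <- if (spec$hsv_low[1] <= spec$hsv_high[1])
      h >= spec$hsv_low[1] & h <= spec$hsv_high[1]
    else h >= spec$hsv_low[1] | h <= spec$hsv_high[1]
    oracle <- sum(in_h & s >= spec$hsv_low[2] & s <= spec$hsv_high[2] &
                    v >= spec$hsv_low[3] & v <= spec$hsv_high[3])
    expect_equal(hsv_pixel_count(rnd, spec), oracle)
  }

  expect_error(hsv_pixel_count(array(0, c(0, 0, 3)), specs$red_dot),
               "gazeqc_empty_image")
})

test_that("flag thresholds are strict: boundary counts never flag", {
  led <- mask_spec("led", c(0, 0, 0.7), c(1, 0.3, 1), min_pixels = 10)
  first <- mask_spec("first_led", c(0, 0, 0.7), c(1, 0.3, 1), 10, 250)
  second <- mask_spec("second_led", c(0, 0, 0.7), c(1, 0.3, 1), 300)
  expect_false(flag_frames(10, led))
  expect_true(flag_frames(11, led))
  expect_false(flag_frames(250, first))
  expect_true(flag_frames(249, first))
  expect_false(flag_frames(10, first))
  expect_false(flag_frames(300, second))
  expect_true(flag_frames(301, second))
  expect_true(flag_frames(400, second))
})

test_that("onset detection is a debounced rising edge", {
  f <- as.logical(c(0, 0, 0, 1, 1, 1, 0, 0, 0, 1, 1, 1))
  expect_equal(detect_onsets(f, debounce = 1), c(4, 10))
  expect_equal(detect_onsets(as.logical(c(0, 1, 0, 1)), debounce = 2), 2)
  expect_equal(detect_onsets(rep(FALSE, 20), 1), integer(0))
  expect_equal(detect_onsets(c(TRUE, TRUE, FALSE, FALSE, TRUE), 2), c(1, 5))
})

test_that("interval counting pairs each LED with its window's first dot", {
  expect_equal(count_intervals(10, 17)$intervals, 7L)
  r <- count_intervals(c(10, 400), 17)
  expect_equal(r$intervals, 7L)
  expect_equal(r$n_dropped, 1L)
  r2 <- count_intervals(10, 8)
  expect_equal(r2$intervals, integer(0))
  expect_equal(r2$n_dropped, 1L)
  # dot belonging to the second LED is not matched to the first
  r3 <- count_intervals(c(10, 20), c(25, 27))
  expect_equal(r3$intervals, 5L)
  expect_equal(r3$n_dropped, 1L)
})

test_that("latency summary is the median interval times mean frame duration", {
  res <- latency_summary(rep(7L, 33), fps = 1000 / 8.3)
  expect_equal(res$latency_ms, 58.1, tolerance = 1e-9)
  expect_equal(latency_summary(c(6L, 7L, 8L), fps = 100)$latency_ms, 70)
  expect_equal(latency_summary(c(6L, 8L), fps = 100)$latency_ms, 70)
  # timestamps dominate fps when given
  res2 <- latency_summary(c(7L, 7L), frame_times = seq(0, 1, by = 0.01), fps = 999)
  expect_equal(res2$mean_frame_duration_ms, 10, tolerance = 1e-9)
  # identity invariant
  expect_equal(res$latency_ms, res$median_frames * res$mean_frame_duration_ms)
  expect_error(latency_summary(integer(0)), "gazeqc_no_events")
})

test_that("full scenario runs recover injected lags exactly", {
  d <- withr::local_tempdir()
  render_small_sequence(d, lag = 4L)
  res <- run_scenario(d, "eye_detection", debounce = 1, fps = 30)
  expect_equal(res$intervals_frames, rep(4L, 3))
  expect_equal(res$median_frames, 4)
  expect_equal(res$n_dropped, 0L)
  # per-cycle lags -> median of the list
  d2 <- withr::local_tempdir()
  cfg <- frame_sim_config(rng_seed = 2, fps = 30, n_cycles = 3,
                          lag_frames = c(3L, 4L, 5L), width = 96, height = 72)
  render_frame_sequence(cfg, d2)
  res2 <- run_scenario(d2, "eye_detection", debounce = 1, fps = 30)
  expect_equal(sort(res2$intervals_frames), c(3L, 4L, 5L))
  expect_equal(res2$median_frames, 4)
})

test_that("gaze-contingent runs ignore the persisting green dot", {
  d <- withr::local_tempdir()
  render_small_sequence(d, lag = 5L, scenario = "gaze_contingent")
  res <- run_scenario(d, "gaze_contingent", debounce = 1, fps = 30)
  expect_equal(res$intervals_frames, rep(5L, 3))

  # first/second LED flags are mutually exclusive per frame
  specs <- default_mask_specs("gaze_contingent")
  frames <- read_frame_sequence(d, fps = 30)
  counts <- attr(res, "counts")
  flags <- flag_frames(counts, specs)
  expect_equal(sum(flags[, "first_led"] & flags[, "second_led"]), 0)
  # the green dot really does persist across the LED switch
  g_on <- which(flags[, "green_dot"])
  led2_on <- which(flags[, "second_led"])
  expect_true(all(led2_on %in% g_on))

  # scenario/mask mismatch and empty events are named errors
  expect_error(run_scenario(d, "gaze_contingent",
                            specs = default_mask_specs("eye_detection")),
               "gazeqc_mask_mismatch")
  d3 <- withr::local_tempdir()
  render_small_sequence(d3, lag = 4L)  # eye-detection: no red dot anywhere
  expect_error(run_scenario(d3, "gaze_contingent", debounce = 1),
               "gazeqc_no_events")
})

test_that("frame sequences read timestamps from frames.csv when present", {
  d <- withr::local_tempdir()
  cfg <- frame_sim_config(rng_seed = 3, frame_duration_ms = 8.3, n_cycles = 1,
                          on_s = 0.05, off_s = 0.05, lag_frames = 2,
                          width = 64, height = 48)
  render_frame_sequence(cfg, d)
  fr <- read_frame_sequence(d, fps = 999)
  expect_true(fr$timestamps_from_file)
  expect_equal(mean(diff(fr$t)) * 1000, 8.3, tolerance = 1e-9)
  res <- run_scenario(fr, "eye_detection", debounce = 1)
  expect_equal(res$mean_frame_duration_ms, 8.3, tolerance = 1e-9)
})
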