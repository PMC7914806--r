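test_that("binocular averaging renormalises and respects validity", {
  s <- make_samples(t = c(0, 0.01, 0.02))
  # identical eyes -> same direction
  avg <- average_binocular(s)
  expect_equal(unlist(avg[1, c("dir_x", "dir_y", "dir_z")]),
               c(dir_x = 0, dir_y = 0, dir_z = 1))

  # symmetric convergence collapses to the bisector
  th <- 10 * pi / 180
  s$left_dir_x <- sin(th); s$left_dir_z <- cos(th)
  s$right_dir_x <- -sin(th); s$right_dir_z <- cos(th)
  avg <- average_binocular(s)
  expect_equal(avg$dir_x[1], 0)
  expect_equal(avg$dir_z[1], 1)  # renormalised to unit length

  # one lost eye invalidates the sample regardless of the other
  s$left_valid[2] <- FALSE
  expect_false(average_binocular(s)$valid[2])

  # anti-parallel eyes: invalid, not an error
  s$right_dir_x[3] <- 0; s$right_dir_z[3] <- -1
  s$left_dir_x[3] <- 0; s$left_dir_z[3] <- 1
  expect_false(average_binocular(s)$valid[3])
})

test_that("target re-referencing subtracts the eye position with unit handling", {
  expect_equal(as.numeric(reref_target_to_eye(c(0, 0, 1), c(0, 0, 0))),
               c(0, 0, 1))
  expect_equal(as.numeric(reref_target_to_eye(c(0, 0, 1), c(0.03, 0, 0))),
               c(-0.03, 0, 1))
  expect_equal(
    as.numeric(reref_target_to_eye(c(0, 0, 1), c(30, 0, 0), origin_unit = "mm")),
    c(-0.03, 0, 1))
})

test_that("quaternion angular speed matches its definition and double cover", {
  q0 <- c(1, 0, 0, 0)
  expect_equal(quaternion_angular_speed(q0, q0, 1 / 120), 0)
  # 1 degree about y over one 120 Hz sample -> 120 deg/s
  q1 <- c(cos(0.5 * pi / 180), 0, sin(0.5 * pi / 180), 0)
  expect_equal(quaternion_angular_speed(q0, q1, 1 / 120), 120, tolerance = 1e-9)
  # sign flip of either quaternion changes nothing
  expect_equal(quaternion_angular_speed(q0, -q1, 1 / 120), 120, tolerance = 1e-9)
  expect_equal(quaternion_angular_speed(-q0, q0, 1), 0)
  expect_error(quaternion_angular_speed(q0, q1, 0), "gazeqc_bad_dt")
})

test_that("head-phase labelling thresholds, smooths, and merges short runs", {
  # constant pose -> all stable
  expect_true(all(label_head_phases(rep(0, 100)) == "stable"))

  # 1 s still, 1 s at 30 deg/s, 1 s still at 120 Hz, threshold 10
  spd <- c(rep(0, 120), rep(30, 120), rep(0, 120))
  lab <- label_head_phases(spd, threshold_dps = 10, min_run = 12, smooth_window = 5)
  expect_equal(sum(lab == "moving"), 120, tolerance = 4)  # edges blur by the smoother
  expect_true(all(lab[10:110] == "stable"))
  expect_true(all(lab[130:230] == "moving"))

  # a single-sample spike is absorbed into the surrounding stable phase
  spike <- rep(0, 100); spike[50] <- 100
  expect_true(all(label_head_phases(spike, 10, min_run = 5,
                                    smooth_window = 1) == "stable"))
})

test_that("segmentation retains the discard-window contract", {
  proto <- one_target_protocol()
  rate <- 120
  t <- seq(0, 5 - 1 / rate, by = 1 / rate)
  sess <- gaze_session(make_samples(t), proto, nominal_rate_hz = rate)
  segs <- segment_by_target(sess)
  expect_length(segs, 1)
  seg <- segs[[1]]
  expect_equal(seg$n_expected, 540)         # 4.5 s x 120 Hz
  expect_equal(nrow(seg$samples), 540)
  expect_true(all(seg$samples$t >= 0.5))
  expect_true(all(seg$samples$phase == "n/a"))

  # boundary samples: 0.499 excluded, 0.501 retained
  sess2 <- gaze_session(make_samples(c(0.499, 0.501)), proto)
  seg2 <- segment_by_target(sess2)[[1]]
  expect_equal(seg2$samples$t, 0.501)

  # disjoint times are a named error
  sess3 <- gaze_session(make_samples(c(100, 101)), proto)
  expect_error(segment_by_target(sess3), "gazeqc_disjoint_times")
})

test_that("invalid samples are retained in segments for loss accounting", {
  proto <- make_protocol("head_still", rng_seed = 4, repetitions = 1)
  sim <- simulate_gaze_session(gaze_sim_config(
    rng_seed = 4, protocol = proto, dropout_rate = 0.1))
  segs <- segment_by_target(sim$session)
  n_rows <- sum(vapply(segs, function(sg) nrow(sg$samples), 0L))
  n_valid <- sum(vapply(segs, function(sg) sum(sg$samples$valid), 0L))
  # every recorded slot is retained; the invalid count matches ground truth
  truth <- sim$truth$samples
  keep <- logical(nrow(truth))
  for (sg in segs)
    keep[truth$t %in% sg$samples$t] <- TRUE
  expect_equal(n_rows, sum(keep))
  expect_equal(n_valid, sum(truth$valid[keep]))
  expect_gt(n_rows - n_valid, 0)
})

test_that("head-free phase labels recover well-separated ground truth", {
  proto <- make_protocol("head_free", rng_seed = 6, repetitions = 1,
                         target_duration_s = 2, recenter_duration_s = 1)
  motion <- list(list(start_s = 10, end_s = 20, axis = "y", rate_dps = 30),
                 list(start_s = 40, end_s = 50, axis = "x", rate_dps = 25))
  sim <- simulate_gaze_session(gaze_sim_config(
    rng_seed = 6, protocol = proto, head_motion = motion))
  segs <- segment_by_target(sim$session, threshold_dps = 10)
  truth <- sim$truth$samples
  agree <- total <- 0L
  for (sg in segs) {
    m <- match(sg$samples$t, truth$t)
    agree <- agree + sum(sg$samples$phase == truth$phase[m])
    total <- total + nrow(sg$samples)
  }
  expect_gt(agree / total, 0.99)
  # partition property: every retained sample has exactly one phase
  phases <- unlist(lapply(segs, function(sg) sg$samples$phase))
  expect_true(all(phases %in% c("stable", "moving")))
})
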