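# Shared fixture builders. Everything is generated in code; nothing is
# stored on disk.

# a minimal hand-built gaze-sample data frame (all eyes valid, looking +z)
make_samples <- function(t, dir = c(0, 0, 1), valid = TRUE,
                         quat = c(1, 0, 0, 0)) {
  n <- length(t)
  dirm <- matrix(dir, n, 3, byrow = TRUE)
  data.frame(
    t = t,
    left_valid = rep(valid, length.out = n),
    left_origin_x_mm = -31.5, left_origin_y_mm = 0, left_origin_z_mm = 0,
    left_dir_x = dirm[, 1], left_dir_y = dirm[, 2], left_dir_z = dirm[, 3],
    right_valid = rep(valid, length.out = n),
    right_origin_x_mm = 31.5, right_origin_y_mm = 0, right_origin_z_mm = 0,
    right_dir_x = dirm[, 1], right_dir_y = dirm[, 2], right_dir_z = dirm[, 3],
    world_dir_x = NA_real_, world_dir_y = NA_real_, world_dir_z = NA_real_,
    hmd_quat_w = quat[1], hmd_quat_x = quat[2], hmd_quat_y = quat[3],
    hmd_quat_z = quat[4],
    hmd_pos_x_m = 0, hmd_pos_y_m = 0, hmd_pos_z_m = 0)
}

# short single-target head-still protocol for focused segment tests
one_target_protocol <- function(duration_s = 5) {
  p <- make_protocol("head_still", rng_seed = 1, repetitions = 1)
  ev <- p$events[p$events$target_id == "3c", ]
  ev$onset_s <- 0; ev$offset_s <- duration_s
  p$events <- ev
  p$repetitions <- 1L
  p
}

# small frame-sequence fixture shared by latency tests
render_small_sequence <- function(dir, lag = 4L, scenario = "eye_detection",
                                  n_cycles = 3L, fps = 30, seed = 1L,
                                  jitter = 0L) {
  cfg <- frame_sim_config(rng_seed = seed, fps = fps, n_cycles = n_cycles,
                          lag_frames = lag, scenario = scenario,
                          width = 96L, height = 72L,
                          area_jitter_px = jitter)
  render_frame_sequence(cfg, dir)
}
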