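# Synthetic gaze-session generator with known ground truth. Sessions are
# built so that every quantity the spatial pipeline estimates (per-target
# offset, sample-to-sample noise, per-phase dropout, head-motion phases)
# is known exactly by construction.

#' Configuration for the gaze-session simulator
#'
#' @param rng_seed integer seed; all randomness in the simulation flows
#'   from it.
#' @param protocol a [make_protocol()] schedule (default: head-still with
#'   seed `rng_seed`).
#' @param offset_deg injected angular offset between true target direction
#'   and simulated gaze: a scalar, or a vector of 25 per-cell values in
#'   row-major grid order (row 1 column a first).
#' @param offset_direction `"radial"` (away from the grid centre; central
#'   target falls back to +x), `"fixed"` (toward +x), or `"random"` (one
#'   seeded random tangent direction per grid cell).
#' @param noise_sigma_deg isotropic per-component direction noise SD,
#'   degrees, applied in the tangent plane of the true (offset) direction.
#' @param dropout_rate per-sample probability that no eye is detected.
#' @param dropout_moving_multiplier factor applied to `dropout_rate` while
#'   the head is moving (head-free sessions).
#' @param interocular_mm distance between the two simulated eyes (default
#'   63 mm); both eyes share the cyclopean gaze direction.
#' @param head_motion list of head-rotation intervals, each a list/vector
#'   `(start_s, end_s, axis, rate_dps)` with `axis` one of `"x"`, `"y"`,
#'   `"z"`; drives the HMD quaternion trace.
#' @param rate_hz sampling rate (default 120).
#' @return list of class `gaze_sim_config`.
#' @export
gaze_sim_config <- function(rng_seed = 1L, protocol = NULL,
                            offset_deg = 0, offset_direction = c("radial", "fixed", "random"),
                            noise_sigma_deg = 0, dropout_rate = 0,
                            dropout_moving_multiplier = 1,
                            interocular_mm = 63,
                            head_motion = list(), rate_hz = 120) {
  offset_direction <- match.arg(offset_direction)
  if (is.null(protocol)) protocol <- make_protocol("head_still", rng_seed = rng_seed)
  stopifnot(noise_sigma_deg >= 0, rate_hz > 0,
            dropout_rate >= 0, dropout_rate <= 1,
            dropout_moving_multiplier >= 0,
            length(offset_deg) %in% c(1L, 25L))
  if (length(head_motion) && protocol$condition == "head_still")
    warning("head_motion specified for a head_still protocol: the pose is recorded but targets move with the headset")
  structure(list(rng_seed = as.integer(rng_seed), protocol = protocol,
                 offset_deg = offset_deg, offset_direction = offset_direction,
                 noise_sigma_deg = noise_sigma_deg, dropout_rate = dropout_rate,
                 dropout_moving_multiplier = dropout_moving_multiplier,
                 interocular_mm = interocular_mm, head_motion = head_motion,
                 rate_hz = rate_hz),
            class = "gaze_sim_config")
}

# normalise one head-motion interval to a named list
norm_motion <- function(hm) {
  hm <- as.list(hm)
  want <- c("start_s", "end_s", "axis", "rate_dps")
  if (is.null(names(hm)) || !all(want %in% names(hm))) names(hm) <- want
  hm
}

# HMD orientation trace from the configured rotation intervals: each
# interval contributes a rotation about its axis accruing at rate_dps,
# composed in chronological order (later rotations multiply on the left).
simulate_hmd_quat <- function(t, head_motion) {
  n <- length(t)
  q <- cbind(rep(1, n), 0, 0, 0)
  axes <- list(x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  for (hm in head_motion) {
    hm <- norm_motion(hm)
    start <- as.numeric(hm$start_s); end <- as.numeric(hm$end_s)
    ax <- if (is.character(hm$axis)) axes[[hm$axis]] else as.numeric(hm$axis)
    ang <- as.numeric(hm$rate_dps) *
      pmin(pmax(t - start, 0), end - start) * pi / 180
    dq <- quat_from_axis_angle(matrix(ax, 1), ang)
    q <- quat_mult(dq, q)
  }
  q
}

# moving/stable ground-truth phase mask from the motion intervals
motion_phase <- function(t, head_motion) {
  moving <- rep(FALSE, length(t))
  for (hm in head_motion) {
    hm <- norm_motion(hm)
    moving <- moving |
      (t >= as.numeric(hm$start_s) & t < as.numeric(hm$end_s))
  }
  ifelse(moving, "moving", "stable")
}

#' Simulate a gaze recording session
#'
#' Generates a tracker log against the configured protocol. The simulated
#' observer fixates each target exactly (acquisition happens within the
#' onset-discard window), with the configured angular offset and isotropic
#' tangent-plane noise; dropout invalidates samples at the configured rate
#' (optionally increased during head-moving phases); the HMD quaternion
#' trace follows the configured head-motion intervals. In head-free
#' protocols the targets are world-fixed, the log's `world_dir` holds the
#' simulated world-frame gaze, and HMD-local directions are derived by the
#' inverse head rotation; re-centering windows direct gaze at the world
#' point straight ahead of the origin.
#'
#' Both eyes record the same (cyclopean) direction from origins offset by
#' half the interocular distance, so that the binocular average reproduces
#' the simulated direction exactly and the injected offset is the exact
#' per-target accuracy of a noise-free session.
#'
#' @param cfg a [gaze_sim_config()].
#' @return list with `session` (a [gaze_session()]) and `truth`, a list
#'   holding `samples` (per-sample data frame: `t`, `target_id`,
#'   `repetition`, `is_recentering`, `true_error_deg` — the realised angle
#'   between simulated gaze and true target direction, noise included —
#'   `phase`, `valid`) and `offset_by_cell` (named per-cell injected
#'   offsets, degrees).
#' @export
simulate_gaze_session <- function(cfg) {
  stopifnot(inherits(cfg, "gaze_sim_config"))
  proto <- cfg$protocol
  events <- proto$events
  head_free <- proto$condition == "head_free"
  d_view <- proto$viewing_distance_m

  n_ev <- nrow(events)
  t_end <- max(events$offset_s)
  t <- seq(0, t_end, by = 1 / cfg$rate_hz)
  n <- length(t)

  ev_idx <- findInterval(t, events$onset_s)
  ev_idx[ev_idx < 1L] <- 1L

  tgt <- as.matrix(events[ev_idx, c("pos_x_m", "pos_y_m", "pos_z_m")])
  is_rec <- events$is_recentering[ev_idx]
  # the degenerate world-origin re-centering target: look straight ahead
  tgt[is_rec, ] <- matrix(rep(c(0, 0, d_view), sum(is_rec)), ncol = 3, byrow = TRUE)

  # per-cell offset lookup, row-major over the grid
  cell_key <- function(r, c) r * 5L + c + 1L
  off_vec <- if (length(cfg$offset_deg) == 1L) rep(cfg$offset_deg, 25L) else cfg$offset_deg
  off_ev <- ifelse(events$is_recentering, 0,
                   off_vec[cell_key(events$grid_row, events$grid_col)])
  off_smp <- off_ev[ev_idx]

  with_seed(cfg$rng_seed, {
    # true direction toward the active target (world frame for head-free,
    # HMD-local otherwise); eye centre sits at the origin in both frames
    dir_true <- unit_rows(tgt)

    # offset rotation axis per sample
    centre <- matrix(rep(c(0, 0, 1), n), ncol = 3, byrow = TRUE)
    u <- switch(cfg$offset_direction,
      radial = {
        rad <- dir_true - dot_rows(dir_true, centre) * centre
        deg <- row_norm(rad) < 1e-9
        rad[deg, ] <- matrix(rep(c(1, 0, 0), sum(deg)), ncol = 3, byrow = TRUE)
        unit_rows(rad)
      },
      fixed = matrix(rep(c(1, 0, 0), n), ncol = 3, byrow = TRUE),
      random = {
        phi <- stats::runif(25L, 0, 2 * pi)
        tb <- tangent_basis(dir_true)
        phi_ev <- ifelse(events$is_recentering, 0,
                         phi[cell_key(events$grid_row, events$grid_col)])
        ph <- phi_ev[ev_idx]
        unit_rows(tb$e1 * cos(ph) + tb$e2 * sin(ph))
      })
    axis <- cross_rows(dir_true, u)
    deg_ax <- row_norm(axis) < 1e-9
    axis[deg_ax, ] <- matrix(rep(c(0, 1, 0), sum(deg_ax)), ncol = 3, byrow = TRUE)
    axis <- unit_rows(axis)
    dir_off <- rotate_rows(dir_true, axis, off_smp * pi / 180)

    # isotropic tangent-plane noise
    if (cfg$noise_sigma_deg > 0) {
      tb <- tangent_basis(dir_off)
      srad <- cfg$noise_sigma_deg * pi / 180
      z1 <- stats::rnorm(n, 0, srad); z2 <- stats::rnorm(n, 0, srad)
      dir_gaze <- unit_rows(dir_off + tb$e1 * z1 + tb$e2 * z2)
    } else {
      dir_gaze <- dir_off
    }

    q <- simulate_hmd_quat(t, cfg$head_motion)
    phase <- if (head_free) motion_phase(t, cfg$head_motion) else rep("n/a", n)

    p_drop <- cfg$dropout_rate *
      ifelse(phase == "moving", cfg$dropout_moving_multiplier, 1)
    valid <- stats::runif(n) >= p_drop
  })

  true_err <- angular_error_deg(dir_gaze, dir_true)

  if (head_free) {
    world_dir <- dir_gaze
    dir_local <- quat_rotate(quat_conj(q), dir_gaze)
  } else {
    world_dir <- quat_rotate(q, dir_gaze)
    dir_local <- dir_gaze
  }

  half <- cfg$interocular_mm / 2
  zero3 <- function(m, bad) { m[bad, ] <- 0; m }
  dir_local <- zero3(dir_local, !valid)
  world_dir <- zero3(world_dir, !valid)

  samples <- data.frame(
    t = t,
    left_valid = valid,
    left_origin_x_mm = -half, left_origin_y_mm = 0, left_origin_z_mm = 0,
    left_dir_x = dir_local[, 1], left_dir_y = dir_local[, 2],
    left_dir_z = dir_local[, 3],
    right_valid = valid,
    right_origin_x_mm = half, right_origin_y_mm = 0, right_origin_z_mm = 0,
    right_dir_x = dir_local[, 1], right_dir_y = dir_local[, 2],
    right_dir_z = dir_local[, 3],
    world_dir_x = world_dir[, 1], world_dir_y = world_dir[, 2],
    world_dir_z = world_dir[, 3],
    hmd_quat_w = q[, 1], hmd_quat_x = q[, 2], hmd_quat_y = q[, 3],
    hmd_quat_z = q[, 4],
    hmd_pos_x_m = 0, hmd_pos_y_m = 0, hmd_pos_z_m = 0)

  session <- gaze_session(samples, schedule = proto,
                          nominal_rate_hz = cfg$rate_hz,
                          metadata = list(generator = "simulate_gaze_session",
                                          rng_seed = cfg$rng_seed))

  cells <- expand.grid(grid_row = 0:4, grid_col = 0:4)
  names(off_vec) <- paste0(cells$grid_row + 1L, letters[cells$grid_col + 1L])[
    order(cell_key(cells$grid_row, cells$grid_col))]

  truth <- list(
    samples = data.frame(t = t,
                         target_id = events$target_id[ev_idx],
                         repetition = events$repetition[ev_idx],
                         is_recentering = is_rec,
                         true_error_deg = true_err,
                         phase = phase, valid = valid),
    offset_by_cell = off_vec,
    noise_sigma_deg = cfg$noise_sigma_deg,
    dropout_rate = cfg$dropout_rate,
    dropout_moving_multiplier = cfg$dropout_moving_multiplier)

  list(session = session, truth = truth)
}
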