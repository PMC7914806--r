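# Pre-processing: binocular averaging, target re-referencing, onset discard,
# per-target segmentation, and head-motion phase labelling.

#' Average the two eyes' gaze vectors
#'
#' Combines left and right eye data into a single cyclopean gaze sample: the
#' direction is the component-wise mean of the two unit direction vectors,
#' renormalised to unit length; the origin is the component-wise mean of the
#' two origins. A sample is valid only when both eyes were tracked — samples
#' where either eye was lost are excluded from spatial analysis for both
#' eyes. Anti-parallel eye vectors (zero mean) mark the sample invalid
#' rather than raising an error.
#'
#' @param samples data frame of gaze-log rows (see [read_gaze_log()]).
#' @return data frame with columns `dir_x/y/z` (unit, or 0 when invalid),
#'   `origin_x/y/z_mm`, `valid`.
#' @export
average_binocular <- function(samples) {
  ld <- as.matrix(samples[, c("left_dir_x", "left_dir_y", "left_dir_z")])
  rd <- as.matrix(samples[, c("right_dir_x", "right_dir_y", "right_dir_z")])
  lo <- as.matrix(samples[, c("left_origin_x_mm", "left_origin_y_mm", "left_origin_z_mm")])
  ro <- as.matrix(samples[, c("right_origin_x_mm", "right_origin_y_mm", "right_origin_z_mm")])
  valid <- as.logical(samples$left_valid) & as.logical(samples$right_valid)
  m <- (ld + rd) / 2
  nrm <- row_norm(m)
  valid <- valid & nrm > 1e-12 & !is.na(nrm)
  dir <- matrix(0, nrow(m), 3L)
  dir[valid, ] <- m[valid, , drop = FALSE] / nrm[valid]
  org <- (lo + ro) / 2
  out <- data.frame(dir_x = dir[, 1], dir_y = dir[, 2], dir_z = dir[, 3],
                    origin_x_mm = org[, 1], origin_y_mm = org[, 2],
                    origin_z_mm = org[, 3], valid = valid)
  out
}

#' Re-reference a target position to the eye
#'
#' Subtracts the gaze origin (eye position) from the target position so that
#' the resulting vector points from the eye to the target, in the shared
#' reference frame. Origins reported in millimetres are converted to metres
#' before subtraction.
#'
#' @param target_pos_m n x 3 matrix (or length-3 vector) of target
#'   positions, metres.
#' @param gaze_origin n x 3 matrix (or length-3 vector) of eye positions.
#' @param origin_unit `"m"` or `"mm"`.
#' @return n x 3 matrix of target-to-eye vectors, metres.
#' @export
reref_target_to_eye <- function(target_pos_m, gaze_origin, origin_unit = c("m", "mm")) {
  origin_unit <- match.arg(origin_unit)
  tp <- as_mat3(target_pos_m)
  go <- as_mat3(gaze_origin)
  if (origin_unit == "mm") go <- go / 1000
  if (nrow(go) == 0L || nrow(tp) == 0L)
    return(matrix(numeric(0), 0L, 3L))
  if (nrow(go) == 1L && nrow(tp) > 1L) go <- go[rep(1L, nrow(tp)), , drop = FALSE]
  if (nrow(tp) == 1L && nrow(go) > 1L) tp <- tp[rep(1L, nrow(go)), , drop = FALSE]
  tp - go
}

#' Angular speed between two HMD orientations
#'
#' Computes the rotation rate implied by two consecutive unit quaternions,
#' as the geodesic angle `2 * acos(|<q1, q2>|)` divided by the sample
#' interval, in degrees per second. The absolute value of the inner product
#' makes the result invariant to the quaternion double cover (q and -q
#' describe the same orientation).
#'
#' @param q1,q2 unit quaternions as length-4 vectors `(w, x, y, z)` or n x 4
#'   matrices.
#' @param dt positive time step(s), seconds.
#' @return angular speed(s), degrees per second.
#' @export
quaternion_angular_speed <- function(q1, q2, dt) {
  if (any(dt <= 0)) stop("gazeqc_bad_dt: dt must be > 0", call. = FALSE)
  if (is.null(dim(q1))) q1 <- matrix(q1, ncol = 4L, byrow = TRUE)
  if (is.null(dim(q2))) q2 <- matrix(q2, ncol = 4L, byrow = TRUE)
  d <- pmin(1, abs(rowSums(q1 * q2)))
  ang <- 2 * acos(d)
  ang * 180 / pi / dt
}

#' Head angular-speed trace for a session
#'
#' Differentiates the HMD orientation quaternion over consecutive samples,
#' giving one angular-speed value per sample (the first sample repeats the
#' second's value so every sample is covered).
#'
#' @param session a [gaze_session()].
#' @return data frame `t`, `angular_speed_dps`.
#' @export
head_phase_trace <- function(session) {
  s <- session$samples
  n <- nrow(s)
  q <- as.matrix(s[, c("hmd_quat_w", "hmd_quat_x", "hmd_quat_y", "hmd_quat_z")])
  dt <- diff(s$t)
  dt[dt <= 0] <- 1 / session$nominal_rate_hz
  spd <- quaternion_angular_speed(q[-n, , drop = FALSE], q[-1, , drop = FALSE], dt)
  data.frame(t = s$t, angular_speed_dps = c(spd[1], spd))
}

#' Label samples as head-stable or head-moving
#'
#' Thresholds a (smoothed) head angular-speed trace to split head-free
#' fixation samples into a stable phase and a moving phase. The speed is
#' smoothed with a centred moving average, samples above the threshold are
#' labelled `moving`, and runs shorter than `min_run` samples are absorbed
#' into the surrounding phase so that single-sample flicker does not
#' fragment the segmentation.
#'
#' @param angular_speed_dps numeric vector of angular speeds, degrees/second.
#' @param threshold_dps speed threshold separating the phases (default 10).
#' @param min_run minimum run length, in samples, for a phase to stand
#'   (default 12, i.e. 100 ms at 120 Hz).
#' @param smooth_window moving-average window, samples (default 5; 1 = none).
#' @return character vector `"stable"` / `"moving"`, one label per sample.
#' @export
label_head_phases <- function(angular_speed_dps, threshold_dps = 10,
                              min_run = 12L, smooth_window = 5L) {
  stopifnot(threshold_dps > 0, min_run >= 1)
  x <- angular_speed_dps
  n <- length(x)
  if (n == 0L) return(character(0))
  if (smooth_window > 1L && n > 1L) {
    k <- min(as.integer(smooth_window), n)
    x <- stats::filter(x, rep(1 / k, k), sides = 2)
    x <- as.numeric(x)
    # edges: shrink the window rather than dropping samples
    half <- k %/% 2
    for (i in which(is.na(x))) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      x[i] <- mean(angular_speed_dps[lo:hi])
    }
  }
  moving <- x > threshold_dps
  # merge runs shorter than min_run into the surrounding phase
  repeat {
    r <- rle(moving)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < min_run)
    if (!length(short)) break
    i <- short[which.min(r$lengths[short])]
    r$values[i] <- !r$values[i]
    moving <- inverse.rle(r)
  }
  ifelse(moving, "moving", "stable")
}

#' Split a session into per-target fixation segments
#'
#' Applies the standard pre-processing chain: the first `discard_s` seconds
#' after each target onset are discarded (gaze-redirection time), the two
#' eyes are averaged (or a single eye channel is selected), the target is
#' re-referenced to the eye position, and — for head-free recordings — each
#' sample is labelled head-stable or head-moving from the HMD quaternion
#' trace. Samples in which an eye was not detected are *retained* with
#' `valid = FALSE` so that data-loss accounting can see them; spatial
#' metrics skip them.
#'
#' For head-free sessions the analysis direction is the logged world-frame
#' gaze vector when present, otherwise the HMD-local averaged direction
#' rotated into the world frame by the HMD quaternion; target-to-eye
#' vectors are formed in the world frame using the eye position rotated and
#' translated by the HMD pose.
#'
#' @param session a [gaze_session()] with a schedule attached.
#' @param discard_s onset discard, seconds (default 0.5).
#' @param channel `"averaged"`, `"left"`, or `"right"` eye channel.
#' @param threshold_dps,min_run,smooth_window head-phase parameters, see
#'   [label_head_phases()].
#' @return list of `fixation_segment` objects, one per (target,
#'   repetition) presentation (re-centering presentations included, flagged
#'   with `is_recentering = TRUE`). Each segment holds the target metadata,
#'   `n_expected` (samples the nominal rate predicts for the retained
#'   window) and a `samples` data frame with `t`, `dir_x/y/z`,
#'   `origin_x/y/z_m`, `tve_x/y/z` (target-to-eye vector), `phase`, `valid`.
#' @export
segment_by_target <- function(session, discard_s = 0.5,
                              channel = c("averaged", "left", "right"),
                              threshold_dps = 10, min_run = 12L,
                              smooth_window = 5L) {
  stopifnot(inherits(session, "gaze_session"))
  channel <- match.arg(channel)
  sched <- session$schedule
  if (is.null(sched))
    stop("gazeqc_no_schedule: session has no schedule attached", call. = FALSE)
  s <- session$samples
  events <- sched$events
  if (max(s$t) < min(events$onset_s) || min(s$t) > max(events$offset_s))
    stop("gazeqc_disjoint_times: sample times do not overlap the schedule",
         call. = FALSE)
  tgt_ev <- events[!events$is_recentering, ]
  if (any(discard_s >= tgt_ev$offset_s - tgt_ev$onset_s))
    stop("gazeqc_bad_discard: discard_s must be shorter than every target presentation",
         call. = FALSE)

  if (channel == "averaged") {
    avg <- average_binocular(s)
    dir_l <- as.matrix(avg[, c("dir_x", "dir_y", "dir_z")])
    org_m <- as.matrix(avg[, c("origin_x_mm", "origin_y_mm", "origin_z_mm")]) / 1000
    valid <- avg$valid
  } else {
    pre <- paste0(channel, "_")
    dir_l <- as.matrix(s[, paste0(pre, c("dir_x", "dir_y", "dir_z"))])
    org_m <- as.matrix(s[, paste0(pre, c("origin_x_mm", "origin_y_mm", "origin_z_mm"))]) / 1000
    valid <- as.logical(s[[paste0(pre, "valid")]])
  }

  head_free <- sched$condition == "head_free"
  q <- as.matrix(s[, c("hmd_quat_w", "hmd_quat_x", "hmd_quat_y", "hmd_quat_z")])
  pos_w <- as.matrix(s[, c("hmd_pos_x_m", "hmd_pos_y_m", "hmd_pos_z_m")])

  if (head_free) {
    wd <- as.matrix(s[, c("world_dir_x", "world_dir_y", "world_dir_z")])
    have_world <- channel == "averaged" && !anyNA(wd) && any(row_norm(wd) > 0)
    dir_use <- if (have_world) wd else quat_rotate(q, dir_l)
    org_use <- pos_w + quat_rotate(q, org_m)
    trace <- head_phase_trace(session)
    phase <- label_head_phases(trace$angular_speed_dps, threshold_dps,
                               min_run, smooth_window)
  } else {
    dir_use <- dir_l
    org_use <- org_m
    phase <- rep("n/a", nrow(s))
  }

  rate <- session$nominal_rate_hz
  segs <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    lo <- ev$onset_s + discard_s
    idx <- which(s$t >= lo & s$t < ev$offset_s)
    tvec <- reref_target_to_eye(c(ev$pos_x_m, ev$pos_y_m, ev$pos_z_m),
                                org_use[idx, , drop = FALSE])
    seg_samples <- data.frame(
      t = s$t[idx],
      dir_x = dir_use[idx, 1], dir_y = dir_use[idx, 2], dir_z = dir_use[idx, 3],
      origin_x_m = org_use[idx, 1], origin_y_m = org_use[idx, 2],
      origin_z_m = org_use[idx, 3],
      tve_x = tvec[, 1], tve_y = tvec[, 2], tve_z = tvec[, 3],
      phase = phase[idx], valid = valid[idx])
    segs[[i]] <- structure(
      list(target_id = ev$target_id, grid_row = ev$grid_row,
           grid_col = ev$grid_col, repetition = ev$repetition,
           frame = ev$frame, is_recentering = ev$is_recentering,
           onset_s = ev$onset_s, offset_s = ev$offset_s,
           n_expected = as.integer(round((ev$offset_s - ev$onset_s - discard_s) * rate)),
           channel = channel, condition = sched$condition,
           samples = seg_samples),
      class = "fixation_segment")
  }
  segs
}

#' @export
print.fixation_segment <- function(x, ...) {
  cat(sprintf("<fixation_segment> target %s rep %d: %d samples (%d valid), expected %d\n",
              x$target_id, x$repetition, nrow(x$samples),
              sum(x$samples$valid), x$n_expected))
  invisible(x)
}
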