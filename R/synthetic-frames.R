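# Synthetic LED/dot frame-sequence generator for the latency pipeline.
# Frames are flat-colour blobs on a dark, sparsely noisy background; the
# contract is mask-band compliance and exactly known onset frames, not
# photorealism.

#' Configuration for the frame-sequence simulator
#'
#' Defaults mirror the latency test protocol: 33 LED cycles of 1 s on / 2 s
#' off recorded by a 120 Hz camera, with the response dot lagging each LED
#' onset by a fixed number of frames.
#'
#' @param rng_seed integer seed (background noise).
#' @param fps camera frame rate, Hz.
#' @param frame_duration_ms optional exact frame duration; when given it
#'   overrides `fps` (`fps = 1000 / frame_duration_ms`) and fixes the
#'   timestamp spacing written to `frames.csv`.
#' @param n_cycles number of LED on/off cycles.
#' @param on_s,off_s LED on and off durations, seconds.
#' @param lag_frames frames between each LED onset and its response-dot
#'   onset; a scalar or one value per cycle.
#' @param scenario `"eye_detection"` (LED + green dot) or
#'   `"gaze_contingent"` (first/second LED pairs + persisting green dot +
#'   red dot lagging the second pair).
#' @param led_px,second_led_px,dot_px blob areas in pixels. They must
#'   respect the flag bands of the default masks: the LED blob in (10, 250),
#'   the second-LED blob above 300 (areas falling in the dead band
#'   \[250, 300\] are rejected), dots above 10.
#' @param area_jitter_px uniform per-frame jitter applied to each blob area
#'   (clipped to its flag band).
#' @param width,height frame size in pixels.
#' @param background background grey level in `[0, 1)`.
#' @param noise_frac fraction of background pixels given random noise.
#' @param noise_amplitude maximum noise value (kept below the mask value
#'   thresholds).
#' @return list of class `frame_sim_config`.
#' @export
frame_sim_config <- function(rng_seed = 1L, fps = 120, frame_duration_ms = NULL,
                             n_cycles = 33L, on_s = 1, off_s = 2,
                             lag_frames = 7L,
                             scenario = c("eye_detection", "gaze_contingent"),
                             led_px = 100L, second_led_px = 400L, dot_px = 100L,
                             area_jitter_px = 0L,
                             width = 320L, height = 240L,
                             background = 0.03, noise_frac = 0.005,
                             noise_amplitude = 0.12) {
  scenario <- match.arg(scenario)
  if (!is.null(frame_duration_ms)) fps <- 1000 / frame_duration_ms
  stopifnot(fps > 0, n_cycles >= 1, on_s > 0, off_s >= 0, all(lag_frames >= 0),
            length(lag_frames) %in% c(1L, n_cycles))
  check_band <- function(px, what, lo, hi = Inf) {
    if (px >= 250 && px <= 300)
      stop(sprintf("gazeqc_dead_band: %s area %d lies in the 250-300 px dead band between the first/second LED flag bands",
                   what, px), call. = FALSE)
    if (px <= lo || px >= hi)
      stop(sprintf("gazeqc_bad_blob: %s area %d outside its flag band (%s, %s)",
                   what, px, lo, hi), call. = FALSE)
  }
  check_band(led_px, "led", 10, 250)
  check_band(dot_px, "dot", 10)
  if (scenario == "gaze_contingent") check_band(second_led_px, "second_led", 300)
  structure(list(rng_seed = as.integer(rng_seed), fps = fps,
                 frame_duration_ms = frame_duration_ms,
                 n_cycles = as.integer(n_cycles), on_s = on_s, off_s = off_s,
                 lag_frames = as.integer(lag_frames), scenario = scenario,
                 led_px = as.integer(led_px),
                 second_led_px = as.integer(second_led_px),
                 dot_px = as.integer(dot_px),
                 area_jitter_px = as.integer(area_jitter_px),
                 width = as.integer(width), height = as.integer(height),
                 background = background, noise_frac = noise_frac,
                 noise_amplitude = noise_amplitude),
            class = "frame_sim_config")
}

# paint `area` pixels of colour `col` as a compact block with its top-left
# corner at (row0, col0)
paint_blob <- function(img, row0, col0, area, col) {
  side <- ceiling(sqrt(area))
  k <- 0L
  for (r in seq_len(side)) {
    for (c in seq_len(side)) {
      if (k >= area) break
      img[row0 + r - 1L, col0 + c - 1L, ] <- col
      k <- k + 1L
    }
  }
  img
}

#' Render a synthetic LED/dot frame sequence
#'
#' Writes `frame_%06d.png` images, a `frames.csv` timestamp index, and a
#' `ground_truth.json` file (onset frames per event type, per-cycle lags,
#' frame duration) to `out_dir`.
#'
#' In the eye-detection scenario each cycle shows the LED reflection blob
#' for `on_s` seconds, with the green dot switching on `lag_frames` frames
#' after the LED onset and off the same number of frames after the LED
#' offset. In the gaze-contingent scenario the first LED pair is followed
#' immediately by the (larger) second pair; the green dot appears after the
#' first-pair onset and persists across the switch — an eye is still
#' detected — while the red dot lags the second-pair onset.
#'
#' @param cfg a [frame_sim_config()].
#' @param out_dir output directory (created; existing frames are removed).
#' @return invisibly, a list with `dir`, `n_frames`, and `truth` (the
#'   ground-truth list also written as JSON).
#' @export
render_frame_sequence <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "frame_sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old <- list.files(out_dir, pattern = "^frame_\\d+\\.png$", full.names = TRUE)
  if (length(old)) file.remove(old)

  fd_s <- if (!is.null(cfg$frame_duration_ms)) cfg$frame_duration_ms / 1000
          else 1 / cfg$fps
  on_f <- max(1L, round(cfg$on_s / fd_s))
  off_f <- round(cfg$off_s / fd_s)
  lags <- rep(cfg$lag_frames, length.out = cfg$n_cycles)
  gc_mode <- cfg$scenario == "gaze_contingent"
  cycle_f <- if (gc_mode) 2L * on_f + off_f else on_f + off_f
  n_frames <- cfg$n_cycles * cycle_f + max(lags) + 2L

  w <- cfg$width; h <- cfg$height
  # blob anchor points (top-left corners), scaled to the frame
  at <- function(fy, fx) c(max(1L, round(fy * h)), max(1L, round(fx * w)))
  p_led <- at(0.10, 0.10)
  p_led2 <- at(0.45, 0.10)
  p_green <- at(0.10, 0.60)
  p_red <- at(0.45, 0.60)
  col_led <- c(1, 0.92, 0.95)     # near-white reflection: low S, high V
  col_green <- c(0.10, 0.90, 0.10)
  col_red <- c(0.90, 0.05, 0.10)

  cyc0 <- (seq_len(cfg$n_cycles) - 1L) * cycle_f  # frame before each cycle
  led_onsets <- cyc0 + 1L
  led2_onsets <- if (gc_mode) cyc0 + on_f + 1L else integer(0)
  dot_onsets <- (if (gc_mode) led2_onsets else led_onsets) + lags
  green_onsets <- led_onsets + lags

  in_window <- function(i, onsets, len) {
    k <- findInterval(i, onsets)
    k >= 1L && i < onsets[k] + len
  }

  idx_csv <- data.frame(index = seq_len(n_frames),
                        t_seconds = (seq_len(n_frames) - 1L) * fd_s)

  with_seed(cfg$rng_seed, {
    npx <- w * h
    n_noise <- max(0L, round(cfg$noise_frac * npx))
    jit <- function(base, lo, hi) {
      if (cfg$area_jitter_px == 0L) return(base)
      v <- base + sample.int(2L * cfg$area_jitter_px + 1L, 1L) - cfg$area_jitter_px - 1L
      min(max(v, lo), hi)
    }
    for (i in seq_len(n_frames)) {
      img <- array(cfg$background, dim = c(h, w, 3L))
      if (n_noise > 0L) {
        pix <- sample.int(npx, n_noise)
        vals <- stats::runif(n_noise * 3L, 0, cfg$noise_amplitude)
        rr <- (pix - 1L) %% h + 1L
        cc <- (pix - 1L) %/% h + 1L
        img[cbind(rep(rr, 3L), rep(cc, 3L), rep(1:3, each = n_noise))] <- vals
      }
      if (gc_mode) {
        if (in_window(i, led_onsets, on_f))
          img <- paint_blob(img, p_led[1], p_led[2],
                            jit(cfg$led_px, 11L, 249L), col_led)
        if (in_window(i, led2_onsets, on_f))
          img <- paint_blob(img, p_led2[1], p_led2[2],
                            jit(cfg$second_led_px, 301L, Inf), col_led)
        if (in_window(i, green_onsets, 2L * on_f))
          img <- paint_blob(img, p_green[1], p_green[2],
                            jit(cfg$dot_px, 11L, Inf), col_green)
        if (in_window(i, dot_onsets, on_f))
          img <- paint_blob(img, p_red[1], p_red[2],
                            jit(cfg$dot_px, 11L, Inf), col_red)
      } else {
        if (in_window(i, led_onsets, on_f))
          img <- paint_blob(img, p_led[1], p_led[2],
                            jit(cfg$led_px, 11L, 249L), col_led)
        if (in_window(i, dot_onsets, on_f))
          img <- paint_blob(img, p_green[1], p_green[2],
                            jit(cfg$dot_px, 11L, Inf), col_green)
      }
      png::writePNG(img, file.path(out_dir, sprintf("frame_%06d.png", i)))
    }
  })

  utils::write.csv(idx_csv, file.path(out_dir, "frames.csv"), row.names = FALSE)
  truth <- list(scenario = cfg$scenario,
                n_frames = n_frames,
                frame_duration_ms = fd_s * 1000,
                fps = 1 / fd_s,
                lag_frames = lags,
                led_onsets = led_onsets,
                second_led_onsets = led2_onsets,
                dot_onsets = dot_onsets)
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = out_dir, n_frames = n_frames, truth = truth))
}
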