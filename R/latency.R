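# Video-based end-to-end latency estimation: HSV colour-mask segmentation,
# pixel-count flagging, onset detection, interval counting, and the median
# frame-count latency summary.

#' Define an HSV segmentation mask
#'
#' A mask selects pixels whose hue/saturation/value triple lies inside a
#' box, and turns the per-frame pixel count into a boolean event flag via
#' strict count bounds: a frame flags when `count > min_pixels` and (when a
#' maximum is set) `count < max_pixels`. The hue window may wrap through 0
#' (`hsv_low[1] > hsv_high[1]`), as red windows do.
#'
#' @param name mask name; conventionally one of `"led"`, `"first_led"`,
#'   `"second_led"`, `"green_dot"`, `"red_dot"`.
#' @param hsv_low,hsv_high length-3 lower/upper HSV bounds, each channel in
#'   `[0, 1]`.
#' @param min_pixels strict lower flag bound on the pixel count.
#' @param max_pixels strict upper flag bound, or `Inf` for none.
#' @return object of class `mask_spec`.
#' @export
mask_spec <- function(name, hsv_low, hsv_high, min_pixels = 10, max_pixels = Inf) {
  stopifnot(length(hsv_low) == 3L, length(hsv_high) == 3L, min_pixels >= 0)
  if (any(hsv_low[2:3] > hsv_high[2:3]))
    stop("gazeqc_bad_mask: saturation/value low bound exceeds high bound",
         call. = FALSE)
  structure(list(name = name, hsv_low = as.numeric(hsv_low),
                 hsv_high = as.numeric(hsv_high),
                 min_pixels = min_pixels, max_pixels = max_pixels),
            class = "mask_spec")
}

#' Default mask specifications per scenario
#'
#' The eye-detection scenario needs a mask for the infrared LED reflection
#' (low saturation, high value — the reflection is near-white on camera)
#' and one for the tracker's green pupil-on dot; both flag above 10 pixels.
#' The gaze-contingent scenario distinguishes the first LED pair (flag band
#' 10–250 pixels) from the larger second pair (flag above 300 pixels) and
#' adds the red pupil-shift dot; the red hue window wraps through 0.
#'
#' @param scenario `"eye_detection"` or `"gaze_contingent"`.
#' @return named list of [mask_spec()]s.
#' @export
default_mask_specs <- function(scenario = c("eye_detection", "gaze_contingent")) {
  scenario <- match.arg(scenario)
  led_lo <- c(0, 0, 0.7); led_hi <- c(1, 0.3, 1)
  green <- mask_spec("green_dot", c(0.25, 0.4, 0.4), c(0.45, 1, 1), min_pixels = 10)
  if (scenario == "eye_detection") {
    list(led = mask_spec("led", led_lo, led_hi, min_pixels = 10),
         green_dot = green)
  } else {
    list(first_led = mask_spec("first_led", led_lo, led_hi,
                               min_pixels = 10, max_pixels = 250),
         second_led = mask_spec("second_led", led_lo, led_hi, min_pixels = 300),
         green_dot = green,
         red_dot = mask_spec("red_dot", c(0.95, 0.4, 0.4), c(0.05, 1, 1),
                             min_pixels = 10))
  }
}

# Vectorised RGB -> HSV for flat channel vectors in [0, 1]
rgb_to_hsv_vec <- function(r, g, b) {
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- mx - mn
  v <- mx
  s <- ifelse(mx > 0, d / mx, 0)
  h <- numeric(length(r))
  idx <- d > 0
  if (any(idx)) {
    rr <- r[idx]; gg <- g[idx]; bb <- b[idx]; dd <- d[idx]; mm <- mx[idx]
    hh <- numeric(sum(idx))
    i1 <- mm == rr
    i2 <- !i1 & mm == gg
    i3 <- !i1 & !i2
    hh[i1] <- ((gg[i1] - bb[i1]) / dd[i1]) %% 6
    hh[i2] <- (bb[i2] - rr[i2]) / dd[i2] + 2
    hh[i3] <- (rr[i3] - gg[i3]) / dd[i3] + 4
    h[idx] <- hh / 6
  }
  list(h = h, s = s, v = v)
}

# count mask membership for several specs over one frame, computing HSV
# once and only for pixels that can pass the cheapest (value) bound
mask_counts_frame <- function(frame, specs) {
  if (length(frame) == 0L)
    stop("gazeqc_empty_image: cannot count pixels of an empty image", call. = FALSE)
  dm <- dim(frame)
  if (is.null(dm) || length(dm) != 3L || dm[3] < 3L)
    stop("gazeqc_bad_image: expected an H x W x 3 RGB array", call. = FALSE)
  r <- as.vector(frame[, , 1]); g <- as.vector(frame[, , 2]); b <- as.vector(frame[, , 3])
  v_all <- pmax(r, g, b)
  v_floor <- min(vapply(specs, function(sp) sp$hsv_low[3], 0))
  cand <- which(v_all >= v_floor)
  out <- integer(length(specs))
  names(out) <- names(specs)
  if (!length(cand)) return(out)
  hsv <- rgb_to_hsv_vec(r[cand], g[cand], b[cand])
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    keep <- hsv$s >= sp$hsv_low[2] & hsv$s <= sp$hsv_high[2] &
            hsv$v >= sp$hsv_low[3] & hsv$v <= sp$hsv_high[3]
    h <- hsv$h[keep]
    lo <- sp$hsv_low[1]; hi <- sp$hsv_high[1]
    out[j] <- if (lo <= hi) sum(h >= lo & h <= hi) else sum(h >= lo | h <= hi)
  }
  out
}

#' Count pixels matching an HSV mask
#'
#' Converts an RGB frame to HSV and counts the pixels inside the mask's
#' HSV box (hue wrap-around supported; bounds inclusive).
#'
#' @param frame H x W x 3 RGB array with values in `[0, 1]` (as returned by
#'   `png::readPNG`).
#' @param spec a [mask_spec()].
#' @return integer pixel count.
#' @export
hsv_pixel_count <- function(frame, spec) {
  unname(mask_counts_frame(frame, list(spec))[1])
}

#' Open a rendered / recorded frame sequence
#'
#' A frame sequence is a directory of `frame_%06d.png` images plus an
#' optional `frames.csv` (columns `index`, `t_seconds`). When the timestamp
#' file is absent, times are derived from the frame index and `fps`.
#'
#' @param dir directory containing the frames.
#' @param fps fallback frame rate when no timestamp file exists.
#' @return object of class `frame_sequence`: list with `paths`, `t`
#'   (seconds), `n`, `fps`.
#' @export
read_frame_sequence <- function(dir, fps = 120) {
  if (!dir.exists(dir))
    stop(sprintf("gazeqc_missing_dir: frame directory not found: %s", dir),
         call. = FALSE)
  paths <- sort(list.files(dir, pattern = "^frame_\\d+\\.(png|PNG)$",
                           full.names = TRUE))
  if (!length(paths))
    stop(sprintf("gazeqc_no_frames: no frame_*.png files in %s", dir),
         call. = FALSE)
  ts_file <- file.path(dir, "frames.csv")
  if (file.exists(ts_file)) {
    ts <- utils::read.csv(ts_file)
    if (!all(c("index", "t_seconds") %in% names(ts)))
      stop("gazeqc_missing_column: frames.csv needs columns index, t_seconds",
           call. = FALSE)
    ts <- ts[order(ts$index), ]
    t <- ts$t_seconds[seq_along(paths)]
    from_ts <- TRUE
  } else {
    t <- (seq_along(paths) - 1L) / fps
    from_ts <- FALSE
  }
  structure(list(paths = paths, t = t, n = length(paths), fps = fps,
                 timestamps_from_file = from_ts),
            class = "frame_sequence")
}

#' Per-frame mask pixel counts
#'
#' @param frames a [read_frame_sequence()] object.
#' @param specs named list of [mask_spec()]s.
#' @return integer matrix, one row per frame, one column per mask.
#' @export
frame_mask_counts <- function(frames, specs) {
  stopifnot(inherits(frames, "frame_sequence"))
  out <- matrix(0L, frames$n, length(specs),
                dimnames = list(NULL, names(specs)))
  for (i in seq_len(frames$n)) {
    img <- png::readPNG(frames$paths[i])
    out[i, ] <- mask_counts_frame(img, specs)
  }
  out
}

#' Turn pixel counts into event flags
#'
#' A frame flags a mask when its pixel count is strictly greater than the
#' mask's `min_pixels` and, when the mask has a `max_pixels` bound,
#' strictly smaller than it. Counts exactly on a bound never flag.
#'
#' @param counts matrix from [frame_mask_counts()] (or a vector for one mask).
#' @param specs the matching [mask_spec()] list (or single spec).
#' @return logical matrix (or vector) of flags.
#' @export
flag_frames <- function(counts, specs) {
  if (inherits(specs, "mask_spec")) {
    return(counts > specs$min_pixels & counts < specs$max_pixels)
  }
  out <- counts
  mode(out) <- "logical"
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    out[, j] <- counts[, j] > sp$min_pixels & counts[, j] < sp$max_pixels
  }
  out
}

#' Detect event onsets in a flag sequence
#'
#' An onset is a rising edge: frame `i` flags while the preceding
#' `debounce` frames do not. The first frame counts as an onset when it
#' flags.
#'
#' @param flags logical vector.
#' @param debounce number of preceding frames required to be off.
#' @return integer vector of onset frame indices (1-based).
#' @export
detect_onsets <- function(flags, debounce = 3L) {
  stopifnot(debounce >= 1)
  n <- length(flags)
  if (!n) return(integer(0))
  onsets <- integer(0)
  for (i in seq_len(n)) {
    if (!flags[i]) next
    lo <- max(1L, i - debounce)
    if (i == 1L || !any(flags[lo:(i - 1L)])) onsets <- c(onsets, i)
  }
  onsets
}

#' Count frames between LED and response-dot onsets
#'
#' For each LED onset, finds the first dot onset at or after it and before
#' the next LED onset, and records the elapsed frame count. LED events with
#' no matching dot onset in their window are dropped from the intervals and
#' counted separately.
#'
#' @param led_onsets,dot_onsets sorted onset frame indices.
#' @return list `intervals` (integer frame counts) and `n_dropped`.
#' @export
count_intervals <- function(led_onsets, dot_onsets) {
  intervals <- integer(0)
  dropped <- 0L
  n_led <- length(led_onsets)
  for (k in seq_len(n_led)) {
    lo <- led_onsets[k]
    hi <- if (k < n_led) led_onsets[k + 1L] else Inf
    cand <- dot_onsets[dot_onsets >= lo & dot_onsets < hi]
    if (length(cand)) intervals <- c(intervals, cand[1] - lo)
    else dropped <- dropped + 1L
  }
  list(intervals = as.integer(intervals), n_dropped = dropped)
}

#' Summarise intervals as a latency estimate
#'
#' End-to-end latency is the median of the frame counts elapsed between LED
#' and dot onsets, multiplied by the mean frame duration (from timestamps
#' when available, else `1000 / fps` ms). Even-length medians use the
#' midpoint convention. A one-sample Kolmogorov–Smirnov test of the
#' intervals against a normal distribution with the sample mean and SD is
#' attached for reference; non-normal intervals are common and the median
#' remains the headline statistic.
#'
#' @param intervals integer frame counts.
#' @param frame_times optional per-frame timestamps, seconds.
#' @param fps frame rate used when no timestamps are given.
#' @param scenario label stored in the result.
#' @param n_dropped LED events with no matching dot onset.
#' @return object of class `latency_result`: `scenario`,
#'   `intervals_frames`, `median_frames`, `mean_frame_duration_ms`,
#'   `latency_ms`, `ks_stat`, `ks_p`, `n_events`, `n_dropped`.
#' @export
latency_summary <- function(intervals, frame_times = NULL, fps = 120,
                            scenario = "eye_detection", n_dropped = 0L) {
  if (!length(intervals))
    stop("gazeqc_no_events: no LED/dot intervals found; inspect the mask specs and flag thresholds",
         call. = FALSE)
  mfd <- if (!is.null(frame_times) && length(frame_times) > 1L)
    mean(diff(frame_times)) * 1000 else 1000 / fps
  med <- stats::median(intervals)
  ks <- if (length(intervals) > 1L && stats::sd(intervals) > 0) {
    k <- suppressWarnings(stats::ks.test(intervals, "pnorm",
                                         mean(intervals), stats::sd(intervals)))
    list(stat = unname(k$statistic), p = unname(k$p.value))
  } else list(stat = NA_real_, p = NA_real_)
  structure(
    list(scenario = scenario, intervals_frames = as.integer(intervals),
         median_frames = med, mean_frame_duration_ms = mfd,
         latency_ms = med * mfd, ks_stat = ks$stat, ks_p = ks$p,
         n_events = length(intervals), n_dropped = as.integer(n_dropped)),
    class = "latency_result")
}

#' @export
print.latency_result <- function(x, ...) {
  cat(sprintf("<latency_result> %s: median %.3g frames x %.3f ms/frame = %.2f ms (%d events, %d dropped)\n",
              x$scenario, x$median_frames, x$mean_frame_duration_ms,
              x$latency_ms, x$n_events, x$n_dropped))
  invisible(x)
}

#' Run a full latency scenario on a frame sequence
#'
#' Computes mask pixel counts for every frame, flags frames, detects LED
#' and response-dot onsets, pairs them, and summarises the intervals as a
#' median latency. The eye-detection scenario pairs the LED mask with the
#' green dot; the gaze-contingent scenario pairs the second LED pair with
#' the red dot (the green dot may stay on throughout, since an eye remains
#' detected, and does not participate in the pairing).
#'
#' @param frames a [read_frame_sequence()] object or a directory path.
#' @param scenario `"eye_detection"` or `"gaze_contingent"`.
#' @param specs named list of [mask_spec()]s; defaults per scenario.
#' @param debounce onset debounce in frames.
#' @param fps fallback frame rate.
#' @param counts optional precomputed [frame_mask_counts()] matrix.
#' @return a [latency_summary()] result with the per-frame `counts` matrix
#'   attached as attribute `"counts"`.
#' @export
run_scenario <- function(frames, scenario = c("eye_detection", "gaze_contingent"),
                         specs = NULL, debounce = 3L, fps = 120,
                         counts = NULL) {
  scenario <- match.arg(scenario)
  if (is.character(frames)) frames <- read_frame_sequence(frames, fps = fps)
  if (is.null(specs)) specs <- default_mask_specs(scenario)
  need <- if (scenario == "eye_detection") c("led", "green_dot")
          else c("second_led", "red_dot")
  miss <- setdiff(need, names(specs))
  if (length(miss))
    stop(sprintf("gazeqc_mask_mismatch: scenario %s needs mask spec(s): %s",
                 scenario, paste(miss, collapse = ", ")), call. = FALSE)
  if (is.null(counts)) counts <- frame_mask_counts(frames, specs)
  flags <- flag_frames(counts, specs)
  led_key <- need[1]; dot_key <- need[2]
  led_on <- detect_onsets(flags[, led_key], debounce)
  dot_on <- detect_onsets(flags[, dot_key], debounce)
  ci <- count_intervals(led_on, dot_on)
  res <- latency_summary(ci$intervals,
                         frame_times = if (frames$timestamps_from_file) frames$t,
                         fps = frames$fps, scenario = scenario,
                         n_dropped = ci$n_dropped)
  attr(res, "counts") <- counts
  res
}

#' Write a latency result to disk
#'
#' Writes `latency.json`, `intervals.csv` and (when the counts matrix is
#' attached) `mask_counts.csv`.
#'
#' @param result a `latency_result`.
#' @param dir output directory.
#' @param provenance optional named list appended to the JSON.
#' @return invisibly, the output directory.
#' @export
write_latency_result <- function(result, dir, provenance = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- unclass(result)
  if (!is.null(provenance)) out$provenance <- provenance
  jsonlite::write_json(out, file.path(dir, "latency.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(data.frame(event = seq_along(result$intervals_frames),
                              interval_frames = result$intervals_frames),
                   file.path(dir, "intervals.csv"), row.names = FALSE)
  counts <- attr(result, "counts")
  if (!is.null(counts))
    utils::write.csv(cbind(frame = seq_len(nrow(counts)), as.data.frame(counts)),
                     file.path(dir, "mask_counts.csv"), row.names = FALSE)
  invisible(dir)
}
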