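#' Build a fixation-target presentation schedule
#'
#' Constructs the target schedule for a data-quality recording session on a
#' head-mounted display. Twenty-five targets are laid out on a 5 x 5 grid at
#' equal angular spacing from `-grid_extent_deg` to `+grid_extent_deg` both
#' horizontally and vertically, placed on a plane at the viewing distance
#' (angles are mapped to plane coordinates via the tangent). Each target is
#' shown `target_duration_s` seconds and repeated `repetitions` times, in a
#' seeded random order.
#'
#' Two protocols are supported:
#' \describe{
#'   \item{`head_still`}{targets are fixed to the headset (HMD-local frame);
#'     total stimulus time with defaults is 25 x 5 x 5 s = 625 s.}
#'   \item{`head_free`}{targets are fixed in the world frame and every
#'     presentation is followed by a 2 s central re-centering fixation at the
#'     world origin; total time with defaults is 25 x 5 x (5 + 2) s = 875 s.}
#' }
#'
#' @param condition `"head_still"` or `"head_free"`.
#' @param rng_seed integer seed controlling the presentation order.
#' @param grid_extent_deg half-width of the grid in degrees of visual angle
#'   (default 26.6, i.e. the grid spans +/- 26.6 deg).
#' @param viewing_distance_m distance from the eyes to the target plane, metres.
#' @param repetitions number of presentations per grid cell.
#' @param target_duration_s presentation time per target, seconds.
#' @param recenter_duration_s duration of the head-free central re-centering
#'   target, seconds.
#' @return An object of class `gaze_protocol`: a list with the constructor
#'   parameters and `$events`, a data frame with one row per scheduled event
#'   (columns `target_id`, `grid_row`, `grid_col`, `frame`, `pos_x_m`,
#'   `pos_y_m`, `pos_z_m`, `onset_s`, `offset_s`, `is_recentering`,
#'   `repetition`). Rows labelled `3c` sit at the grid centre, rows `1`/`5`
#'   at the top/bottom, columns `a`/`e` at the left/right.
#' @examples
#' p <- make_protocol("head_still", rng_seed = 1)
#' sum(p$events$offset_s - p$events$onset_s)  # 625
#' @export
make_protocol <- function(condition = c("head_still", "head_free"),
                          rng_seed = 1L,
                          grid_extent_deg = 26.6,
                          viewing_distance_m = 1,
                          repetitions = 5L,
                          target_duration_s = 5,
                          recenter_duration_s = 2) {
  condition <- match.arg(condition)
  if (!is.numeric(grid_extent_deg) || grid_extent_deg <= 0 || grid_extent_deg >= 60)
    stop("gazeqc_bad_protocol: grid_extent_deg must be in (0, 60)", call. = FALSE)
  if (viewing_distance_m <= 0)
    stop("gazeqc_bad_protocol: viewing_distance_m must be > 0", call. = FALSE)

  n_rows <- 5L; n_cols <- 5L
  angles <- seq(-grid_extent_deg, grid_extent_deg, length.out = n_cols)
  # row 1 (label "1") is the top row: vertical angle decreases with row index
  row_angle <- rev(angles)
  col_letters <- letters[seq_len(n_cols)]

  grid <- expand.grid(grid_row = 0:(n_rows - 1L), grid_col = 0:(n_cols - 1L))
  grid$target_id <- paste0(grid$grid_row + 1L, col_letters[grid$grid_col + 1L])
  grid$pos_x_m <- viewing_distance_m * tan(angles[grid$grid_col + 1L] * pi / 180)
  grid$pos_y_m <- viewing_distance_m * tan(row_angle[grid$grid_row + 1L] * pi / 180)
  grid$pos_z_m <- viewing_distance_m

  pres <- grid[rep(seq_len(nrow(grid)), times = repetitions), ]
  pres$repetition <- rep(seq_len(repetitions), each = nrow(grid))
  ord <- with_seed(rng_seed, sample.int(nrow(pres)))
  pres <- pres[ord, ]

  slot <- target_duration_s +
    if (condition == "head_free") recenter_duration_s else 0
  pres$onset_s <- (seq_len(nrow(pres)) - 1L) * slot
  pres$offset_s <- pres$onset_s + target_duration_s
  pres$frame <- if (condition == "head_still") "hmd_local" else "world"
  pres$is_recentering <- FALSE

  events <- pres[, c("target_id", "grid_row", "grid_col", "frame",
                     "pos_x_m", "pos_y_m", "pos_z_m",
                     "onset_s", "offset_s", "is_recentering", "repetition")]

  if (condition == "head_free") {
    rec <- events
    rec$target_id <- "center"
    rec$grid_row <- NA_integer_; rec$grid_col <- NA_integer_
    rec$pos_x_m <- 0; rec$pos_y_m <- 0; rec$pos_z_m <- 0
    rec$onset_s <- events$offset_s
    rec$offset_s <- rec$onset_s + recenter_duration_s
    rec$is_recentering <- TRUE
    events <- rbind(events, rec)
    events <- events[order(events$onset_s), ]
  }
  rownames(events) <- NULL

  structure(
    list(condition = condition,
         events = events,
         grid_extent_deg = grid_extent_deg,
         viewing_distance_m = viewing_distance_m,
         n_rows = n_rows, n_cols = n_cols,
         repetitions = as.integer(repetitions),
         target_duration_s = target_duration_s,
         recenter_duration_s = if (condition == "head_free") recenter_duration_s else NA_real_,
         rng_seed = as.integer(rng_seed)),
    class = "gaze_protocol")
}

#' @export
print.gaze_protocol <- function(x, ...) {
  cat(sprintf("<gaze_protocol> condition=%s, %d events, %.0f s stimulus time\n",
              x$condition, nrow(x$events),
              sum(x$events$offset_s - x$events$onset_s)))
  invisible(x)
}

schedule_columns <- c("target_id", "grid_row", "grid_col", "frame",
                      "pos_x_m", "pos_y_m", "pos_z_m",
                      "onset_s", "offset_s", "is_recentering", "repetition")

#' Write / read a target schedule as CSV
#'
#' @param protocol a `gaze_protocol` (or a bare event data frame).
#' @param path file path.
#' @return `read_schedule` returns a `gaze_protocol`; metadata fields not
#'   stored in the CSV (seed, durations) are reconstructed from the events.
#' @export
write_schedule <- function(protocol, path) {
  events <- if (inherits(protocol, "gaze_protocol")) protocol$events else protocol
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  if (!file.exists(path))
    stop(sprintf("gazeqc_missing_file: schedule file not found: %s", path),
         call. = FALSE)
  events <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(setdiff(schedule_columns, "repetition"), names(events))
  if (length(miss))
    stop(sprintf("gazeqc_missing_column: schedule is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  events$is_recentering <- as.logical(events$is_recentering)
  if (is.null(events$repetition)) {
    events$repetition <- stats::ave(seq_len(nrow(events)), events$target_id,
                                    FUN = seq_along)
  }
  condition <- if (any(events$frame == "world")) "head_free" else "head_still"
  tgt <- events[!events$is_recentering, ]
  dur <- tgt$offset_s - tgt$onset_s
  structure(
    list(condition = condition,
         events = events,
         grid_extent_deg = NA_real_,
         viewing_distance_m = stats::median(tgt$pos_z_m),
         n_rows = length(unique(tgt$grid_row)),
         n_cols = length(unique(tgt$grid_col)),
         repetitions = max(tgt$repetition),
         target_duration_s = stats::median(dur),
         recenter_duration_s = if (any(events$is_recentering))
           stats::median(events$offset_s[events$is_recentering] -
                         events$onset_s[events$is_recentering]) else NA_real_,
         rng_seed = NA_integer_),
    class = "gaze_protocol")
}
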