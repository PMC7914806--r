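# Gaze-log container and CSV I/O.
#
# A gaze session holds the raw per-sample tracker output: binocular gaze
# origins (millimetres, HMD-local frame) and unit direction vectors, per-eye
# validity flags, an optional world-frame combined gaze direction, and the
# HMD pose (unit orientation quaternion + world position in metres).

gaze_log_columns <- c(
  "t",
  "left_valid", "left_origin_x_mm", "left_origin_y_mm", "left_origin_z_mm",
  "left_dir_x", "left_dir_y", "left_dir_z",
  "right_valid", "right_origin_x_mm", "right_origin_y_mm", "right_origin_z_mm",
  "right_dir_x", "right_dir_y", "right_dir_z",
  "world_dir_x", "world_dir_y", "world_dir_z",
  "hmd_quat_w", "hmd_quat_x", "hmd_quat_y", "hmd_quat_z",
  "hmd_pos_x_m", "hmd_pos_y_m", "hmd_pos_z_m")

#' Construct a gaze session
#'
#' @param samples data frame with the gaze-log columns (see
#'   [read_gaze_log()] for the dialect). `world_dir_*` may be `NA` when the
#'   recording did not log a world-frame gaze vector.
#' @param schedule a [make_protocol()] schedule describing the target
#'   presentations the samples were recorded against.
#' @param nominal_rate_hz nominal tracker sampling rate (default 120 Hz).
#' @param metadata free-form named list.
#' @return An object of class `gaze_session`.
#' @export
gaze_session <- function(samples, schedule, nominal_rate_hz = 120,
                         metadata = list()) {
  stopifnot(is.data.frame(samples), nominal_rate_hz > 0)
  miss <- setdiff(setdiff(gaze_log_columns, c("world_dir_x", "world_dir_y", "world_dir_z")),
                  names(samples))
  if (length(miss))
    stop(sprintf("gazeqc_missing_column: gaze samples missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (is.unsorted(samples$t)) {
    bad <- which(diff(samples$t) < 0)[1] + 1L
    stop(sprintf("gazeqc_nonmonotonic_time: timestamps decrease at row %d", bad),
         call. = FALSE)
  }
  for (col in c("world_dir_x", "world_dir_y", "world_dir_z"))
    if (is.null(samples[[col]])) samples[[col]] <- NA_real_
  samples$left_valid <- as.logical(samples$left_valid)
  samples$right_valid <- as.logical(samples$right_valid)
  structure(list(samples = samples, schedule = schedule,
                 nominal_rate_hz = nominal_rate_hz, metadata = metadata),
            class = "gaze_session")
}

#' @export
print.gaze_session <- function(x, ...) {
  cat(sprintf("<gaze_session> %d samples, %.1f s, nominal %.0f Hz, condition=%s\n",
              nrow(x$samples), diff(range(x$samples$t)), x$nominal_rate_hz,
              if (!is.null(x$schedule)) x$schedule$condition else "?"))
  invisible(x)
}

#' Read / write a gaze log CSV
#'
#' The log is a UTF-8 CSV with a header row and columns `t`, `left_valid`,
#' `left_origin_x/y/z_mm`, `left_dir_x/y/z`, `right_valid`,
#' `right_origin_x/y/z_mm`, `right_dir_x/y/z`, `world_dir_x/y/z`,
#' `hmd_quat_w/x/y/z`, `hmd_pos_x/y/z_m`. Validity flags are 0/1; samples in
#' which an eye was not detected carry flag 0 and direction placeholder
#' `0,0,0` (the placeholder is preserved on round trip and ignored by
#' analysis code). Numeric fields round-trip to at least 9 significant
#' digits.
#'
#' @param path file path.
#' @param schedule optional [make_protocol()] schedule to attach.
#' @param nominal_rate_hz nominal sampling rate for the session.
#' @return `read_gaze_log` returns a [gaze_session()].
#' @export
read_gaze_log <- function(path, schedule = NULL, nominal_rate_hz = 120) {
  if (!file.exists(path))
    stop(sprintf("gazeqc_missing_file: gaze log not found: %s", path),
         call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- setdiff(gaze_log_columns, c("world_dir_x", "world_dir_y", "world_dir_z"))
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop(sprintf("gazeqc_missing_column: gaze log %s is missing column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  gaze_session(raw, schedule = schedule, nominal_rate_hz = nominal_rate_hz)
}

#' @rdname read_gaze_log
#' @param session a `gaze_session`.
#' @export
write_gaze_log <- function(session, path) {
  stopifnot(inherits(session, "gaze_session"))
  s <- session$samples
  out <- s[, intersect(gaze_log_columns, names(s))]
  out$left_valid <- as.integer(out$left_valid)
  out$right_valid <- as.integer(out$right_valid)
  num <- vapply(out, is.double, logical(1))
  for (col in names(out)[num]) out[[col]] <- fmt_num(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
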