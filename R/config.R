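# Run configuration: nested YAML with one block per pipeline stage.
# Unknown keys are rejected so that typos never silently fall back to a
# default.

#' Default run configuration
#'
#' Returns the full nested configuration with every tunable parameter at
#' its default. Blocks: `protocol` (schedule construction), `preprocess`
#' (discard window and head-phase labelling), `metrics` (BCEA proportion,
#' data-loss convention, percentile ranks), `latency` (masks, thresholds,
#' debounce, fps, scenario), `simulate` (generator parameters).
#'
#' @return nested named list.
#' @export
default_run_config <- function() {
  list(
    protocol = list(condition = "head_still", rng_seed = 1L,
                    grid_extent_deg = 26.6, viewing_distance_m = 1,
                    repetitions = 5L, target_duration_s = 5,
                    recenter_duration_s = 2),
    preprocess = list(discard_s = 0.5, threshold_dps = 10, min_run = 12L,
                      smooth_window = 5L),
    metrics = list(bcea_p = 0.5, data_loss_convention = "literal",
                   percentile_ranks = c(25, 50, 75, 90),
                   channels = "averaged"),
    latency = list(scenario = "eye_detection", debounce = 3L, fps = 120,
                   masks = NULL),
    simulate = list(offset_deg = 0, offset_direction = "radial",
                    noise_sigma_deg = 0, dropout_rate = 0,
                    dropout_moving_multiplier = 1, interocular_mm = 63,
                    rate_hz = 120,
                    frames = list(fps = 120, frame_duration_ms = NULL,
                                  n_cycles = 33L, on_s = 1, off_s = 2,
                                  lag_frames = 7L, led_px = 100L,
                                  second_led_px = 400L, dot_px = 100L,
                                  area_jitter_px = 0L, width = 320L,
                                  height = 240L)))
}

merge_config <- function(base, override, path = character()) {
  for (key in names(override)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(base))
      stop(sprintf("gazeqc_unknown_key: unknown configuration key '%s'", here),
           call. = FALSE)
    if (is.list(base[[key]]) && is.list(override[[key]]) &&
        !is.null(names(base[[key]]))) {
      base[[key]] <- merge_config(base[[key]], override[[key]], c(path, key))
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Read a YAML run configuration
#'
#' Reads a YAML file and merges it over [default_run_config()]. Keys not
#' present in the defaults are rejected with an error naming the offending
#' key.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return nested named list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path))
    stop(sprintf("gazeqc_missing_file: config file not found: %s", path),
         call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  merge_config(cfg, user)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

provenance_block <- function(cfg, seed = NULL) {
  list(package = "gazeqc",
       version = as.character(utils::packageVersion("gazeqc")),
       r_version = as.character(getRversion()),
       config_hash = config_hash(cfg),
       seed = seed,
       config = cfg)
}
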