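# Assembly of the full spatial quality report from a gaze session.

#' Spatial data-quality report for a gaze session
#'
#' Runs the complete spatial pipeline: segmentation (with onset discard and,
#' for head-free sessions, head-phase labelling), then per-target accuracy,
#' RMS precision, BCEA and data loss, then aggregate statistics: overall
#' mean +/- SD across targets, percentile summaries, a one-way ANOVA of
#' accuracy and precision across grid rows, and Bonferroni-corrected
#' pairwise row comparisons.
#'
#' Precision is computed per presentation (repetition) and averaged across
#' repetitions of the same target; BCEA pools the fixation points of all
#' repetitions of a target. Re-centering presentations are excluded from
#' the spatial metrics but counted in data-loss accounting. Targets with no
#' valid sample propagate as `NA` and are dropped from group statistics
#' with a warning.
#'
#' @param session a [gaze_session()] with schedule.
#' @param channels eye channels to analyse (any of `"averaged"`, `"left"`,
#'   `"right"`).
#' @param discard_s onset discard, seconds.
#' @param bcea_p BCEA contour proportion.
#' @param data_loss_convention see [data_loss_pct()].
#' @param percentile_ranks percentile ranks for the summary table.
#' @param threshold_dps,min_run,smooth_window head-phase parameters.
#' @return object of class `gaze_quality_report`: list with `per_target`
#'   (data frame: channel, target_id, grid_row/col, accuracy_deg,
#'   precision_rms_deg, bcea_deg2, n_samples_used, and for head-free
#'   sessions phase-split precision), `overall`, `percentiles`,
#'   `row_anova`, `posthoc`, `data_loss`, and the parameters used.
#' @export
quality_report <- function(session,
                           channels = "averaged",
                           discard_s = 0.5,
                           bcea_p = 0.5,
                           data_loss_convention = "literal",
                           percentile_ranks = c(25, 50, 75, 90),
                           threshold_dps = 10, min_run = 12L,
                           smooth_window = 5L) {
  stopifnot(inherits(session, "gaze_session"))
  head_free <- session$schedule$condition == "head_free"

  per_target <- list()
  loss_tab <- NULL
  for (ch in channels) {
    segs <- segment_by_target(session, discard_s = discard_s, channel = ch,
                              threshold_dps = threshold_dps, min_run = min_run,
                              smooth_window = smooth_window)
    metric_segs <- Filter(function(sg) !sg$is_recentering, segs)

    ids <- vapply(metric_segs, `[[`, "", "target_id")
    for (id in unique(ids)) {
      reps <- metric_segs[ids == id]
      acc_reps <- vapply(reps, accuracy_deg, 0)
      prec_reps <- vapply(reps, precision_rms_deg, 0)
      pts <- do.call(rbind, lapply(reps, function(sg) {
        s <- sg$samples[sg$samples$valid, ]
        if (!nrow(s)) return(NULL)
        gaze_dir_to_angles(as.matrix(s[, c("dir_x", "dir_y", "dir_z")]))
      }))
      bc <- if (!is.null(pts) && nrow(pts) >= 3L) bcea_deg2(pts, bcea_p)$area_deg2
            else NA_real_
      row <- data.frame(
        channel = ch, target_id = id,
        grid_row = reps[[1]]$grid_row, grid_col = reps[[1]]$grid_col,
        accuracy_deg = mean(acc_reps, na.rm = TRUE),
        precision_rms_deg = mean(prec_reps, na.rm = TRUE),
        bcea_deg2 = bc,
        n_samples_used = sum(vapply(reps, function(sg) sum(sg$samples$valid), 0L)))
      if (head_free) {
        row$precision_stable_deg <- mean(
          vapply(reps, precision_rms_deg, 0, phase = "stable"), na.rm = TRUE)
        row$precision_moving_deg <- mean(
          vapply(reps, precision_rms_deg, 0, phase = "moving"), na.rm = TRUE)
      }
      per_target[[length(per_target) + 1L]] <- row
    }

    if (ch == channels[[1]]) {
      # data loss over all retained samples, including re-centering windows
      all_s <- do.call(rbind, lapply(segs, `[[`, "samples"))
      n_exp <- sum(vapply(segs, `[[`, 0L, "n_expected"))
      loss_tab <- list(
        overall = data_loss_pct(nrow(all_s), sum(all_s$valid), n_exp,
                                data_loss_convention),
        n_samples = nrow(all_s), n_valid = sum(all_s$valid),
        n_expected = n_exp)
      if (head_free) {
        for (ph in c("stable", "moving")) {
          sel <- all_s$phase == ph
          loss_tab[[ph]] <- if (any(sel))
            data_loss_pct(sum(sel), sum(all_s$valid[sel]), sum(sel),
                          data_loss_convention) else NA_real_
        }
      }
    }
  }
  per_target <- do.call(rbind, per_target)

  n_missing <- sum(is.na(per_target$accuracy_deg))
  if (n_missing > 0)
    warning(sprintf("%d target(s) had no valid samples; excluded from group statistics",
                    n_missing))

  first_ch <- per_target[per_target$channel == channels[[1]], ]
  overall <- list(
    accuracy_mean_deg = mean(first_ch$accuracy_deg, na.rm = TRUE),
    accuracy_sd_deg = stats::sd(first_ch$accuracy_deg[!is.na(first_ch$accuracy_deg)]),
    precision_mean_deg = mean(first_ch$precision_rms_deg, na.rm = TRUE),
    precision_sd_deg = stats::sd(first_ch$precision_rms_deg[!is.na(first_ch$precision_rms_deg)]))

  pct <- list(
    accuracy = percentile_summary(first_ch$accuracy_deg, percentile_ranks),
    precision = percentile_summary(first_ch$precision_rms_deg, percentile_ranks))

  by_row <- function(metric) {
    split(first_ch[[metric]], first_ch$grid_row)
  }
  anova_res <- posthoc_res <- list()
  for (metric in c("accuracy_deg", "precision_rms_deg")) {
    g <- by_row(metric)
    anova_res[[metric]] <- tryCatch(row_anova(g), error = function(e) NULL)
    posthoc_res[[metric]] <- tryCatch(bonferroni_posthoc(g), error = function(e) NULL)
  }

  structure(
    list(per_target = per_target, overall = overall, percentiles = pct,
         row_anova = anova_res, posthoc = posthoc_res, data_loss = loss_tab,
         params = list(channels = channels, discard_s = discard_s,
                       bcea_p = bcea_p,
                       data_loss_convention = data_loss_convention,
                       threshold_dps = threshold_dps, min_run = min_run,
                       smooth_window = smooth_window),
         condition = session$schedule$condition),
    class = "gaze_quality_report")
}

#' @export
print.gaze_quality_report <- function(x, ...) {
  cat(sprintf("<gaze_quality_report> %s, %d target rows\n", x$condition,
              nrow(x$per_target)))
  cat(sprintf("  accuracy %.3f +/- %.3f deg, precision %.3f +/- %.3f deg, loss %.2f%%\n",
              x$overall$accuracy_mean_deg, x$overall$accuracy_sd_deg,
              x$overall$precision_mean_deg, x$overall$precision_sd_deg,
              x$data_loss$overall))
  invisible(x)
}

#' Write a quality report to disk
#'
#' Writes `report.json` (full nested report), `per_target.csv` (one row per
#' target x channel), `grid.csv` (5 x 5 layout with an accuracy line over a
#' precision line per grid row), and `percentiles.csv`.
#'
#' @param report a `gaze_quality_report`.
#' @param dir output directory (created if needed).
#' @param provenance optional named list appended to the JSON output.
#' @return invisibly, the output directory.
#' @export
write_quality_report <- function(report, dir, provenance = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_target, file.path(dir, "per_target.csv"),
                   row.names = FALSE)

  pt <- report$per_target[report$per_target$channel == report$params$channels[[1]], ]
  pt <- pt[!is.na(pt$grid_row), ]
  grid_lines <- list()
  for (r in sort(unique(pt$grid_row))) {
    sel <- pt[pt$grid_row == r, ]
    sel <- sel[order(sel$grid_col), ]
    grid_lines[[length(grid_lines) + 1L]] <-
      data.frame(grid_row = r + 1L, metric = "accuracy_deg",
                 t(stats::setNames(sel$accuracy_deg, letters[sel$grid_col + 1L])))
    grid_lines[[length(grid_lines) + 1L]] <-
      data.frame(grid_row = r + 1L, metric = "precision_rms_deg",
                 t(stats::setNames(sel$precision_rms_deg, letters[sel$grid_col + 1L])))
  }
  utils::write.csv(do.call(rbind, grid_lines), file.path(dir, "grid.csv"),
                   row.names = FALSE)

  pc <- rbind(cbind(metric = "accuracy_deg", report$percentiles$accuracy),
              cbind(metric = "precision_rms_deg", report$percentiles$precision))
  utils::write.csv(pc, file.path(dir, "percentiles.csv"), row.names = FALSE)

  out <- unclass(report)
  if (!is.null(provenance)) out$provenance <- provenance
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  invisible(dir)
}
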