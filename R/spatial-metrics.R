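# Spatial data-quality statistics: angular accuracy, RMS sample-to-sample
# precision, bivariate contour ellipse area, data-loss percentage,
# percentile summaries, and row-wise group comparisons.

#' Angle between gaze direction and target vector
#'
#' Computes the angular error (degrees of visual angle) between the measured
#' gaze direction and the eye-referenced target vector, as
#' `atan2(||g x t||, g . t)`. The two-argument arctangent form is
#' numerically stable for small angles, where `acos` of a near-1 dot
#' product loses precision.
#'
#' @param gaze_dir n x 3 matrix (or length-3 vector) of gaze directions.
#' @param target_vec n x 3 matrix (or length-3 vector) of target-to-eye
#'   vectors; need not be unit length.
#' @return angle(s) in degrees, in `[0, 180]`.
#' @export
angular_error_deg <- function(gaze_dir, target_vec) {
  g <- as_mat3(gaze_dir)
  tv <- as_mat3(target_vec)
  if (nrow(g) == 1L && nrow(tv) > 1L) g <- g[rep(1L, nrow(tv)), , drop = FALSE]
  if (nrow(tv) == 1L && nrow(g) > 1L) tv <- tv[rep(1L, nrow(g)), , drop = FALSE]
  if (any(row_norm(g) == 0) || any(row_norm(tv) == 0))
    stop("gazeqc_zero_vector: angular error undefined for zero-magnitude input",
         call. = FALSE)
  atan2(row_norm(cross_rows(g, tv)), dot_rows(g, tv)) * 180 / pi
}

#' Accuracy of a fixation segment
#'
#' Accuracy is the arithmetic mean of the per-sample angular errors between
#' the gaze direction and the target-to-eye vector, over valid samples.
#'
#' @param segment a `fixation_segment` from [segment_by_target()].
#' @param phase optional `"stable"` / `"moving"` restriction (head-free).
#' @return mean angular error in degrees, or `NA` if the segment has no
#'   valid sample.
#' @export
accuracy_deg <- function(segment, phase = NULL) {
  s <- segment$samples
  keep <- s$valid
  if (!is.null(phase)) keep <- keep & s$phase == phase
  if (!any(keep)) return(NA_real_)
  mean(angular_error_deg(as.matrix(s[keep, c("dir_x", "dir_y", "dir_z")]),
                         as.matrix(s[keep, c("tve_x", "tve_y", "tve_z")])))
}

#' RMS sample-to-sample precision
#'
#' Precision is the root mean square of the angular distances between
#' successive gaze directions. Only genuinely consecutive samples are
#' paired: pairs never straddle an invalid sample, a phase boundary, or a
#' segment boundary.
#'
#' @param directions n x 3 matrix of unit gaze directions in recording
#'   order, or a `fixation_segment`.
#' @param phase optional phase restriction when a segment is given.
#' @return RMS of inter-sample angular distances, degrees; `NA` when fewer
#'   than two pairable samples exist.
#' @export
precision_rms_deg <- function(directions, phase = NULL) {
  if (inherits(directions, "fixation_segment")) {
    s <- directions$samples
    keep <- s$valid
    if (!is.null(phase)) keep <- keep & s$phase == phase
    # adjacency: consecutive rows of the segment, both retained
    d <- as.matrix(s[, c("dir_x", "dir_y", "dir_z")])
    idx <- which(keep)
    if (length(idx) < 2L) return(NA_real_)
    pair <- idx[-length(idx)]
    adjacent <- diff(idx) == 1L
    if (!any(adjacent)) return(NA_real_)
    a <- d[pair[adjacent], , drop = FALSE]
    b <- d[pair[adjacent] + 1L, , drop = FALSE]
  } else {
    d <- as_mat3(directions)
    if (nrow(d) < 2L) return(NA_real_)
    a <- d[-nrow(d), , drop = FALSE]
    b <- d[-1, , drop = FALSE]
  }
  ang <- angular_error_deg(a, b)
  sqrt(mean(ang^2))
}

#' Bivariate contour ellipse area (BCEA)
#'
#' Fits the bivariate-normal contour ellipse that encompasses a proportion
#' `P` of fixation points around their mean, and returns its area:
#' `area = 2 * pi * k * sd_h * sd_v * sqrt(1 - rho^2)` with
#' `k = -ln(1 - P)`; `sd_h`, `sd_v` are the sample standard deviations of
#' the horizontal and vertical gaze angles and `rho` their correlation.
#'
#' @param points n x 2 matrix of (horizontal, vertical) gaze angles in
#'   degrees; see [gaze_dir_to_angles()].
#' @param P contour proportion, in (0, 1); default 0.5.
#' @return list with `area_deg2`, `center`, `sd_h`, `sd_v`, `rho`,
#'   `semi_axes` (lengths of the ellipse semi-axes, degrees), `angle_rad`
#'   (orientation of the major axis), and `degenerate` (TRUE when the
#'   points carry no spread).
#' @export
bcea_deg2 <- function(points, P = 0.5) {
  stopifnot(P > 0, P < 1)
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("gazeqc_bad_points: expected n x 2 points", call. = FALSE)
  if (nrow(pts) < 3L)
    stop("gazeqc_too_few_points: BCEA needs at least 3 points", call. = FALSE)
  k <- -log(1 - P)
  ctr <- colMeans(pts)
  sd_h <- stats::sd(pts[, 1]); sd_v <- stats::sd(pts[, 2])
  if (sd_h == 0 && sd_v == 0) {
    return(list(area_deg2 = 0, center = ctr, sd_h = 0, sd_v = 0, rho = NA_real_,
                semi_axes = c(0, 0), angle_rad = 0, k = k, P = P,
                degenerate = TRUE))
  }
  rho <- if (sd_h == 0 || sd_v == 0) 0 else stats::cor(pts[, 1], pts[, 2])
  area <- 2 * pi * k * sd_h * sd_v * sqrt(max(0, 1 - rho^2))
  cv <- stats::cov(pts)
  eg <- eigen(cv, symmetric = TRUE)
  semi <- sqrt(pmax(0, 2 * k * eg$values))
  list(area_deg2 = area, center = ctr, sd_h = sd_h, sd_v = sd_v, rho = rho,
       semi_axes = semi, angle_rad = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
       k = k, P = P, degenerate = FALSE)
}

#' Project gaze directions to planar angles
#'
#' Maps 3D gaze directions to (horizontal, vertical) visual angles in
#' degrees: horizontal = `atan2(x, z)`, vertical = `atan2(y, z)`.
#'
#' @param directions n x 3 matrix of gaze directions.
#' @return n x 2 matrix of angles, degrees.
#' @export
gaze_dir_to_angles <- function(directions) {
  d <- as_mat3(directions)
  cbind(h = atan2(d[, 1], d[, 3]) * 180 / pi,
        v = atan2(d[, 2], d[, 3]) * 180 / pi)
}

#' Data-loss percentage
#'
#' `100 * (n_samples - n_valid) / n_expected`, where `n_samples` is the
#' number of samples actually recorded in the retained analysis window
#' (after the onset discard), `n_valid` those with a valid gaze position,
#' and `n_expected` the count the nominal sampling rate predicts. The
#' `"expected"` convention replaces the numerator with
#' `n_expected - n_valid`, which additionally counts samples the tracker
#' never delivered; the literal convention is the default.
#'
#' @param n_samples,n_valid,n_expected sample counts.
#' @param convention `"literal"` or `"expected"`.
#' @return loss percentage.
#' @export
data_loss_pct <- function(n_samples, n_valid, n_expected,
                          convention = c("literal", "expected")) {
  convention <- match.arg(convention)
  if (any(n_expected <= 0))
    stop("gazeqc_bad_expected: n_expected must be > 0", call. = FALSE)
  num <- if (convention == "literal") n_samples - n_valid else n_expected - n_valid
  100 * num / n_expected
}

#' Percentile summary of a metric distribution
#'
#' Empirical percentiles (linear interpolation between order statistics) of
#' pooled per-target metric values.
#'
#' @param values numeric vector (NAs dropped).
#' @param ranks percentile ranks in (0, 100); default `c(25, 50, 75, 90)`.
#' @return data frame `rank`, `value`.
#' @export
percentile_summary <- function(values, ranks = c(25, 50, 75, 90)) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("gazeqc_empty_values: no values to summarise", call. = FALSE)
  data.frame(rank = ranks,
             value = unname(stats::quantile(values, ranks / 100, type = 7)))
}

#' One-way ANOVA across screen rows
#'
#' Standard one-way fixed-effects ANOVA testing whether a quality metric
#' differs across groups (typically the five horizontal rows of the target
#' grid, each group holding that row's per-target values).
#'
#' @param groups list of numeric vectors, one per group.
#' @return list `F`, `df1`, `df2`, `p`.
#' @export
row_anova <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L || any(vapply(groups, length, 1L) < 2L))
    stop("gazeqc_bad_groups: need >= 2 groups with >= 2 values each", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  fit <- stats::oneway.test(values ~ fac, var.equal = TRUE)
  list(F = unname(fit$statistic), df1 = unname(fit$parameter[1]),
       df2 = unname(fit$parameter[2]), p = unname(fit$p.value))
}

#' Bonferroni-corrected pairwise post-hoc t-tests
#'
#' Two-sample t-tests for every pair of groups, with the raw p-value
#' multiplied by the number of pairs (capped at 1).
#'
#' @param groups list of numeric vectors.
#' @param welch use Welch's unequal-variance test instead of the pooled
#'   test (default pooled).
#' @return data frame `group1`, `group2`, `t`, `p_raw`, `p_adj`.
#' @export
bonferroni_posthoc <- function(groups, welch = FALSE) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L || any(vapply(groups, length, 1L) < 2L))
    stop("gazeqc_bad_groups: need >= 2 groups with >= 2 values each", call. = FALSE)
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_along(groups))
  pairs <- utils::combn(length(groups), 2)
  m <- ncol(pairs)
  res <- apply(pairs, 2, function(ij) {
    a <- groups[[ij[1]]]; b <- groups[[ij[2]]]
    if (stats::sd(c(a, b)) == 0) return(c(t = 0, p = 1))
    tt <- stats::t.test(a, b, var.equal = !welch)
    c(t = unname(tt$statistic), p = unname(tt$p.value))
  })
  data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
             t = res["t", ], p_raw = res["p", ],
             p_adj = pmin(1, res["p", ] * m))
}
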