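test_that("angular error matches closed-form cases and the arccos oracle", {
  expect_equal(angular_error_deg(c(0, 0, 1), c(0, 0, 2)), 0)
  expect_equal(angular_error_deg(c(0, 0, 1), c(1, 0, 1)), 45)
  expect_equal(angular_error_deg(c(0, 0, 1), c(0, sin(5 * pi / 180), cos(5 * pi / 180))),
               5, tolerance = 1e-9)

  # oracle: acos of the normalised dot product, on random pairs
  set.seed(42)
  n <- 20000
  a <- matrix(rnorm(3 * n), ncol = 3)
  b <- matrix(rnorm(3 * n), ncol = 3)
  an <- a / sqrt(rowSums(a^2)); bn <- b / sqrt(rowSums(b^2))
  oracle <- acos(pmin(1, pmax(-1, rowSums(an * bn)))) * 180 / pi
  got <- angular_error_deg(a, b)
  keep <- oracle > 1e-3 * 180 / pi & oracle < 179
  expect_lt(max(abs(got[keep] - oracle[keep])), 1e-9)
  expect_true(all(got >= 0 & got <= 180))

  expect_error(angular_error_deg(c(0, 0, 0), c(0, 0, 1)), "gazeqc_zero_vector")
})

test_that("accuracy is the mean angle over valid samples", {
  proto <- one_target_protocol()
  t <- seq(0, 5 - 1 / 120, by = 1 / 120)
  # looking exactly at the central target (0,0,1): 0 degrees
  sess <- gaze_session(make_samples(t), proto)
  seg <- segment_by_target(sess)[[1]]
  expect_equal(accuracy_deg(seg), 0)

  # constant 2 degree offset, no noise -> exactly 2
  th <- 2 * pi / 180
  sess2 <- gaze_session(make_samples(t, dir = c(sin(th), 0, cos(th))), proto)
  seg2 <- segment_by_target(sess2)[[1]]
  # targets are re-referenced to the averaged eye at the origin
  expect_equal(accuracy_deg(seg2), 2, tolerance = 1e-9)

  # zero valid samples -> NA, not an error
  sess3 <- gaze_session(make_samples(t, valid = FALSE), proto)
  expect_true(is.na(accuracy_deg(segment_by_target(sess3)[[1]])))
})

test_that("accuracy under noise matches a direct simulation oracle", {
  # oracle: the generator's own per-sample realised errors; the pipeline
  # must reproduce their mean through I/O, segmentation and Eq-style math
  proto <- make_protocol("head_still", rng_seed = 9, repetitions = 1)
  sim <- simulate_gaze_session(gaze_sim_config(
    rng_seed = 9, protocol = proto, offset_deg = 2, noise_sigma_deg = 0.5))
  segs <- segment_by_target(sim$session)
  truth <- sim$truth$samples
  seg <- segs[[3]]
  m <- match(seg$samples$t, truth$t)
  expect_equal(accuracy_deg(seg), mean(truth$true_error_deg[m]),
               tolerance = 1e-6)
  # the mean sits above the injected 2 deg: noise-induced positive bias
  acc_all <- vapply(segs, accuracy_deg, 0)
  expect_gt(mean(acc_all), 2)
  expect_lt(mean(acc_all), 2.2)
})

test_that("RMS precision follows its definition and decouples from offset", {
  # constant direction -> 0
  d <- matrix(c(0, 0, 1), 50, 3, byrow = TRUE)
  expect_equal(precision_rms_deg(d), 0)

  # alternating between two vectors 1 degree apart -> exactly 1
  th <- 1 * pi / 180
  two <- rbind(c(0, 0, 1), c(sin(th), 0, cos(th)))
  d2 <- two[rep(1:2, 25), ]
  expect_equal(precision_rms_deg(d2), 1, tolerance = 1e-9)

  expect_true(is.na(precision_rms_deg(matrix(c(0, 0, 1), 1, 3))))

  # isotropic per-component sigma -> RMS ~= 2 sigma (Monte Carlo)
  set.seed(7)
  n <- 1e5
  sigma <- 0.4 * pi / 180
  pts <- cbind(rnorm(n, 0, sigma), rnorm(n, 0, sigma), 1)
  dirs <- pts / sqrt(rowSums(pts^2))
  rms <- precision_rms_deg(dirs)
  se <- 2 * 0.4 / sqrt(2 * n)  # rough MC standard error of the RMS
  expect_equal(rms, 2 * 0.4, tolerance = 5 * se / (2 * 0.4))

  # adding a constant offset leaves precision unchanged
  th0 <- 3 * pi / 180
  rot <- cbind(dirs[, 1] * cos(th0) + dirs[, 3] * sin(th0), dirs[, 2],
               -dirs[, 1] * sin(th0) + dirs[, 3] * cos(th0))
  expect_equal(precision_rms_deg(rot), rms, tolerance = 1e-6)
})

test_that("precision pairs never straddle invalid samples or phase boundaries", {
  proto <- one_target_protocol()
  t <- seq(0, 5 - 1 / 120, by = 1 / 120)
  th <- 5 * pi / 180
  s <- make_samples(t)
  # one wild invalid sample in the middle: if paired, RMS would explode
  mid <- 300
  s$left_dir_x[mid] <- sin(th); s$left_dir_z[mid] <- cos(th)
  s$right_dir_x[mid] <- sin(th); s$right_dir_z[mid] <- cos(th)
  s$left_valid[mid] <- FALSE; s$right_valid[mid] <- FALSE
  seg <- segment_by_target(gaze_session(s, proto))[[1]]
  expect_equal(precision_rms_deg(seg), 0)
})

test_that("BCEA matches the bivariate-normal closed form", {
  # degenerate cloud -> 0 with flag
  pts0 <- matrix(1, 10, 2)
  res0 <- bcea_deg2(pts0)
  expect_equal(res0$area_deg2, 0)
  expect_true(res0$degenerate)

  set.seed(11)
  n <- 1e5
  pts <- cbind(rnorm(n), rnorm(n))
  res <- bcea_deg2(pts, P = 0.5)
  expect_equal(res$area_deg2, 2 * pi * log(2), tolerance = 0.02)

  # empirical coverage of the fitted ellipse ~= P
  ctr <- res$center
  cv <- stats::cov(pts)
  ci <- solve(cv)
  dx <- sweep(pts, 2, ctr)
  md2 <- rowSums((dx %*% ci) * dx)
  cover <- mean(md2 <= 2 * res$k)
  expect_equal(cover, 0.5, tolerance = 0.02)

  # area strictly increasing in P
  areas <- vapply(c(0.3, 0.5, 0.7, 0.9),
                  function(p) bcea_deg2(pts, p)$area_deg2, 0)
  expect_true(all(diff(areas) > 0))

  expect_error(bcea_deg2(pts[1:2, ]), "gazeqc_too_few_points")
})

test_that("data loss follows the literal formula and its bounds", {
  expect_equal(data_loss_pct(100, 100, 100), 0)
  expect_equal(data_loss_pct(95, 90, 100), 5)
  expect_equal(data_loss_pct(95, 90, 100, convention = "expected"), 10)
  expect_error(data_loss_pct(10, 10, 0), "gazeqc_bad_expected")
  # bounds when n_samples <= n_expected
  set.seed(3)
  for (i in 1:50) {
    ne <- sample(50:200, 1); ns <- sample(0:ne, 1); nv <- sample(0:ns, 1)
    loss <- data_loss_pct(ns, nv, ne)
    expect_true(loss >= 0 && loss <= 100)
  }
})

test_that("percentile summary uses linear interpolation over the pooled pool", {
  expect_equal(percentile_summary(c(1, 2, 3, 4), 50)$value, 2.5)
  expect_equal(percentile_summary(rep(7, 20))$value, rep(7, 4))
  set.seed(13)
  v <- rnorm(5000)
  got <- percentile_summary(v, c(25, 50, 75, 90))$value
  oracle <- {
    sv <- sort(v)
    vapply(c(0.25, 0.5, 0.75, 0.9), function(p) {
      h <- (length(sv) - 1) * p + 1
      lo <- floor(h)
      sv[lo] + (h - lo) * (sv[min(lo + 1, length(sv))] - sv[lo])
    }, 0)
  }
  expect_equal(got, oracle, tolerance = 1e-12)
  # non-decreasing in rank
  expect_true(all(diff(got) >= 0))
})

test_that("row ANOVA agrees with brute-force sums of squares and t^2", {
  # identical group means with within-group spread -> F ~ 0
  g_eq <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  res_eq <- row_anova(g_eq)
  expect_equal(res_eq$F, 0)
  expect_equal(res_eq$p, 1)

  # two groups: F equals the square of the pooled t statistic
  a <- c(1.2, 2.3, 0.8, 1.9); b <- c(2.8, 3.1, 2.2)
  res2 <- row_anova(list(a, b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-12)

  # textbook toy against explicit sums of squares
  g <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  res <- row_anova(g)
  vals <- unlist(g); k <- 3; N <- 9
  gm <- mean(vals)
  ssb <- sum(vapply(g, function(x) length(x) * (mean(x) - gm)^2, 0))
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), 0))
  f_oracle <- (ssb / (k - 1)) / (ssw / (N - k))
  expect_equal(res$F, f_oracle, tolerance = 1e-12)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 6)

  expect_error(row_anova(list(1, c(1, 2))), "gazeqc_bad_groups")
})

test_that("Bonferroni post-hoc multiplies raw p by the pair count, capped", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res <- bonferroni_posthoc(g)
  expect_true(all(res$p_adj == 1))

  set.seed(5)
  g5 <- lapply(1:5, function(i) rnorm(6, mean = i / 3))
  res5 <- bonferroni_posthoc(g5)
  expect_equal(nrow(res5), 10)  # C(5, 2)
  for (r in seq_len(nrow(res5))) {
    raw <- stats::t.test(g5[[as.integer(res5$group1[r])]],
                         g5[[as.integer(res5$group2[r])]],
                         var.equal = TRUE)$p.value
    expect_equal(res5$p_adj[r], min(1, raw * 10), tolerance = 1e-12)
  }
})
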