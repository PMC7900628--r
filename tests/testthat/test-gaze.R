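# Point patterns, window clipping, quadrat test, distances, ellipses,
# dispersion, correlations.

test_that("window clipping keeps boundary points and reports fractions", {
  g <- data.frame(x_deg = c(0, 25, -20, 0, 5), y_deg = c(0, 0, 0, 11.25, -30),
                  group = c("A", "A", "B", "B", "B"))
  out <- clip_to_window(g)
  expect_equal(out$pattern$n, 3) # (0,0), (-20,0), (0,11.25) retained
  expect_equal(out$excluded_fraction, 2 / 5)
  expect_equal(unname(out$excluded_by_group["A"]), 1 / 2)
  expect_equal(unname(out$excluded_by_group["B"]), 1 / 3)
  # all inside: nothing excluded
  out2 <- clip_to_window(data.frame(x_deg = rep(0, 4), y_deg = rep(0, 4)))
  expect_equal(out2$excluded_fraction, 0)
})

test_that("excluded mass matches the bivariate normal rectangle", {
  set.seed(61)
  sx <- 9; sy <- 6
  g <- data.frame(x_deg = rnorm(2e5, 0, sx), y_deg = rnorm(2e5, 0, sy))
  out <- clip_to_window(g)
  p_in <- (pnorm(20 / sx) - pnorm(-20 / sx)) *
    (pnorm(11.25 / sy) - pnorm(-11.25 / sy))
  expect_lt(abs(out$excluded_fraction - (1 - p_in)), 0.003)
  # wider dispersion loses more points
  g2 <- data.frame(x_deg = rnorm(2e5, 0, 1.6 * sx),
                   y_deg = rnorm(2e5, 0, 1.6 * sy))
  expect_gt(clip_to_window(g2)$excluded_fraction, out$excluded_fraction)
})

test_that("quadrat test has the documented df and hand-checked statistic", {
  # evenly filled quadrats: statistic 0
  cx <- rep(seq(-16, 16, by = 8), each = 5)
  cy <- rep(seq(-9, 9, by = 4.5), times = 5)
  pp <- point_pattern(cx, cy)
  expect_warning(qt <- quadrat_test(pp, 5, 5), "below 5")
  expect_equal(qt$chi2, 0)
  expect_equal(qt$df, 24)
  expect_equal(qt$p, 1)
  # 2 x 2 partition with counts (40, 20, 20, 20)
  qx <- c(rep(-10, 40), rep(10, 20), rep(-10, 20), rep(10, 20))
  qy <- c(rep(6, 40), rep(6, 20), rep(-6, 20), rep(-6, 20))
  qt2 <- suppressWarnings(quadrat_test(point_pattern(qx, qy), 2, 2))
  expect_equal(qt2$chi2, (15^2 + 3 * 5^2) / 25)
  expect_equal(qt2$df, 3)
  expect_equal(sum(qt2$counts), 100)
  expect_error(quadrat_test(point_pattern(numeric(0), numeric(0))),
               "at least one")
})

test_that("quadrat test is roughly calibrated under CSR", {
  set.seed(62)
  rej <- mean(replicate(300, {
    pp <- point_pattern(runif(500, -20, 20), runif(500, -11.25, 11.25))
    quadrat_test(pp)$p < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("pairwise distances are enumerated correctly", {
  s <- pairwise_distance_summary(c(0, 3), c(0, 4))
  expect_equal(s$distances, 5)
  expect_equal(s$median, 5)
  s3 <- pairwise_distance_summary(c(0, 1, 2), c(0, 0, 0))
  expect_equal(sort(s3$distances), c(1, 1, 2))
  expect_equal(s3$median, 1)
  n <- 12
  sN <- pairwise_distance_summary(rnorm(n), rnorm(n))
  expect_length(sN$distances, n * (n - 1) / 2)
  expect_error(pairwise_distance_summary(1, 1), "at least 2")
})

test_that("groups with wider dispersion have larger pairwise medians", {
  set.seed(63)
  hits <- replicate(40, {
    a <- pairwise_distance_summary(rnorm(24, 0, 0.16), rnorm(24, 0, 0.16))
    b <- pairwise_distance_summary(rnorm(32, 0, 0.10), rnorm(32, 0, 0.10))
    a$median > b$median
  })
  expect_gte(mean(hits), 0.95)
})

test_that("variance ellipse matches the eigenstructure", {
  set.seed(64)
  x <- rnorm(5e4, 0, 2)
  y <- rnorm(5e4, 0, 2)
  e <- variance_ellipse(x, y)
  expect_equal(e$lambda_max / e$lambda_min, 1, tolerance = 0.05)
  expect_equal(e$area, pi * qchisq(0.95, 2) * sqrt(e$lambda_max * e$lambda_min))
  expect_false(e$degenerate)
  # collinear points are flagged with zero area
  ec <- variance_ellipse(1:10, 2 * (1:10))
  expect_true(ec$degenerate)
  expect_equal(ec$area, 0, tolerance = 1e-10)
  expect_error(variance_ellipse(1:2, 1:2), "at least 3")
})

test_that("the 95% ellipse covers 95% of Gaussian draws", {
  set.seed(65)
  n <- 4e4
  x <- rnorm(n, 1, 1.5)
  y <- 0.4 * x + rnorm(n, -1, 0.8)
  e <- variance_ellipse(x, y)
  S <- cov(cbind(x, y))
  ctr <- c(mean(x), mean(y))
  md2 <- stats::mahalanobis(cbind(x, y), ctr, S)
  inside <- mean(md2 <= qchisq(0.95, 2))
  expect_equal(inside, 0.95, tolerance = 0.012)
})

test_that("variance F test flags unequal variances only", {
  eq <- variance_f_test(2, 50, 2, 50)
  expect_equal(eq$F, 1)
  expect_equal(eq$p, 1)
  uneq <- variance_f_test(2, 200, 1, 200)
  expect_lt(uneq$p, 0.01)
  # major vs minor variance of an isotropic cloud is not significant
  set.seed(66)
  x <- rnorm(200); y <- rnorm(200)
  e <- variance_ellipse(x, y)
  iso <- variance_f_test(e$lambda_max, 200, e$lambda_min, 200)
  expect_gt(iso$p, 0.001)
  expect_error(variance_f_test(0, 10, 1, 10), "degenerate")
})

test_that("per-subject dispersion recovers known SDs and group ordering", {
  set.seed(67)
  mk <- function(sid, grp, sd0, n = 120) {
    data.frame(subject_id = sid, group = grp,
               noise_level = rep(c(10, 45), each = n / 2),
               x_deg = rnorm(n, 0, sd0), y_deg = rnorm(n, 0, sd0))
  }
  gz <- rbind(mk("A1", "A", 1.5), mk("A2", "A", 1.6), mk("A3", "A", 1.4),
              mk("B1", "B", 1.0), mk("B2", "B", 0.9), mk("B3", "B", 1.1))
  out <- per_subject_dispersion(gz, groups = c("A", "B"), n_draws = 500,
                                seed = 1)
  a1 <- out$cells$sd_total[out$cells$subject_id == "A1"]
  expect_equal(mean(a1), sqrt(2) * 1.5, tolerance = 0.15)
  expect_true(all(out$comparison$p_greater > 0.9))
  # single-point cells are skipped with a log entry
  gz1 <- rbind(gz, data.frame(subject_id = "C1", group = "A",
                              noise_level = 60, x_deg = 0, y_deg = 0))
  out1 <- per_subject_dispersion(gz1, groups = c("A", "B"), n_draws = 200)
  expect_equal(out1$skipped$subject_id, "C1")
  # identical points give zero dispersion
  gz0 <- data.frame(subject_id = "Z", group = "A", noise_level = 10,
                    x_deg = rep(1, 5), y_deg = rep(2, 5))
  out0 <- per_subject_dispersion(rbind(gz, gz0), groups = c("A", "B"),
                                 n_draws = 200)
  expect_equal(out0$cells$sd_total[out0$cells$subject_id == "Z"], 0)
})

test_that("gaze-area correlations recover planted couplings", {
  set.seed(68)
  n <- 40
  sd0 <- runif(n, 0.8, 2.4)
  gaze <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(subject_id = sprintf("S%02d", i),
               x_deg = rnorm(60, 0, sd0[i]), y_deg = rnorm(60, 0, sd0[i]))
  }))
  acc <- data.frame(subject_id = sprintf("S%02d", seq_len(n)),
                    prop_correct = 0.95 - 0.1 * sd0 + rnorm(n, 0, 0.02))
  rt <- data.frame(subject_id = sprintf("S%02d", seq_len(n)),
                   median_rt = 0.4 + 0.1 * sd0 + rnorm(n, 0, 0.02))
  out <- gaze_area_correlations(gaze, acc, rt)
  expect_lt(out$accuracy$r, 0)
  expect_lt(out$accuracy$p, 0.01)
  expect_gt(out$rt$r, 0)
  expect_lt(out$rt$p, 0.01)
  # constant area propagates the undefined-correlation error
  gaze_const <- do.call(rbind, lapply(1:5, function(i) {
    data.frame(subject_id = sprintf("S%02d", i),
               x_deg = c(-1, 0, 1, 0), y_deg = c(0, 1, 0, -1))
  }))
  acc5 <- acc[1:5, ]
  expect_error(gaze_area_correlations(gaze_const, acc5), "zero variance")
})
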