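# RT filtering, SDT categorization, Bayesian bootstrap, correlations,
# accuracy summaries.

test_that("RT filter keeps boundary values and logs exclusions", {
  tr <- data.frame(subject_id = rep("S01", 5),
                   rt_s = c(0.20, 0.25, 1.0, 4.0, 4.5))
  out <- filter_rt(tr)
  expect_equal(out$trials$rt_s, c(0.25, 1.0, 4.0))
  expect_equal(out$exclusions$n_excluded, 2)
  expect_equal(out$exclusions$n_total, 5)
  # all in range: identity; refiltering is idempotent
  ok <- data.frame(subject_id = "S02", rt_s = c(0.3, 1, 2))
  expect_equal(filter_rt(ok)$trials, ok)
  twice <- filter_rt(filter_rt(tr)$trials)
  expect_equal(twice$trials, out$trials, ignore_attr = TRUE)
  expect_equal(sum(twice$exclusions$n_excluded), 0)
})

test_that("observed exclusion fraction matches the gamma tail", {
  obs <- observer_params(rt_shift = 0.3, rt_scale = 0.5, rt_shape = 3,
                         rt_noise_slope = 0)
  set.seed(51)
  rt <- simulate_rt(2e5, obs, 0)
  frac <- mean(rt > 4.0) # lower bound unreachable: shift > 0.25
  tail_theory <- pgamma((4.0 - 0.3) / 0.5, shape = 3, lower.tail = FALSE)
  expect_lt(abs(frac - tail_theory), 0.15 * tail_theory)
  tr <- data.frame(subject_id = "S", rt_s = rt)
  expect_equal(nrow(filter_rt(tr)$trials), sum(rt <= 4))
})

test_that("SDT categorization is exhaustive and mutually exclusive", {
  tr <- data.frame(subject_id = "S01", noise_level = 10,
                   class = c("signal", "signal", "signal", "noise", "noise"),
                   response = c("yes", "yes", "no", "yes", "no"))
  s <- sdt_categorize(tr)
  expect_equal(s$hits, 2)
  expect_equal(s$misses, 1)
  expect_equal(s$false_alarms, 1)
  expect_equal(s$correct_rejections, 1)
  expect_equal(s$hit_rate, 2 / 3)
  expect_equal(s$fa_rate, 1 / 2)
  # a perfect responder has no misses or false alarms
  tr$response <- ifelse(tr$class == "signal", "yes", "no")
  s2 <- sdt_categorize(tr)
  expect_equal(s2$misses + s2$false_alarms, 0)
})

test_that("SDT counts conserve trial totals on random tables", {
  set.seed(53)
  for (rep in 1:5) {
    tr <- data.frame(
      subject_id = sample(c("A", "B"), 120, replace = TRUE),
      noise_level = sample(c(0, 45), 120, replace = TRUE),
      class = sample(c("signal", "noise"), 120, replace = TRUE),
      response = sample(c("yes", "no"), 120, replace = TRUE))
    s <- sdt_categorize(tr)
    expect_equal(sum(s$hits + s$misses + s$false_alarms +
                       s$correct_rejections), 120)
    expect_equal(s$hits_pct + s$misses_pct + s$false_alarms_pct +
                   s$correct_rejections_pct, rep(100, nrow(s)))
    for (i in seq_len(nrow(s))) {
      cell <- tr[tr$subject_id == s$subject_id[i] &
                   tr$noise_level == s$noise_level[i], ]
      expect_equal(s$hits[i] + s$misses[i], sum(cell$class == "signal"))
      expect_equal(s$false_alarms[i] + s$correct_rejections[i],
                   sum(cell$class == "noise"))
    }
  }
})

test_that("dprime correction handles perfect cells", {
  d <- sdt_dprime(30, 0, 0, 30)
  expect_true(is.finite(d$dprime))
  d_raw <- sdt_dprime(20, 10, 5, 25, correction = FALSE)
  expect_equal(d_raw$dprime, qnorm(20 / 30) - qnorm(5 / 30))
})

test_that("Bayesian bootstrap has Dirichlet-weight behaviour", {
  # constant data give a degenerate posterior
  b <- bayes_boot(rep(3.5, 10), "mean", n_draws = 200, seed = 1)
  expect_equal(b$ci_low, 3.5)
  expect_equal(b$ci_high, 3.5)
  expect_equal(b$draws, rep(3.5, 200))
  # default draw count is 4000
  expect_equal(bayes_boot(rnorm(5), seed = 1)$n_draws, 4000)
  # posterior mean ~ sample mean, posterior SD ~ classical SE
  set.seed(2)
  x <- rnorm(100)
  b <- bayes_boot(x, "mean", n_draws = 8000)
  expect_lt(abs(mean(b$draws) - mean(x)), 0.01)
  se <- sd(x) / sqrt(100)
  expect_lt(abs(sd(b$draws) - se), 0.05 * se)
  # convexity: mean-type draws stay inside the data range
  expect_true(all(b$draws >= min(x) & b$draws <= max(x)))
  expect_error(bayes_boot(1), "at least 2")
})

test_that("bootstrap interval width shrinks like 1/sqrt(n)", {
  set.seed(3)
  widths <- vapply(c(10, 100, 1000), function(n) {
    b <- bayes_boot(rnorm(n), "mean", n_draws = 2000)
    b$ci_high - b$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_equal(widths[1] / widths[3], sqrt(100), tolerance = 0.5 * sqrt(100))
})

test_that("group comparison reports a calibrated exceedance probability", {
  set.seed(4)
  cmp <- bayes_boot_compare(rnorm(40, 1), rnorm(40, 0), "mean",
                            n_draws = 2000)
  expect_gt(cmp$p_greater, 0.99)
  cmp_null <- bayes_boot_compare(rnorm(40), rnorm(40), "mean",
                                 n_draws = 2000)
  expect_gt(cmp_null$p_greater, 0.01)
  expect_lt(cmp_null$p_greater, 0.99)
})

test_that("Pearson correlation matches textbook formulas", {
  x <- c(1.2, 2.1, 2.9, 4.2, 5.1, 5.8, 7.3, 8.1, 9.4, 10.2)
  y <- c(2.3, 2.8, 4.1, 3.9, 5.6, 6.8, 6.4, 8.9, 9.1, 10.8)
  out <- pearson_ci(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  z <- atanh(r_hand)
  expect_equal(out$ci_low, tanh(z - qnorm(0.975) / sqrt(7)), tolerance = 1e-9)
  expect_equal(out$ci_high, tanh(z + qnorm(0.975) / sqrt(7)), tolerance = 1e-9)
  t_hand <- r_hand * sqrt(8 / (1 - r_hand^2))
  expect_equal(out$p, 2 * pt(-abs(t_hand), 8), tolerance = 1e-12)
  expect_equal(out$df, 8)
  # exact linear relations
  expect_equal(pearson_ci(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_ci(1:10, -(1:10))$r, -1)
  expect_error(pearson_ci(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("accuracy summary reproduces per-subject proportions", {
  tr <- toy_trials()
  out <- summarize_accuracy(tr, n_draws = 200, seed = 9)
  expect_equal(nrow(out$subjects), 4) # 2 subjects x 2 levels
  expect_true(all(out$subjects$prop_correct == 0.5))
  # a perfect responder scores 1 everywhere
  tr$correct <- TRUE
  out2 <- summarize_accuracy(tr, n_draws = 200, seed = 9)
  expect_true(all(out2$subjects$prop_correct == 1))
  # a guessing observer stays inside the binomial band for 60 trials
  set.seed(10)
  tr3 <- data.frame(subject_id = "S", group = "G", noise_level = 0,
                    correct = runif(60) < 0.5)
  out3 <- summarize_accuracy(tr3, n_draws = 200, seed = 1)
  expect_lt(abs(out3$subjects$prop_correct - 0.5),
            qnorm(0.999) * sqrt(0.25 / 60))
})
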