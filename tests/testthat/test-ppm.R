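# Inhomogeneous Poisson intensity models, likelihood-ratio tests,
# thinning simulation, and the inhomogeneous K function.

win <- c(-20, 20, -11.25, 11.25)

test_that("intercept-only fit equals the analytic homogeneous MLE", {
  set.seed(71)
  pp <- simulate_ipp(0.6, win)
  fit <- fit_ppm(pp, spatial_degree = 0)
  expect_equal(unname(coef(fit)), log(pp$n / 900), tolerance = 1e-4)
  # the fitted intensity integrates to the point count (score equation)
  expect_equal(fit$integral, pp$n, tolerance = 1e-3 * pp$n)
  # and is within 2 SE of the simulated truth
  expect_lt(abs(coef(fit) - log(0.6)), 2 * sqrt(vcov(fit)[1, 1]))
})

test_that("adding nested terms never lowers the log-likelihood", {
  set.seed(72)
  lam <- function(x, y) 0.8 * exp(-0.002 * x^2 - 0.004 * y^2)
  pp <- simulate_ipp(lam, win)
  f0 <- fit_ppm(pp, 0)
  f1 <- fit_ppm(pp, 1)
  f2 <- fit_ppm(pp, 2)
  expect_gte(f1$logLik, f0$logLik)
  expect_gte(f2$logLik, f1$logLik)
  lr <- lr_test(f0, f2)
  expect_equal(lr$df, 5)
  expect_gte(lr$chi2, 0)
  # identical models: nothing to test
  same <- lr_test(f2, f2)
  expect_equal(same$chi2, 0, tolerance = 1e-9)
  expect_equal(same$p, 1)
  expect_error(lr_test(f2, f1), "not nested")
})

test_that("log-quadratic coefficients are recovered from simulations", {
  beta <- c(-1.2, 0.01, -0.02, -0.004, -0.008, 0.002)
  lam <- function(x, y) exp(beta[1] + beta[2] * x + beta[3] * y +
                              beta[4] * x^2 + beta[5] * y^2 +
                              beta[6] * x * y)
  set.seed(73)
  cover <- matrix(NA, 10, 6)
  for (i in 1:10) {
    pp <- simulate_ipp(lam, win)
    fit <- fit_ppm(pp, 2)
    se <- sqrt(diag(vcov(fit)))
    cover[i, ] <- abs(coef(fit) - beta) <= qnorm(0.975) * se
  }
  # joint 95% coverage over 60 intervals
  expect_gte(mean(cover), 0.85)
})

test_that("categorical marks enter as covariates with the right df", {
  set.seed(74)
  ppA <- simulate_ipp(0.5, win)
  ppB <- simulate_ipp(1.0, win)
  pp <- point_pattern(c(ppA$x, ppB$x), c(ppA$y, ppB$y), win,
                      marks = data.frame(grp = rep(c("A", "B"),
                                                   c(ppA$n, ppB$n))))
  f0 <- fit_ppm(pp, 0, strata = "grp")
  f1 <- fit_ppm(pp, 0, covariates = "grp", strata = "grp")
  lr <- lr_test(f0, f1)
  expect_equal(lr$df, 1) # one extra parameter for the binary mark
  expect_lt(lr$p, 1e-6) # 2x intensity difference is detected
  # the mark coefficient estimates the log intensity ratio
  expect_equal(unname(coef(f1)["grpB"]), log(2), tolerance = 0.2)
  # mismatched quadrature strata are refused
  f_plain <- fit_ppm(point_pattern(pp$x, pp$y, win), 0)
  expect_error(lr_test(f_plain, f1), "same pattern and quadrature")
})

test_that("LR test is calibrated under the null and powerful under 2x", {
  set.seed(75)
  pvals_null <- replicate(60, {
    ppA <- simulate_ipp(0.5, win)
    ppB <- simulate_ipp(0.5, win)
    pp <- point_pattern(c(ppA$x, ppB$x), c(ppA$y, ppB$y), win,
                        marks = data.frame(grp = rep(c("A", "B"),
                                                     c(ppA$n, ppB$n))))
    lr_test(fit_ppm(pp, 0, strata = "grp"),
            fit_ppm(pp, 0, covariates = "grp", strata = "grp"))$p
  })
  rej <- mean(pvals_null < 0.05)
  expect_lt(rej, 0.15)
  expect_gt(mean(pvals_null > 0.2), 0.5)
})

test_that("thinning simulation matches its intensity", {
  set.seed(76)
  # zero intensity: empty pattern
  expect_equal(simulate_ipp(0, win)$n, 0)
  # homogeneous counts are Poisson(900) on average
  counts <- replicate(300, simulate_ipp(1, win)$n)
  expect_equal(mean(counts), 900, tolerance = 0.02 * 900)
  expect_equal(var(counts), 900, tolerance = 0.25 * 900)
  # quadrat profile follows the integrated intensity
  lam <- function(x, y) ifelse(x > 0, 1.5, 0.5)
  tot <- matrix(0, 5, 5)
  for (i in 1:60) {
    pp <- simulate_ipp(lam, win, lmax = 1.5)
    tot <- tot + quadrat_test(pp, 5, 5)$counts
  }
  left <- sum(tot[, 1:2]) / 60
  right <- sum(tot[, 4:5]) / 60
  expect_equal(right / left, 3, tolerance = 0.3)
})

test_that("inhomogeneous K matches the Poisson expectation", {
  set.seed(77)
  pp <- simulate_ipp(1.2, win)
  r_grid <- seq(0, 5, length.out = 21)
  env <- kinhom_envelope(pp, 1.2, r_grid, n_sim = 19)
  expect_equal(env$khat[1], 0)
  expect_equal(env$theo, pi * r_grid^2)
  # CSR estimate tracks pi r^2 and stays inside its own envelope
  inside <- env$khat >= env$lo & env$khat <= env$hi
  expect_gt(mean(inside), 0.85)
  expect_equal(env$khat[r_grid > 1], env$theo[r_grid > 1],
               tolerance = 0.25)
  expect_error(kinhom_envelope(pp, 1.2, c(0, 15), n_sim = 3), "half the")
})

test_that("clustered patterns exceed the Poisson K", {
  set.seed(78)
  # parent-offspring (Neyman-Scott) construction
  parents <- simulate_ipp(0.02, win)
  x <- rep(parents$x, each = 40) + rnorm(40 * parents$n, 0, 0.5)
  y <- rep(parents$y, each = 40) + rnorm(40 * parents$n, 0, 0.5)
  keep <- x >= win[1] & x <= win[2] & y >= win[3] & y <= win[4]
  pp <- point_pattern(x[keep], y[keep], win)
  lam_hom <- pp$n / 900
  r_grid <- seq(0, 3, length.out = 13)
  env <- kinhom_envelope(pp, lam_hom, r_grid, n_sim = 19)
  expect_gt(env$khat[5], env$hi[5])
  expect_gt(env$khat[9], 2 * env$theo[9])
})

test_that("fitted intensities can be predicted and simulated from", {
  set.seed(79)
  lam <- function(x, y) exp(-0.5 + 0.03 * x - 0.01 * y)
  pp <- simulate_ipp(lam, win)
  fit <- fit_ppm(pp, 1)
  lf <- intensity_function(fit)
  expect_equal(lf(0, 0), unname(exp(coef(fit)[1])), tolerance = 1e-9)
  pred <- predict(fit, data.frame(x = c(-10, 10), y = c(0, 0)))
  expect_true(all(pred > 0))
  pp2 <- simulate_ipp(lf, win)
  expect_equal(pp2$n, pp$n, tolerance = 5 * sqrt(pp$n))
})
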