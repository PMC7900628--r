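# Inhomogeneous Poisson point-process modelling: log-polynomial intensity
# fitted by the Berman-Turner quadrature device, likelihood-ratio tests,
# simulation by thinning, and the inhomogeneous K function.

spatial_terms <- function(degree) {
  switch(as.character(degree),
         "0" = character(0),
         "1" = c("x", "y"),
         "2" = c("x", "y", "I(x^2)", "I(y^2)", "I(x * y)"),
         stop("`spatial_degree` must be 0, 1 or 2", call. = FALSE))
}

# Berman-Turner quadrature: data points plus a regular dummy grid, with
# counting weights (each tile's area divided among the data + dummy points
# it contains). Computed within each covariate stratum so that each
# stratum's intensity integrates to its own point count at the MLE.
build_quadrature <- function(x, y, window, covs = NULL, dummy = c(64, 36)) {
  nxt <- dummy[1]; nyt <- dummy[2]
  gx <- window[1] + (seq_len(nxt) - 0.5) / nxt * (window[2] - window[1])
  gy <- window[3] + (seq_len(nyt) - 0.5) / nyt * (window[4] - window[3])
  dum <- expand.grid(x = gx, y = gy)
  tile_area <- window_area(window) / (nxt * nyt)
  tile_of <- function(px, py) {
    ix <- pmin(nxt, 1L + floor((px - window[1]) / (window[2] - window[1]) * nxt))
    iy <- pmin(nyt, 1L + floor((py - window[3]) / (window[4] - window[3]) * nyt))
    (iy - 1L) * nxt + ix
  }
  strata <- if (is.null(covs)) {
    factor(rep("all", length(x)))
  } else {
    interaction(covs, drop = TRUE, lex.order = TRUE)
  }
  out <- list()
  for (lev in levels(strata)) {
    sel <- strata == lev
    qx <- c(x[sel], dum$x)
    qy <- c(y[sel], dum$y)
    is_data <- c(rep(TRUE, sum(sel)), rep(FALSE, nrow(dum)))
    tl <- tile_of(qx, qy)
    cnt <- tabulate(tl, nbins = nxt * nyt)
    w <- tile_area / cnt[tl]
    q <- data.frame(x = qx, y = qy, w = w, is_data = is_data)
    if (!is.null(covs)) {
      cv <- covs[sel, , drop = FALSE][rep(1L, length(qx)), , drop = FALSE]
      rownames(cv) <- NULL
      q <- cbind(q, cv)
    }
    out[[lev]] <- q
  }
  do.call(rbind, out)
}

#' Fit an inhomogeneous Poisson intensity model to a point pattern
#'
#' Models the point intensity (expected density of points per unit area)
#' as a log-polynomial of the coordinates,
#' \deqn{\log\lambda(x, y) = \beta_0 + \beta_1 x + \beta_2 y + \beta_3 x^2
#'   + \beta_4 y^2 + \beta_5 xy,}
#' optionally with categorical covariate (mark) terms and their
#' interactions with the spatial trend. The Poisson process
#' log-likelihood \eqn{\sum_i \log\lambda(x_i) - \int_W \lambda} is
#' maximized via the Berman--Turner quadrature device: data and dummy
#' points with counting weights reduce the problem to a weighted Poisson
#' regression solved by iteratively reweighted least squares.
#'
#' @param pattern a [point_pattern()]; covariates are taken from its
#'   marks.
#' @param spatial_degree polynomial degree of the spatial trend (0, 1 or
#'   2).
#' @param covariates character vector of mark columns entering as
#'   categorical main effects (e.g. `c("group", "noise_level")`).
#' @param spatial_interactions subset of `covariates` whose levels get
#'   their own spatial trend (covariate x coordinate interactions).
#' @param strata mark columns defining the replicated sub-patterns over
#'   which the quadrature is stratified. Defaults to `covariates`. Nested
#'   models compared by [lr_test()] must share the same strata (and hence
#'   the same quadrature), so fit the null with the full model's strata.
#' @param dummy dummy grid dimensions `c(nx, ny)` (default 64 x 36,
#'   roughly the window aspect).
#' @return an object of class `ppm_fit`: `coefficients`, `vcov`,
#'   `logLik` (point-process log-likelihood), `df`, `n_points`, fitted
#'   `terms`/`xlevels` for prediction, and the quadrature summary.
#' @seealso [lr_test()], [predict.ppm_fit()], [simulate_ipp()]
#' @examples
#' set.seed(1)
#' pp <- point_pattern(runif(200, -20, 20), runif(200, -11.25, 11.25))
#' fit <- fit_ppm(pp, spatial_degree = 0)
#' coef(fit) # ~ log(200 / 900)
#' @export
fit_ppm <- function(pattern, spatial_degree = 2, covariates = NULL,
                    spatial_interactions = NULL, strata = covariates,
                    dummy = c(64, 36)) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (!is.null(spatial_interactions) &&
      !all(spatial_interactions %in% covariates)) {
    stop("`spatial_interactions` must be a subset of `covariates`",
         call. = FALSE)
  }
  if (!is.null(covariates) && !all(covariates %in% strata)) {
    stop("`covariates` must be contained in the quadrature `strata`",
         call. = FALSE)
  }
  covs <- NULL
  if (!is.null(strata)) {
    if (is.null(pattern$marks) || !all(strata %in% names(pattern$marks))) {
      stop("strata/covariates must name mark columns of the pattern",
           call. = FALSE)
    }
    covs <- pattern$marks[, strata, drop = FALSE]
    covs[] <- lapply(covs, function(col) factor(col))
  }
  sp <- spatial_terms(spatial_degree)
  rhs <- c(if (length(sp)) sp else "1", covariates)
  for (v in spatial_interactions) {
    if (length(sp)) rhs <- c(rhs, paste0(v, ":", sp))
  }
  fml <- stats::as.formula(paste(".z ~", paste(rhs, collapse = " + ")))
  quad <- build_quadrature(pattern$x, pattern$y, pattern$window, covs, dummy)
  quad$.z <- quad$is_data / quad$w
  n_par <- spatial_degree # rough rank guard; glm handles the rest
  if (pattern$n <= length(rhs)) {
    stop("too few points (", pattern$n, ") for the requested model",
         call. = FALSE)
  }
  fit <- suppressWarnings(stats::glm(fml, family = stats::quasipoisson(),
                                     data = quad, weights = quad$w))
  if (!fit$converged) {
    stop("ppm fit did not converge (", fit$iter, " IRLS iterations); ",
         "deviance ", format(fit$deviance), call. = FALSE)
  }
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop("rank-deficient design: coefficient(s) ",
         paste(names(beta)[is.na(beta)], collapse = ", "),
         " not estimable", call. = FALSE)
  }
  lam <- fit$fitted.values
  ll <- sum(log(lam[quad$is_data])) - sum(quad$w * lam)
  sm <- summary(fit, dispersion = 1)
  structure(
    list(coefficients = beta, vcov = sm$cov.scaled, logLik = ll,
         df = length(beta), n_points = pattern$n,
         terms = stats::delete.response(stats::terms(fit)),
         xlevels = fit$xlevels, window = pattern$window,
         spatial_degree = spatial_degree, covariates = covariates,
         spatial_interactions = spatial_interactions, strata = strata,
         dummy = dummy,
         integral = sum(quad$w * lam), converged = fit$converged),
    class = "ppm_fit")
}

#' @export
print.ppm_fit <- function(x, ...) {
  cat("Inhomogeneous Poisson point-process model\n")
  cat(sprintf("  %d points, spatial degree %d%s\n", x$n_points,
              x$spatial_degree,
              if (!is.null(x$covariates))
                paste0(", covariates: ", paste(x$covariates, collapse = ", "))
              else ""))
  cat(sprintf("  logLik %.2f on %d parameters\n", x$logLik, x$df))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.ppm_fit <- function(object, ...) object$coefficients

#' @export
vcov.ppm_fit <- function(object, ...) object$vcov

#' @export
logLik.ppm_fit <- function(object, ...) {
  structure(object$logLik, df = object$df, class = "logLik")
}

#' Predict the fitted intensity at new locations
#'
#' @param object a `ppm_fit`.
#' @param newdata data frame with columns `x`, `y` and any covariates in
#'   the model.
#' @param ... unused.
#' @return numeric vector of intensities (points per unit area).
#' @export
predict.ppm_fit <- function(object, newdata, ...) {
  mf <- stats::model.frame(object$terms, newdata, xlev = object$xlevels)
  mm <- stats::model.matrix(object$terms, mf)
  as.numeric(exp(mm %*% object$coefficients))
}

#' Intensity function of a fitted model
#'
#' Convenience closure `function(x, y)` evaluating the fitted intensity,
#' with covariates frozen at given values.
#'
#' @param fit a `ppm_fit`.
#' @param covariate_values one-row data frame (or named list) of covariate
#'   levels, required when the model has covariates.
#' @return `function(x, y)` returning intensities.
#' @export
intensity_function <- function(fit, covariate_values = NULL) {
  stopifnot(inherits(fit, "ppm_fit"))
  force(covariate_values)
  function(x, y) {
    nd <- data.frame(x = x, y = y)
    if (!is.null(covariate_values)) {
      for (nm in names(covariate_values)) nd[[nm]] <- covariate_values[[nm]]
    }
    predict(fit, nd)
  }
}

#' Likelihood-ratio test of nested intensity models
#'
#' @param model_null,model_full `ppm_fit` objects fitted to the same
#'   pattern and quadrature, the null's terms nested in the full's.
#' @return a list: `chi2`, `df`, `p`.
#' @examples
#' set.seed(1)
#' pp <- point_pattern(runif(300, -20, 20), runif(300, -11.25, 11.25))
#' lr_test(fit_ppm(pp, 0), fit_ppm(pp, 1))$df # 2
#' @export
lr_test <- function(model_null, model_full) {
  stopifnot(inherits(model_null, "ppm_fit"), inherits(model_full, "ppm_fit"))
  if (model_null$n_points != model_full$n_points ||
      !identical(model_null$dummy, model_full$dummy) ||
      !identical(model_null$strata, model_full$strata)) {
    stop("models must be fitted to the same pattern and quadrature ",
         "(including strata); refit the null with the full model's ",
         "`strata`", call. = FALSE)
  }
  if (!all(names(model_null$coefficients) %in%
             names(model_full$coefficients))) {
    stop("models are not nested: null terms ",
         paste(setdiff(names(model_null$coefficients),
                       names(model_full$coefficients)), collapse = ", "),
         " absent from the full model", call. = FALSE)
  }
  df <- model_full$df - model_null$df
  chi2 <- 2 * (model_full$logLik - model_null$logLik)
  if (df == 0) {
    # identical parameter sets: nothing to test
    return(list(chi2 = max(chi2, 0), df = 0L, p = 1))
  }
  list(chi2 = chi2, df = df,
       p = stats::pchisq(max(chi2, 0), df, lower.tail = FALSE))
}

#' @export
anova.ppm_fit <- function(object, ...) {
  others <- list(...)
  if (!length(others) || !inherits(others[[1]], "ppm_fit")) {
    stop("supply two nested ppm_fit models", call. = FALSE)
  }
  lr <- lr_test(object, others[[1]])
  out <- data.frame(df = lr$df, chi2 = lr$chi2, p = lr$p)
  rownames(out) <- "LR test"
  out
}

#' Simulate an inhomogeneous Poisson pattern by thinning
#'
#' Simulates a homogeneous Poisson process at the bounding intensity
#' `lmax` and retains each point with probability `lambda(x, y) / lmax`.
#'
#' @param lambda intensity: a single number, or `function(x, y)`.
#' @param window `c(xmin, xmax, ymin, ymax)`.
#' @param lmax upper bound for `lambda` over the window; estimated from a
#'   fine grid (with a 5% safety margin) when omitted.
#' @return a [point_pattern()].
#' @examples
#' set.seed(1)
#' pp <- simulate_ipp(1, c(-20, 20, -11.25, 11.25)) # ~Poisson(900) points
#' @export
simulate_ipp <- function(lambda, window, lmax = NULL) {
  lam_fun <- if (is.function(lambda)) lambda else function(x, y) {
    rep(lambda, length(x))
  }
  if (is.null(lmax)) {
    gx <- seq(window[1], window[2], length.out = 101)
    gy <- seq(window[3], window[4], length.out = 61)
    gr <- expand.grid(x = gx, y = gy)
    lmax <- 1.05 * max(lam_fun(gr$x, gr$y))
  }
  if (!is.finite(lmax)) {
    stop("intensity is unbounded on the window", call. = FALSE)
  }
  if (lmax <= 0) {
    return(point_pattern(numeric(0), numeric(0), window))
  }
  n <- stats::rpois(1, lmax * window_area(window))
  x <- stats::runif(n, window[1], window[2])
  y <- stats::runif(n, window[3], window[4])
  keep <- stats::runif(n) < lam_fun(x, y) / lmax
  point_pattern(x[keep], y[keep], window)
}

# border-corrected inhomogeneous K estimate on a distance grid
kinhom_estimate <- function(x, y, lam, window, r_grid) {
  b <- pmin(x - window[1], window[2] - x, y - window[3], window[4] - y)
  n <- length(x)
  khat <- numeric(length(r_grid))
  if (n < 2L) return(khat + NA_real_)
  d <- as.matrix(stats::dist(cbind(x, y)))
  inv2 <- outer(1 / lam, 1 / lam)
  diag(inv2) <- 0
  for (k in seq_along(r_grid)) {
    r <- r_grid[k]
    valid <- b > r
    if (!any(valid)) {
      khat[k] <- NA_real_
      next
    }
    contrib <- inv2[valid, , drop = FALSE] *
      (d[valid, , drop = FALSE] <= r)
    khat[k] <- sum(contrib) / sum(1 / lam[valid])
  }
  khat
}

#' Inhomogeneous K function with a simulation envelope
#'
#' Border-corrected estimate of the inhomogeneous K function,
#' \deqn{\hat K(r) = \frac{\sum_{i: b_i > r}\sum_{j \ne i, d_{ij} \le r}
#'   1/(\lambda(x_i)\lambda(x_j))}{\sum_{i: b_i > r} 1/\lambda(x_i)},}
#' where \eqn{b_i} is the distance from point i to the window boundary
#' (only points whose r-ball lies inside the window contribute).
#' Under an inhomogeneous Poisson process \eqn{K(r) = \pi r^2}; values
#' above the envelope of simulations from the fitted intensity indicate
#' clustering beyond the intensity trend. The envelope is the pointwise
#' min/max of `n_sim` thinning simulations.
#'
#' @param pattern a [point_pattern()].
#' @param lambda fitted intensity: a number or `function(x, y)` (e.g. from
#'   [intensity_function()]).
#' @param r_grid distances at which to evaluate K; must not exceed half
#'   the shorter window side. Default: 50 steps up to a quarter of the
#'   shorter side.
#' @param n_sim number of envelope simulations (default 99).
#' @return a data frame: `r`, `khat`, `theo` (pi r^2), `lo`, `hi`.
#' @export
kinhom_envelope <- function(pattern, lambda, r_grid = NULL, n_sim = 99) {
  stopifnot(inherits(pattern, "point_pattern"))
  w <- pattern$window
  short <- min(w[2] - w[1], w[4] - w[3])
  if (is.null(r_grid)) {
    r_grid <- seq(0, short / 4, length.out = 50)
  }
  if (max(r_grid) > short / 2) {
    stop("r_grid exceeds half the shorter window side (", short / 2, ")",
         call. = FALSE)
  }
  lam_fun <- if (is.function(lambda)) lambda else function(x, y) {
    rep(lambda, length(x))
  }
  lam_obs <- lam_fun(pattern$x, pattern$y)
  if (any(lam_obs <= 0)) {
    stop("fitted intensity must be positive at every data point",
         call. = FALSE)
  }
  khat <- kinhom_estimate(pattern$x, pattern$y, lam_obs, w, r_grid)
  sims <- matrix(NA_real_, nrow = n_sim, ncol = length(r_grid))
  for (s in seq_len(n_sim)) {
    pp <- simulate_ipp(lam_fun, w)
    if (pp$n < 2L) next
    sims[s, ] <- kinhom_estimate(pp$x, pp$y, lam_fun(pp$x, pp$y), w, r_grid)
  }
  data.frame(r = r_grid, khat = khat, theo = pi * r_grid^2,
             lo = apply(sims, 2, min, na.rm = TRUE),
             hi = apply(sims, 2, max, na.rm = TRUE))
}
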