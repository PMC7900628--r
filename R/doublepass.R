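# Double-pass agreement/accuracy and the fixed-point slope regression
# pc = m * log10(pa / 100) + 100.

#' Agreement and accuracy of a double-pass pair
#'
#' Matches the trials of the two passes by `trial_index` (the presentation
#' order, identical across passes by design) and computes the percent
#' agreement `pa` (same response to the same stimulus in both passes) and
#' percent correct `pc` pooled over both passes.
#'
#' @param pass1,pass2 data frames with columns `trial_index`, `response`,
#'   `correct` for one subject at one noise level.
#' @return a one-row data frame: `pa`, `pc`, `n_trials` (per pass).
#' @examples
#' p <- data.frame(trial_index = 1:4,
#'                 response = c("yes", "no", "yes", "no"),
#'                 correct = c(TRUE, TRUE, FALSE, TRUE))
#' agreement_and_accuracy(p, p) # pa = 100
#' @export
agreement_and_accuracy <- function(pass1, pass2) {
  check_columns(pass1, c("trial_index", "response", "correct"), "pass1")
  check_columns(pass2, c("trial_index", "response", "correct"), "pass2")
  if (nrow(pass1) != nrow(pass2) ||
      !setequal(pass1$trial_index, pass2$trial_index)) {
    stop("pass-1 and pass-2 trial sets do not match", call. = FALSE)
  }
  o1 <- pass1[order(pass1$trial_index), ]
  o2 <- pass2[order(pass2$trial_index), ]
  n <- nrow(o1)
  data.frame(
    pa = 100 * mean(o1$response == o2$response),
    pc = 100 * (sum(o1$correct) + sum(o2$correct)) / (2 * n),
    n_trials = n)
}

#' Per-subject double-pass points from a trial table
#'
#' @param trials a trial table in the canonical schema (see
#'   [simulate_cohort()]), containing `pass` 1 and 2 rows at the
#'   double-pass noise levels.
#' @return a data frame with one row per subject x repeated noise level:
#'   `subject_id`, `group`, `noise_level`, `pa`, `pc`, `n_trials`.
#' @export
double_pass_points <- function(trials) {
  check_columns(trials, c("subject_id", "group", "pass", "trial_index",
                          "noise_level", "response", "correct"), "trials")
  dp_levels <- sort(unique(trials$noise_level[trials$pass == 2]))
  out <- list()
  for (sid in unique(trials$subject_id)) {
    for (lv in dp_levels) {
      p1 <- trials[trials$subject_id == sid & trials$noise_level == lv &
                     trials$pass == 1, ]
      p2 <- trials[trials$subject_id == sid & trials$noise_level == lv &
                     trials$pass == 2, ]
      if (!nrow(p1) || !nrow(p2)) next
      aa <- agreement_and_accuracy(p1, p2)
      out[[length(out) + 1L]] <- cbind(
        data.frame(subject_id = sid, group = p1$group[1], noise_level = lv),
        aa)
    }
  }
  do.call(rbind, out)
}

#' Fit the fixed-point percent-correct vs percent-agreement slope
#'
#' Least-squares fit of the relation
#' \deqn{p_c = m \log_{10}(p_a / 100) + 100,}
#' a one-parameter regression constrained through the point
#' (pa, pc) = (100, 100): with \eqn{x_i = \log_{10}(p_{a,i}/100)} and
#' \eqn{y_i = p_{c,i} - 100}, the slope is
#' \eqn{\hat m = \sum x_i y_i / \sum x_i^2}. Its standard error uses the
#' one-parameter residual variance on `n - 1` degrees of freedom, and the
#' 95% confidence interval the corresponding t quantile. The slope indexes
#' the internal-to-external noise ratio: more internally driven response
#' variability lowers agreement faster than accuracy.
#'
#' @param points data frame with columns `pa` and `pc` in percent (e.g.
#'   from [double_pass_points()], typically one subject per row within a
#'   group x noise level).
#' @param level confidence level for the interval.
#' @return an object of class `dp_slope_fit`: coefficients, SE, CI, df and the
#'   fitting data.
#' @examples
#' pa <- c(70, 80, 90)
#' pts <- data.frame(pa = pa, pc = 100 + 0.82 * log10(pa / 100))
#' coef(fit_dp_slope(pts)) # recovers 0.82
#' @export
fit_dp_slope <- function(points, level = 0.95) {
  check_columns(points, c("pa", "pc"), "points")
  stopifnot(all(points$pa >= 0 & points$pa <= 100),
            all(points$pc >= 0 & points$pc <= 100))
  x <- log10(points$pa / 100)
  y <- points$pc - 100
  sxx <- sum(x^2)
  if (nrow(points) < 2L || sxx == 0) {
    stop("degenerate fit: need at least two points with pa < 100",
         call. = FALSE)
  }
  m <- sum(x * y) / sxx
  df <- nrow(points) - 1L
  s2 <- sum((y - m * x)^2) / df
  se <- sqrt(s2 / sxx)
  tq <- stats::qt(1 - (1 - level) / 2, df)
  structure(
    list(coefficients = c(m = m), se = se,
         ci = c(lower = m - tq * se, upper = m + tq * se),
         df = df, n_points = nrow(points), level = level,
         data = data.frame(pa = points$pa, pc = points$pc, x = x, y = y)),
    class = "dp_slope_fit")
}

#' @export
print.dp_slope_fit <- function(x, ...) {
  cat("Fixed-point slope fit: pc = m * log10(pa/100) + 100\n")
  cat(sprintf("  m = %.4g  [%.4g, %.4g]  (SE %.3g, df %d, n %d)\n",
              x$coefficients["m"], x$ci["lower"], x$ci["upper"],
              x$se, x$df, x$n_points))
  invisible(x)
}

#' @export
coef.dp_slope_fit <- function(object, ...) object$coefficients

#' @export
confint.dp_slope_fit <- function(object, parm = "m", level = NULL, ...) {
  if (is.null(level) || level == object$level) {
    return(matrix(object$ci, nrow = 1,
                  dimnames = list("m", names(object$ci))))
  }
  tq <- stats::qt(1 - (1 - level) / 2, object$df)
  m <- object$coefficients["m"]
  matrix(c(m - tq * object$se, m + tq * object$se), nrow = 1,
         dimnames = list("m", c("lower", "upper")))
}

#' Predict percent correct from percent agreement
#'
#' @param object a `dp_slope_fit`.
#' @param newdata data frame with a `pa` column (percent); defaults to the
#'   fitting data.
#' @param ... unused.
#' @return numeric vector of predicted `pc` (percent); `pa = 100` always
#'   maps to `pc = 100` by construction.
#' @export
predict.dp_slope_fit <- function(object, newdata = NULL, ...) {
  pa <- if (is.null(newdata)) object$data$pa else newdata$pa
  unname(object$coefficients["m"] * log10(pa / 100) + 100)
}

#' @export
summary.dp_slope_fit <- function(object, ...) {
  res <- object$data$y - object$coefficients["m"] * object$data$x
  out <- list(fit = object, residuals = res,
              sigma = sqrt(sum(res^2) / object$df))
  class(out) <- "summary.dp_slope_fit"
  out
}

#' @export
print.summary.dp_slope_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual SD %.3g on %d df\n", x$sigma, x$fit$df))
  invisible(x)
}

#' @export
residuals.dp_slope_fit <- function(object, ...) {
  object$data$pc - predict(object)
}

#' @export
plot.dp_slope_fit <- function(x, ...) {
  graphics::plot(x$data$pa, x$data$pc, xlab = "percent agreement",
                 ylab = "percent correct", xlim = c(min(x$data$pa), 100),
                 ylim = range(c(x$data$pc, 100)), ...)
  pa_grid <- seq(min(x$data$pa), 100, length.out = 100)
  graphics::lines(pa_grid, predict(x, data.frame(pa = pa_grid)))
  graphics::points(100, 100, pch = 3)
  invisible(x)
}

#' Compare two fixed-point slopes
#'
#' Welch t test on the difference of two independently fitted slopes,
#' using each fit's standard error and a Welch--Satterthwaite df.
#'
#' @param fitA,fitB `dp_slope_fit` objects.
#' @return a list: `t_ratio`, `df`, `p`, `diff` (mA - mB).
#' @examples
#' pa <- c(70, 80, 90, 95)
#' fa <- fit_dp_slope(data.frame(pa = pa, pc = 100 + 0.8 * log10(pa / 100)))
#' compare_slopes(fa, fa) # t = 0, p = 1
#' @export
compare_slopes <- function(fitA, fitB) {
  stopifnot(inherits(fitA, "dp_slope_fit"), inherits(fitB, "dp_slope_fit"))
  vA <- fitA$se^2
  vB <- fitB$se^2
  if (vA + vB == 0) {
    stop("degenerate comparison: both slope standard errors are zero",
         call. = FALSE)
  }
  d <- unname(fitA$coefficients["m"] - fitB$coefficients["m"])
  se <- sqrt(vA + vB)
  t <- d / se
  df <- (vA + vB)^2 / (vA^2 / fitA$df + vB^2 / fitB$df)
  list(t_ratio = t, df = df, p = 2 * stats::pt(-abs(t), df), diff = d)
}
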