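# Linear amplifier model (LAM) of the double-pass experiment: exact
# bivariate-normal predictions of (pc, pa) and their inversion.

# Standard bivariate normal CDF P(X <= a, Y <= b) with correlation rho,
# by 1-D quadrature of phi(z) * Phi((b - rho z)/sqrt(1 - rho^2)).
# Absolute error well below 1e-8 over the range used here.
pbvnorm <- function(a, b, rho) {
  stopifnot(length(a) == 1L, length(b) == 1L, abs(rho) <= 1)
  if (!is.finite(a) || !is.finite(b)) {
    a <- min(a, 8.5); b <- min(b, 8.5)
    if (a <= -8.5 || b <= -8.5) return(0)
    if (a >= 8.5 && b >= 8.5) return(1)
  }
  if (rho >= 1 - 1e-12) return(stats::pnorm(min(a, b)))
  if (rho <= -1 + 1e-12) return(max(0, stats::pnorm(a) + stats::pnorm(b) - 1))
  sr <- sqrt(1 - rho^2)
  f <- function(z) stats::dnorm(z) * stats::pnorm((b - rho * z) / sr)
  stats::integrate(f, -8.5, a, rel.tol = 1e-10, abs.tol = 1e-12,
                   subdivisions = 400L)$value
}

#' Linear amplifier observer model
#'
#' The generative model behind the double-pass paradigm. On each trial the
#' decision variable is \eqn{v = \mu_c + e + \epsilon}: a class mean
#' (\eqn{d} for signal, 0 for noise, in external-noise-SD units with
#' \eqn{\sigma_e = 1}), a frozen stimulus-driven draw \eqn{e \sim N(0, 1)}
#' shared by the two passes, and an independent internal draw
#' \eqn{\epsilon \sim N(0, r^2)} per pass, where \eqn{r = \sigma_i/\sigma_e}.
#' The observer answers "yes" when \eqn{v > \gamma}.
#'
#' @param d signal mean offset in external-noise-SD units.
#' @param r internal-to-external noise ratio (>= 0).
#' @param gamma decision criterion; default `d/2` (unbiased).
#' @return an object of class `lam_model`.
#' @seealso [lam_predict()], [estimate_sigma_ratio()]
#' @examples
#' lam_model(d = 2, r = 1)
#' @export
lam_model <- function(d, r, gamma = d / 2) {
  stopifnot(is.numeric(d), is.numeric(r), r >= 0)
  structure(list(d = d, r = r, gamma = gamma, sigma_e = 1),
            class = "lam_model")
}

#' @export
print.lam_model <- function(x, ...) {
  cat(sprintf(
    "Linear amplifier model: d = %.3g, r = sigma_i/sigma_e = %.3g, gamma = %.3g\n",
    x$d, x$r, x$gamma))
  invisible(x)
}

#' Expected percent correct and percent agreement under the LAM
#'
#' Closed-form single- and double-pass response probabilities. With
#' \eqn{a_c = (\mu_c - \gamma)/\sqrt{1 + r^2}} the single-pass yes rate
#' for class \eqn{c} is \eqn{\Phi(a_c)}; the probability of answering yes
#' in both passes is the bivariate normal orthant
#' \eqn{\Phi_2(a_c, a_c; \rho)} with pass-to-pass correlation
#' \eqn{\rho = 1/(1 + r^2)} (the share of decision variance that is frozen
#' in the stimulus). Percent agreement averages the both-yes and both-no
#' probabilities over the two classes; percent correct averages the hit
#' and correct-rejection rates.
#'
#' @param model a [lam_model()].
#' @return a list: `expected_pc`, `expected_pa` (percent), plus the yes
#'   rates per class.
#' @examples
#' lam_predict(lam_model(d = 2, r = 0))$expected_pa # 100: no internal noise
#' @export
lam_predict <- function(model) {
  stopifnot(inherits(model, "lam_model"))
  r <- model$r
  s <- sqrt(1 + r^2)
  rho <- 1 / (1 + r^2)
  a_sig <- (model$d - model$gamma) / s
  a_noi <- (0 - model$gamma) / s
  p_yes_sig <- stats::pnorm(a_sig)
  p_yes_noi <- stats::pnorm(a_noi)
  agree_c <- function(a) {
    both_yes <- pbvnorm(a, a, rho)
    both_no <- pbvnorm(-a, -a, rho)
    both_yes + both_no
  }
  pa <- 100 * mean(c(agree_c(a_sig), agree_c(a_noi)))
  pc <- 100 * (p_yes_sig + (1 - p_yes_noi)) / 2
  list(expected_pc = pc, expected_pa = pa,
       p_yes_signal = p_yes_sig, p_yes_noise = p_yes_noi)
}

#' Simulate double-pass trials from a LAM observer
#'
#' Monte-Carlo generator matching [lam_predict()] exactly: frozen external
#' draws shared across passes, independent internal draws per pass. Used
#' as the independent oracle for the closed-form predictions and for
#' recovery studies.
#'
#' @param object a [lam_model()].
#' @param nsim number of double-pass trials (half signal, half noise).
#' @param seed optional seed.
#' @param ... unused.
#' @return a data frame with columns `class`, `yes1`, `yes2`, `correct1`,
#'   `correct2`.
#' @export
simulate.lam_model <- function(object, nsim = 1000, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n_sig <- floor(nsim / 2)
  cls <- rep(c("signal", "noise"), c(n_sig, nsim - n_sig))
  mu <- ifelse(cls == "signal", object$d, 0)
  e <- stats::rnorm(nsim) # frozen stimulus draw
  v1 <- mu + e + stats::rnorm(nsim, 0, object$r)
  v2 <- mu + e + stats::rnorm(nsim, 0, object$r)
  yes1 <- v1 > object$gamma
  yes2 <- v2 > object$gamma
  data.frame(class = cls, yes1 = yes1, yes2 = yes2,
             correct1 = yes1 == (cls == "signal"),
             correct2 = yes2 == (cls == "signal"))
}

# (pc, pa) for criterion gamma = d/2, as functions of (a, r) where
# a = (d/2)/sqrt(1+r^2); by symmetry pc = 100*Phi(a) and both classes give
# the same agreement.
pa_given_a_r <- function(a, r) {
  rho <- 1 / (1 + r^2)
  100 * (pbvnorm(a, a, rho) + pbvnorm(-a, -a, rho))
}

#' Estimate the internal-to-external noise ratio from one (pc, pa) pair
#'
#' Inverts [lam_predict()] under the unbiased-criterion assumption
#' (`gamma = d/2`). By symmetry percent correct then pins down the
#' standardized half-separation `a = qnorm(pc/100)` in closed form, and
#' percent agreement is a strictly decreasing function of `r` given `a`,
#' solved by bracketed root finding. Feasibility requires
#' `50 < pc < 100` and `pa` at or above the independence floor
#' `100 * (Phi(a)^2 + Phi(-a)^2)` reached as `r` grows without bound.
#'
#' @param pc percent correct (pooled over both passes), in (50, 100).
#' @param pa percent agreement between passes, in (0, 100].
#' @param r_max upper bracket for the ratio search.
#' @param tol convergence tolerance on `r`.
#' @return a list: `r_hat`, `d_hat`, `gamma_hat`, `converged`, and the
#'   model-implied (`pc_fit`, `pa_fit`).
#' @examples
#' p <- lam_predict(lam_model(d = 1.5, r = 0.8))
#' estimate_sigma_ratio(p$expected_pc, p$expected_pa)$r_hat # 0.8
#' @export
estimate_sigma_ratio <- function(pc, pa, r_max = 50, tol = 1e-9) {
  stopifnot(is.numeric(pc), is.numeric(pa), length(pc) == 1L,
            length(pa) == 1L)
  if (pc <= 50 || pc >= 100) {
    stop("infeasible: pc must lie strictly between 50 and 100 (got ",
         format(pc), ")", call. = FALSE)
  }
  if (pa > 100) stop("pa cannot exceed 100", call. = FALSE)
  a <- stats::qnorm(pc / 100)
  if (pa >= 100) {
    d_hat <- 2 * a
    return(list(r_hat = 0, d_hat = d_hat, gamma_hat = d_hat / 2,
                converged = TRUE, pc_fit = pc, pa_fit = 100))
  }
  floor_pa <- 100 * (stats::pnorm(a)^2 + stats::pnorm(-a)^2)
  if (pa < floor_pa - 1e-9) {
    stop("infeasible: pa = ", format(pa), " is below the independence ",
         "floor ", format(round(floor_pa, 3)), " implied by pc = ",
         format(pc), call. = FALSE)
  }
  f <- function(r) pa_given_a_r(a, r) - pa
  lo <- 0
  hi <- 1
  while (f(hi) > 0 && hi < r_max) hi <- hi * 2
  if (f(hi) > 0) {
    # pa is (numerically) at the floor; the ratio is effectively unbounded
    r_hat <- r_max
    converged <- FALSE
  } else {
    r_hat <- stats::uniroot(f, c(lo, min(hi, r_max)), tol = tol)$root
    converged <- TRUE
  }
  d_hat <- 2 * a * sqrt(1 + r_hat^2)
  list(r_hat = r_hat, d_hat = d_hat, gamma_hat = d_hat / 2,
       converged = converged,
       pc_fit = 100 * stats::pnorm(a), pa_fit = pa_given_a_r(a, r_hat))
}

#' Estimate LAM parameters from hit and false-alarm rates plus agreement
#'
#' Three-parameter variant that drops the unbiased-criterion assumption:
#' the single-pass hit and false-alarm rates identify
#' \eqn{(d - \gamma)/\sqrt{1+r^2}} and \eqn{-\gamma/\sqrt{1+r^2}}, and the
#' observed agreement then pins down `r` by root finding.
#'
#' @param hit_rate,fa_rate single-pass hit and false-alarm proportions in
#'   (0, 1).
#' @param pa percent agreement between passes.
#' @param r_max upper bracket for the ratio search.
#' @return a list: `r_hat`, `d_hat`, `gamma_hat`, `converged`.
#' @export
estimate_lam_full <- function(hit_rate, fa_rate, pa, r_max = 50) {
  stopifnot(hit_rate > 0, hit_rate < 1, fa_rate > 0, fa_rate < 1)
  if (hit_rate <= fa_rate) {
    stop("infeasible: hit rate must exceed false-alarm rate", call. = FALSE)
  }
  a_sig <- stats::qnorm(hit_rate)
  a_noi <- stats::qnorm(fa_rate)
  agree_r <- function(r) {
    rho <- 1 / (1 + r^2)
    50 * (pbvnorm(a_sig, a_sig, rho) + pbvnorm(-a_sig, -a_sig, rho) +
            pbvnorm(a_noi, a_noi, rho) + pbvnorm(-a_noi, -a_noi, rho))
  }
  f <- function(r) agree_r(r) - pa
  hi <- 1
  while (f(hi) > 0 && hi < r_max) hi <- hi * 2
  if (f(0) < 0) {
    stop("infeasible: pa exceeds the perfect-consistency ceiling for the ",
         "given hit/false-alarm rates", call. = FALSE)
  }
  if (f(hi) > 0) {
    r_hat <- r_max
    converged <- FALSE
  } else {
    r_hat <- stats::uniroot(f, c(0, hi), tol = 1e-9)$root
    converged <- TRUE
  }
  s <- sqrt(1 + r_hat^2)
  gamma_hat <- -a_noi * s
  d_hat <- a_sig * s + gamma_hat
  list(r_hat = r_hat, d_hat = d_hat, gamma_hat = gamma_hat,
       converged = converged)
}
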