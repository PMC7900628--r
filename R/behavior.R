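# Behavioral statistics: RT filtering, SDT categorization, Bayesian
# bootstrap, correlations, accuracy summaries.

#' Filter reaction-time outliers
#'
#' Excludes trials whose RT is strictly below `lo` or strictly above `hi`
#' seconds (boundary values are retained), and logs exclusion counts per
#' subject.
#'
#' @param trials trial table with columns `subject_id` and `rt_s`.
#' @param lo,hi retention bounds in seconds (defaults 0.25 and 4.0).
#' @return a list: `trials` (filtered table) and `exclusions` (data frame
#'   `subject_id`, `n_total`, `n_excluded`).
#' @examples
#' tr <- data.frame(subject_id = "S01",
#'                  rt_s = c(0.20, 0.25, 1.0, 4.0, 4.5))
#' filter_rt(tr)$trials$rt_s # 0.25, 1.0, 4.0 retained
#' @export
filter_rt <- function(trials, lo = 0.25, hi = 4.0) {
  check_columns(trials, c("subject_id", "rt_s"), "trials")
  keep <- trials$rt_s >= lo & trials$rt_s <= hi
  excl <- stats::aggregate(list(n_excluded = !keep),
                           by = list(subject_id = trials$subject_id), FUN = sum)
  tot <- stats::aggregate(list(n_total = rep(1L, nrow(trials))),
                          by = list(subject_id = trials$subject_id), FUN = sum)
  log <- merge(tot, excl, by = "subject_id")
  list(trials = trials[keep, , drop = FALSE], exclusions = log)
}

#' Signal-detection categorization of yes/no responses
#'
#' Classifies every trial as hit (signal, "yes"), miss (signal, "no"),
#' false alarm (noise, "yes") or correct rejection (noise, "no"), and
#' tabulates counts and percentages per subject and noise level.
#'
#' @param trials trial table with columns `subject_id`, `noise_level`,
#'   `class` ("signal"/"noise") and `response` ("yes"/"no").
#' @return a data frame per subject x noise level: counts `hits`,
#'   `misses`, `false_alarms`, `correct_rejections`, their percentages of
#'   the cell's trials (`*_pct`), and the `hit_rate` / `fa_rate`
#'   conditional rates.
#' @export
sdt_categorize <- function(trials) {
  check_columns(trials, c("subject_id", "noise_level", "class", "response"),
                "trials")
  stopifnot(all(trials$class %in% c("signal", "noise")),
            all(trials$response %in% c("yes", "no")))
  cat4 <- ifelse(trials$class == "signal",
                 ifelse(trials$response == "yes", "hit", "miss"),
                 ifelse(trials$response == "yes", "false_alarm",
                        "correct_rejection"))
  key <- interaction(trials$subject_id, trials$noise_level, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sel <- key == k
    n <- sum(sel)
    cts <- table(factor(cat4[sel], levels = c("hit", "miss", "false_alarm",
                                              "correct_rejection")))
    n_sig <- cts[["hit"]] + cts[["miss"]]
    n_noi <- cts[["false_alarm"]] + cts[["correct_rejection"]]
    data.frame(subject_id = trials$subject_id[sel][1],
               noise_level = trials$noise_level[sel][1],
               hits = cts[["hit"]], misses = cts[["miss"]],
               false_alarms = cts[["false_alarm"]],
               correct_rejections = cts[["correct_rejection"]],
               hits_pct = 100 * cts[["hit"]] / n,
               misses_pct = 100 * cts[["miss"]] / n,
               false_alarms_pct = 100 * cts[["false_alarm"]] / n,
               correct_rejections_pct = 100 * cts[["correct_rejection"]] / n,
               hit_rate = if (n_sig > 0) cts[["hit"]] / n_sig else NA_real_,
               fa_rate = if (n_noi > 0) cts[["false_alarm"]] / n_noi else NA_real_,
               n_trials = n)
  })
  out <- do.call(rbind, rows)
  out[order(out$subject_id, out$noise_level), ]
}

#' d-prime and criterion with log-linear correction
#'
#' Optional SDT indices from hit/false-alarm counts; the log-linear
#' (add 0.5) correction guards against empty cells.
#'
#' @param hits,misses,false_alarms,correct_rejections counts.
#' @param correction apply the log-linear correction (default TRUE).
#' @return a list: `dprime`, `criterion`.
#' @export
sdt_dprime <- function(hits, misses, false_alarms, correct_rejections,
                       correction = TRUE) {
  add <- if (correction) 0.5 else 0
  h <- (hits + add) / (hits + misses + 2 * add)
  f <- (false_alarms + add) / (false_alarms + correct_rejections + 2 * add)
  zh <- stats::qnorm(h)
  zf <- stats::qnorm(f)
  list(dprime = zh - zf, criterion = -(zh + zf) / 2)
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  cw <- cumsum(w)
  x[which(cw >= 0.5)[1]]
}

#' Bayesian bootstrap of a statistic
#'
#' Each posterior draw assigns the observations Dirichlet(1, ..., 1)
#' weights and recomputes the statistic with those weights. The 95%
#' credible interval is the 2.5/97.5 empirical percentile of the draws.
#'
#' @param values numeric observations (n >= 2).
#' @param statistic `"mean"` or `"median"` (weighted versions), or a
#'   function `f(values, weights)`.
#' @param n_draws number of posterior draws (default 4000).
#' @param seed optional seed.
#' @return an object of class `bayes_boot`: `draws`, `estimate` (posterior
#'   median), `ci_low`, `ci_high`, `statistic`.
#' @examples
#' b <- bayes_boot(rnorm(50), "mean", seed = 1)
#' b$ci_low < b$estimate && b$estimate < b$ci_high
#' @export
bayes_boot <- function(values, statistic = "mean", n_draws = 4000,
                       seed = NULL) {
  if (length(values) < 2L) {
    stop("Bayesian bootstrap needs at least 2 observations", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  stat_fun <- if (is.function(statistic)) {
    statistic
  } else {
    switch(match.arg(statistic, c("mean", "median")),
           mean = function(x, w) sum(w * x) / sum(w),
           median = weighted_median)
  }
  n <- length(values)
  g <- matrix(stats::rexp(n * n_draws), nrow = n_draws)
  w <- g / rowSums(g)
  draws <- vapply(seq_len(n_draws),
                  function(i) stat_fun(values, w[i, ]), numeric(1))
  qs <- stats::quantile(draws, c(0.025, 0.5, 0.975), names = FALSE)
  structure(list(draws = draws, estimate = qs[2], ci_low = qs[1],
                 ci_high = qs[3],
                 statistic = if (is.function(statistic)) "custom" else statistic,
                 n_obs = n, n_draws = n_draws),
            class = "bayes_boot")
}

#' @export
print.bayes_boot <- function(x, ...) {
  cat(sprintf("Bayesian bootstrap (%s, %d draws, n = %d): %.4g [%.4g, %.4g]\n",
              x$statistic, x$n_draws, x$n_obs, x$estimate, x$ci_low,
              x$ci_high))
  invisible(x)
}

#' @export
plot.bayes_boot <- function(x, ...) {
  graphics::hist(x$draws, breaks = 40, main = "posterior draws",
                 xlab = x$statistic, ...)
  graphics::abline(v = c(x$ci_low, x$estimate, x$ci_high), lty = c(2, 1, 2))
  invisible(x)
}

#' Posterior comparison of two groups
#'
#' Runs [bayes_boot()] on each group and compares paired draws.
#'
#' @param valuesA,valuesB observations per group.
#' @param statistic,n_draws,seed passed to [bayes_boot()].
#' @return a list: `bootA`, `bootB`, `p_greater` (posterior probability
#'   that the group-A statistic exceeds group B's), `diff_ci` (95%
#'   interval of the A - B draws).
#' @export
bayes_boot_compare <- function(valuesA, valuesB, statistic = "mean",
                               n_draws = 4000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bootA <- bayes_boot(valuesA, statistic, n_draws)
  bootB <- bayes_boot(valuesB, statistic, n_draws)
  d <- bootA$draws - bootB$draws
  list(bootA = bootA, bootB = bootB,
       p_greater = mean(d > 0),
       diff_ci = stats::quantile(d, c(0.025, 0.975), names = FALSE))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Reports `r`, a 95% CI from the Fisher z transform, and a two-sided p
#' from the t distribution on `n - 2` df — the conventional reporting
#' format `r(df) = ... [CI]`.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @param level confidence level.
#' @return a list: `r`, `ci_low`, `ci_high`, `p`, `df`, `n`.
#' @examples
#' pearson_ci(1:10, (1:10) * 2 + 1)$r # 1
#' @export
pearson_ci <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = level)
  list(r = unname(ct$estimate), ci_low = ct$conf.int[1],
       ci_high = ct$conf.int[2], p = ct$p.value,
       df = unname(ct$parameter), n = n)
}

#' Accuracy summaries per subject and group
#'
#' Proportion correct per subject x noise level (all passes pooled), and
#' per-level group medians with Bayesian-bootstrap credible intervals —
#' the summary behind the accuracy-by-noise figures.
#'
#' @param trials trial table with `subject_id`, `group`, `noise_level`,
#'   `correct`.
#' @param n_draws bootstrap draws for the group medians.
#' @param seed optional seed for the bootstrap.
#' @return a list: `subjects` (subject x level proportions) and `groups`
#'   (group x level median + CI).
#' @export
summarize_accuracy <- function(trials, n_draws = 4000, seed = NULL) {
  check_columns(trials, c("subject_id", "group", "noise_level", "correct"),
                "trials")
  if (!is.null(seed)) set.seed(seed)
  subj <- stats::aggregate(list(prop_correct = trials$correct),
                           by = list(subject_id = trials$subject_id,
                                     group = trials$group,
                                     noise_level = trials$noise_level),
                           FUN = mean)
  subj <- subj[order(subj$subject_id, subj$noise_level), ]
  cells <- unique(subj[, c("group", "noise_level")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    v <- subj$prop_correct[subj$group == cells$group[i] &
                             subj$noise_level == cells$noise_level[i]]
    if (length(v) < 2L) {
      return(data.frame(group = cells$group[i],
                        noise_level = cells$noise_level[i],
                        median = stats::median(v), ci_low = NA_real_,
                        ci_high = NA_real_, n_subjects = length(v)))
    }
    b <- bayes_boot(v, "median", n_draws = n_draws)
    data.frame(group = cells$group[i], noise_level = cells$noise_level[i],
               median = b$estimate, ci_low = b$ci_low, ci_high = b$ci_high,
               n_subjects = length(v))
  })
  groups <- do.call(rbind, rows)
  list(subjects = subj, groups = groups[order(groups$group,
                                              groups$noise_level), ])
}
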