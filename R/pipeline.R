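# Configuration, schema-validated I/O, and seeded end-to-end orchestration.

trial_schema <- c("subject_id", "group", "block", "pass", "trial_index",
                  "noise_level", "class", "response", "correct", "rt_s")
gaze_schema <- c("subject_id", "group", "block", "trial_index",
                 "noise_level", "class", "x_deg", "y_deg")
subject_schema <- c("subject_id", "group", "age", "iq")

validate_table <- function(df, schema, what) {
  missing <- setdiff(schema, names(df))
  if (length(missing)) {
    stop("parse error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read / write the canonical pipeline tables
#'
#' Plain UTF-8 comma-separated files with a header row and '.' decimals.
#' Required columns are validated on read (extra columns pass through);
#' a missing column raises a parse error naming it.
#'
#' @param path file path.
#' @param trials,gaze,subjects data frames in the canonical schemas (see
#'   [simulate_cohort()]).
#' @return the data frame (readers) or `path` invisibly (writers).
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_trials <- function(path) {
  validate_table(utils::read.csv(path), trial_schema, path)
}

#' @rdname pipeline_io
#' @export
write_trials <- function(trials, path) {
  validate_table(trials, trial_schema, "trials")
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_gaze <- function(path) {
  validate_table(utils::read.csv(path), gaze_schema, path)
}

#' @rdname pipeline_io
#' @export
write_gaze <- function(gaze, path) {
  validate_table(gaze, gaze_schema, "gaze")
  utils::write.csv(gaze, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_subjects <- function(path) {
  validate_table(utils::read.csv(path), subject_schema, path)
}

#' @rdname pipeline_io
#' @export
write_subjects <- function(subjects, path) {
  validate_table(subjects, subject_schema, "subjects")
  utils::write.csv(subjects, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param cohort a [cohort_config()].
#' @param master_seed integer master seed; every random stage derives its
#'   stream from it.
#' @param rt_bounds RT retention bounds in seconds.
#' @param quadrats quadrat-test grid `c(nx, ny)`.
#' @param n_boot Bayesian-bootstrap draws.
#' @param ppm_dummy quadrature dummy grid for [fit_ppm()].
#' @param out_dir output directory (`NULL`: return results only, write
#'   nothing).
#' @return a list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), master_seed = 1,
                       rt_bounds = c(0.25, 4.0), quadrats = c(5, 5),
                       n_boot = 4000, ppm_dummy = c(64, 36),
                       out_dir = NULL) {
  structure(list(cohort = cohort, master_seed = master_seed,
                 rt_bounds = rt_bounds, quadrats = quadrats,
                 n_boot = n_boot, ppm_dummy = ppm_dummy, out_dir = out_dir),
            class = "run_config")
}

#' Run the full simulate-and-analyse pipeline
#'
#' Executes, in order: cohort simulation, RT filtering, accuracy and SDT
#' summaries, double-pass slope fits and model-based noise-ratio
#' estimates, gaze window clipping, quadrat tests, intensity-model
#' likelihood-ratio tests, pairwise-distance and dispersion comparisons,
#' and the gaze-area correlations. With `out_dir` set it also writes the
#' canonical CSVs, a machine-readable `results.json` and a small PDF of
#' summary figures.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return a list of class `pipeline_result` with components `cohort`,
#'   `accuracy`, `sdt`, `rt`, `doublepass`, `gaze`, `correlations`.
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  seed <- config$master_seed
  groups <- names(config$cohort$groups)

  say("simulating cohort")
  cohort <- simulate_cohort(config$cohort, master_seed = seed)
  trials <- cohort$trials

  say("behavioral summaries")
  rtf <- filter_rt(trials, config$rt_bounds[1], config$rt_bounds[2])
  acc <- summarize_accuracy(trials, n_draws = config$n_boot,
                            seed = derive_seed(seed, "boot-acc"))
  sdt <- sdt_categorize(trials)
  rt_subj <- stats::aggregate(list(median_rt = rtf$trials$rt_s),
                              by = list(subject_id = rtf$trials$subject_id,
                                        group = rtf$trials$group,
                                        noise_level = rtf$trials$noise_level),
                              FUN = stats::median)
  rt_groups <- lapply(sort(unique(rt_subj$noise_level)), function(lv) {
    va <- rt_subj$median_rt[rt_subj$group == groups[1] &
                              rt_subj$noise_level == lv]
    vb <- rt_subj$median_rt[rt_subj$group == groups[2] &
                              rt_subj$noise_level == lv]
    bc <- bayes_boot_compare(va, vb, "median", n_draws = config$n_boot,
                             seed = derive_seed(seed, "boot-rt", lv))
    data.frame(noise_level = lv, medianA = bc$bootA$estimate,
               medianB = bc$bootB$estimate, p_greater = bc$p_greater)
  })

  say("double-pass analysis")
  dpp <- double_pass_points(trials)
  dp_levels <- sort(unique(dpp$noise_level))
  slope_fits <- list()
  sigma_ratios <- list()
  for (g in groups) {
    for (lv in dp_levels) {
      pts <- dpp[dpp$group == g & dpp$noise_level == lv, ]
      key <- paste(g, lv, sep = "_")
      # a group of perfectly consistent observers has every pa at 100:
      # the slope is unidentified there, so record the failure and move on
      slope_fits[[key]] <- tryCatch(fit_dp_slope(pts), error = function(e) NULL)
      est <- lapply(seq_len(nrow(pts)), function(i) {
        tryCatch(estimate_sigma_ratio(pts$pc[i], pts$pa[i]),
                 error = function(e) NULL)
      })
      ok <- !vapply(est, is.null, logical(1))
      sigma_ratios[[key]] <- data.frame(
        subject_id = pts$subject_id[ok], group = g, noise_level = lv,
        r_hat = vapply(est[ok], `[[`, numeric(1), "r_hat"),
        d_hat = vapply(est[ok], `[[`, numeric(1), "d_hat"))
    }
  }
  slope_tests <- lapply(dp_levels, function(lv) {
    fA <- slope_fits[[paste(groups[1], lv, sep = "_")]]
    fB <- slope_fits[[paste(groups[2], lv, sep = "_")]]
    if (is.null(fA) || is.null(fB)) {
      return(data.frame(noise_level = lv, t_ratio = NA_real_,
                        df = NA_real_, p = NA_real_))
    }
    ct <- compare_slopes(fA, fB)
    data.frame(noise_level = lv, t_ratio = ct$t_ratio, df = ct$df, p = ct$p)
  })

  say("gaze point-pattern analysis")
  set.seed(derive_seed(seed, "gaze-analysis"))
  clip <- clip_to_window(cohort$gaze)
  pat <- clip$pattern
  quad_by_group <- lapply(groups, function(g) {
    sel <- pat$marks$group == g
    qt <- quadrat_test(point_pattern(pat$x[sel], pat$y[sel], pat$window),
                       config$quadrats[1], config$quadrats[2])
    data.frame(group = g, chi2 = qt$chi2, df = qt$df, p = qt$p)
  })
  # intensity models: spatial trend + noise level, then + group,
  # then + group x coordinates; one shared quadrature stratification
  strata <- c("noise_level", "group")
  m_noise <- fit_ppm(pat, 2, covariates = c("noise_level"),
                     strata = strata, dummy = config$ppm_dummy)
  m_group <- fit_ppm(pat, 2, covariates = c("noise_level", "group"),
                     strata = strata, dummy = config$ppm_dummy)
  m_gxs <- fit_ppm(pat, 2, covariates = c("noise_level", "group"),
                   spatial_interactions = "group", strata = strata,
                   dummy = config$ppm_dummy)
  ppm_tests <- list(group = lr_test(m_noise, m_group),
                    group_x_space = lr_test(m_group, m_gxs))
  # per-subject mean gaze positions -> pairwise distances per group
  mean_pos <- stats::aggregate(
    list(x = cohort$gaze$x_deg, y = cohort$gaze$y_deg),
    by = list(subject_id = cohort$gaze$subject_id,
              group = cohort$gaze$group), FUN = mean)
  pd <- lapply(groups, function(g) {
    s <- pairwise_distance_summary(mean_pos$x[mean_pos$group == g],
                                   mean_pos$y[mean_pos$group == g])
    data.frame(group = g, median = s$median, q1 = s$q1, q3 = s$q3)
  })
  disp <- per_subject_dispersion(cohort$gaze, groups = groups,
                                 n_draws = config$n_boot,
                                 seed = derive_seed(seed, "boot-disp"))

  say("correlations")
  acc_subj <- stats::aggregate(list(prop_correct = trials$correct),
                               by = list(subject_id = trials$subject_id),
                               FUN = mean)
  rt_all <- stats::aggregate(list(median_rt = rtf$trials$rt_s),
                             by = list(subject_id = rtf$trials$subject_id),
                             FUN = stats::median)
  iq_tab <- cohort$subjects[, c("subject_id", "iq")]
  clipped_gaze <- data.frame(subject_id = pat$marks$subject_id,
                             x_deg = pat$x, y_deg = pat$y)
  correlations <- list(
    gaze_area = gaze_area_correlations(clipped_gaze, acc_subj, rt_all,
                                       iq_tab),
    accuracy_iq = pearson_ci(
      merge(acc_subj, iq_tab, by = "subject_id")$prop_correct,
      merge(acc_subj, iq_tab, by = "subject_id")$iq))

  result <- structure(
    list(cohort = cohort,
         accuracy = acc,
         sdt = sdt,
         rt = list(subjects = rt_subj, groups = do.call(rbind, rt_groups),
                   exclusions = rtf$exclusions),
         doublepass = list(points = dpp, fits = slope_fits,
                           slope_tests = do.call(rbind, slope_tests),
                           sigma_ratios = do.call(rbind, sigma_ratios)),
         gaze = list(excluded_fraction = clip$excluded_fraction,
                     excluded_by_group = clip$excluded_by_group,
                     quadrat = do.call(rbind, quad_by_group),
                     ppm_tests = ppm_tests,
                     pairwise = do.call(rbind, pd),
                     dispersion = disp),
         correlations = correlations,
         config = config),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(result, config$out_dir, verbose = verbose)
  }
  result
}

results_json <- function(result) {
  dp <- result$doublepass
  list(
    accuracy_group_medians = result$accuracy$groups,
    rt_group_medians = result$rt$groups,
    doublepass_points = dp$points,
    dp_slopes = lapply(dp$fits, function(f) {
      list(m = unname(f$coefficients["m"]), ci = unname(f$ci), se = f$se,
           n = f$n_points)
    }),
    slope_tests = dp$slope_tests,
    sigma_ratios = dp$sigma_ratios,
    gaze = list(excluded_fraction = result$gaze$excluded_fraction,
                quadrat = result$gaze$quadrat,
                ppm_tests = result$gaze$ppm_tests,
                pairwise_distances = result$gaze$pairwise,
                dispersion_comparison = result$gaze$dispersion$comparison),
    correlations = list(
      gaze_area_accuracy = result$correlations$gaze_area$accuracy,
      gaze_area_rt = result$correlations$gaze_area$rt,
      gaze_area_iq = result$correlations$gaze_area$iq,
      accuracy_iq = result$correlations$accuracy_iq))
}

write_pipeline_outputs <- function(result, out_dir, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_trials(result$cohort$trials, file.path(out_dir, "trials.csv"))
  write_gaze(result$cohort$gaze, file.path(out_dir, "gaze.csv"))
  write_subjects(result$cohort$subjects, file.path(out_dir, "subjects.csv"))
  utils::write.csv(result$doublepass$points,
                   file.path(out_dir, "doublepass_points.csv"),
                   row.names = FALSE)
  utils::write.csv(result$accuracy$subjects,
                   file.path(out_dir, "accuracy_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(result$sdt, file.path(out_dir, "sdt_counts.csv"),
                   row.names = FALSE)
  jsonlite::write_json(results_json(result),
                       file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  grDevices::pdf(file.path(out_dir, "report.pdf"), width = 8, height = 6)
  on.exit(grDevices::dev.off())
  plot(result)
  if (verbose) message("[pipeline] outputs written to ", out_dir)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result (master seed ", x$config$master_seed, ")\n", sep = "")
  print(x$cohort)
  cat("Slope comparisons (groupA - groupB):\n")
  print(x$doublepass$slope_tests, row.names = FALSE)
  cat("Median pairwise distance of mean gaze positions:\n")
  print(x$gaze$pairwise, row.names = FALSE)
  invisible(x)
}

#' @export
plot.pipeline_result <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  ga <- x$accuracy$groups
  groups <- unique(ga$group)
  graphics::plot(NA, xlim = range(ga$noise_level),
                 ylim = range(c(ga$ci_low, ga$ci_high)),
                 xlab = "noise level (deg)", ylab = "proportion correct",
                 main = "accuracy")
  for (i in seq_along(groups)) {
    g <- ga[ga$group == groups[i], ]
    graphics::lines(g$noise_level, g$median, type = "b", pch = i, lty = i)
    graphics::arrows(g$noise_level, g$ci_low, g$noise_level, g$ci_high,
                     angle = 90, code = 3, length = 0.02)
  }
  graphics::legend("bottomleft", legend = groups, pch = seq_along(groups),
                   lty = seq_along(groups), bty = "n")
  dpp <- x$doublepass$points
  graphics::plot(dpp$pa, dpp$pc, pch = as.integer(factor(dpp$group)),
                 xlab = "percent agreement", ylab = "percent correct",
                 main = "double pass")
  rtg <- x$rt$groups
  graphics::plot(rtg$noise_level, rtg$medianA, type = "b", pch = 1,
                 ylim = range(c(rtg$medianA, rtg$medianB)),
                 xlab = "noise level (deg)", ylab = "median RT (s)",
                 main = "reaction time")
  graphics::lines(rtg$noise_level, rtg$medianB, type = "b", pch = 2, lty = 2)
  dc <- x$gaze$dispersion$comparison
  graphics::plot(dc$noise_level, dc$medianA, type = "b", pch = 1,
                 ylim = range(c(dc$medianA, dc$medianB)),
                 xlab = "noise level (deg)", ylab = "gaze SD (deg)",
                 main = "gaze dispersion")
  graphics::lines(dc$noise_level, dc$medianB, type = "b", pch = 2, lty = 2)
  invisible(x)
}
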