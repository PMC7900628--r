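# Synthetic two-group study: subjects, double-pass responses, RTs, gaze.

#' Group-level generative parameters
#'
#' Population distributions from which per-subject [observer_params()] are
#' drawn for one group. Defaults for the two groups are provided by
#' [cohort_config()]; see the package vignette for the rationale behind
#' each value.
#'
#' @param n group size.
#' @param sex_ratio number of male / female subjects (metadata only).
#' @param age_mean,age_sd age distribution, years.
#' @param iq_mean,iq_sd full-scale IQ distribution.
#' @param sigma_add_mean,sigma_add_sd additive internal noise.
#' @param k_mult_mean,k_mult_sd stimulus-dependent internal-noise slope.
#' @param d0_mean,d0_sd signal gain at zero jitter.
#' @param lapse lapse rate.
#' @param rt_shift,rt_shift_sd,rt_scale,rt_shape,rt_noise_slope
#'   reaction-time model (seconds).
#' @param gaze_sigma0_mean,gaze_sigma0_sd baseline within-subject gaze SD
#'   (degrees).
#' @param gaze_noise_slope fractional gaze-SD increase per degree of
#'   jitter.
#' @param gaze_mu_sd between-subject SD of the mean gaze offset (degrees).
#' @param gaze_aspect horizontal/vertical elongation of the gaze cloud.
#' @param iq_coupling correlation magnitude between IQ and (low) additive
#'   internal noise: higher-IQ subjects get lower `sigma_add`.
#' @param gaze_coupling correlation magnitude between gaze dispersion and
#'   additive internal noise: noisier observers also fixate less stably.
#' @return a list of class `group_params`.
#' @export
group_params <- function(n, sex_ratio = c(n, 0),
                         age_mean = 11.5, age_sd = 2.3,
                         iq_mean = 100, iq_sd = 15,
                         sigma_add_mean = 0.8, sigma_add_sd = 0.15,
                         k_mult_mean = 0.015, k_mult_sd = 0.004,
                         d0_mean = 4.0, d0_sd = 0.3,
                         lapse = 0.02,
                         rt_shift = 0.35, rt_shift_sd = 0.05,
                         rt_scale = 0.12, rt_shape = 4,
                         rt_noise_slope = 0.008,
                         gaze_sigma0_mean = 1.0, gaze_sigma0_sd = 0.15,
                         gaze_noise_slope = 0.005,
                         gaze_mu_sd = 0.1, gaze_aspect = 1.5,
                         iq_coupling = 0.5, gaze_coupling = 0.4) {
  structure(as.list(environment()), class = "group_params")
}

#' Cohort configuration
#'
#' The synthetic study emulated by [simulate_cohort()]: an ASD-labelled
#' group of 24 subjects and a TD-labelled comparison group of 32, each
#' performing the full eight-block double-pass session. The default group
#' parameters encode the qualitative structure the downstream analyses
#' assume: the ASD-labelled group has a larger stimulus-dependent
#' internal-noise coefficient, a slightly larger additive noise and lower
#' signal gain, slower shifted-gamma reaction times, and larger,
#' noise-sensitive gaze dispersion with more variable mean gaze positions.
#' Additive internal noise is nearly equal across groups, so low-noise
#' double-pass slopes are similar while high-noise slopes separate.
#' IQ distributions follow the study groups (means ~84 vs ~102).
#'
#' @param groups named list of [group_params()], one per group label.
#' @param spec the [stimulus_spec()] all subjects share.
#' @return a list of class `cohort_config`.
#' @examples
#' cfg <- cohort_config()
#' names(cfg$groups)
#' @export
cohort_config <- function(groups = NULL, spec = stimulus_spec()) {
  if (is.null(groups)) {
    groups <- list(
      ASD = group_params(
        n = 24, sex_ratio = c(16, 8), age_mean = 11.6, age_sd = 2.4,
        iq_mean = 84.04, iq_sd = 17.24,
        sigma_add_mean = 0.80, sigma_add_sd = 0.13,
        k_mult_mean = 0.030, k_mult_sd = 0.006,
        d0_mean = 3.7, d0_sd = 0.3, lapse = 0.04,
        rt_shift = 0.50, rt_noise_slope = 0.008,
        gaze_sigma0_mean = 1.6, gaze_sigma0_sd = 0.25,
        gaze_noise_slope = 0.010, gaze_mu_sd = 0.12),
      TD = group_params(
        n = 32, sex_ratio = c(24, 8), age_mean = 11.4, age_sd = 2.3,
        iq_mean = 102.28, iq_sd = 13.30,
        sigma_add_mean = 0.75, sigma_add_sd = 0.12,
        k_mult_mean = 0.012, k_mult_sd = 0.004,
        d0_mean = 4.2, d0_sd = 0.3, lapse = 0.015,
        rt_shift = 0.35, rt_noise_slope = 0.008,
        gaze_sigma0_mean = 1.0, gaze_sigma0_sd = 0.15,
        gaze_noise_slope = 0.004, gaze_mu_sd = 0.075))
  }
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  structure(list(groups = groups, spec = spec), class = "cohort_config")
}

truncate_at <- function(x, lo) pmax(x, lo)

# draw per-subject profiles (metadata + observer params) for one group
draw_group_subjects <- function(label, gp, id_offset, seed) {
  set.seed(seed)
  n <- gp$n
  z_perf <- stats::rnorm(n) # latent performance/severity factor
  z_iq <- stats::rnorm(n)
  z_gaze <- stats::rnorm(n)
  iq <- gp$iq_mean + gp$iq_sd *
    (-gp$iq_coupling * z_perf + sqrt(1 - gp$iq_coupling^2) * z_iq)
  sigma_add <- truncate_at(gp$sigma_add_mean + gp$sigma_add_sd * z_perf, 0)
  gaze_sigma0 <- truncate_at(
    gp$gaze_sigma0_mean + gp$gaze_sigma0_sd *
      (gp$gaze_coupling * z_perf + sqrt(1 - gp$gaze_coupling^2) * z_gaze),
    0.2)
  k_mult <- truncate_at(stats::rnorm(n, gp$k_mult_mean, gp$k_mult_sd), 0)
  d0 <- truncate_at(stats::rnorm(n, gp$d0_mean, gp$d0_sd), 0.5)
  rt_shift <- truncate_at(stats::rnorm(n, gp$rt_shift, gp$rt_shift_sd), 0.26)
  age <- round(pmin(16, pmax(8, stats::rnorm(n, gp$age_mean, gp$age_sd))), 1)
  sex <- sample(rep(c("M", "F"), gp$sex_ratio))
  mu_x <- stats::rnorm(n, 0, gp$gaze_mu_sd)
  mu_y <- stats::rnorm(n, 0, gp$gaze_mu_sd)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    subjects[[i]] <- list(
      subject_id = sprintf("S%02d", id_offset + i),
      group = label, age = age[i], sex = sex[i], iq = round(iq[i], 1),
      observer = observer_params(
        sigma_add = sigma_add[i], k_mult = k_mult[i], d0 = d0[i],
        lapse = gp$lapse, rt_shift = rt_shift[i], rt_scale = gp$rt_scale,
        rt_shape = gp$rt_shape, rt_noise_slope = gp$rt_noise_slope,
        gaze_mu = c(mu_x[i], mu_y[i]), gaze_sigma0 = gaze_sigma0[i],
        gaze_noise_slope = gp$gaze_noise_slope,
        gaze_aspect = gp$gaze_aspect))
  }
  subjects
}

#' Simulate the full synthetic study
#'
#' Every subject receives a complete eight-block session from
#' [generate_session_design()] (six noise levels, pass-2 replicas at the
#' double-pass levels) and responds through a linear-amplifier observer:
#' the decision variable is `d(delta) * 1[signal] + e + sigma_i * eps`,
#' where `e` is the standardized background-template statistic of the
#' frozen stimulus (identical across the two passes of a repeated block)
#' and `eps` is a fresh standard-normal draw per presentation. Reaction
#' times and one gaze point per trial are generated alongside.
#'
#' All randomness derives from `master_seed` through [derive_seed()]
#' streams per subject and purpose, so any subject can be regenerated in
#' isolation and the full output is byte-reproducible.
#'
#' @param config a [cohort_config()].
#' @param master_seed integer master seed.
#' @param verbose print progress per subject.
#' @return a list of class `cohort` with data frames `trials` (one row per
#'   trial), `gaze` (one gaze point per trial) and `subjects` (metadata +
#'   true generative parameters, for recovery tests).
#' @examples
#' cfg <- cohort_config(groups = list(
#'   A = group_params(n = 2), B = group_params(n = 2)))
#' ch <- simulate_cohort(cfg, master_seed = 1)
#' nrow(ch$trials) / 4 # 480 trials per subject
#' @export
simulate_cohort <- function(config, master_seed, verbose = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  spec <- config$spec
  grid <- build_hex_grid(spec$n_cols, spec$n_rows, spec$spacing)
  ci <- select_contour_path(grid, spec$contour_length,
                            spec$contour_orientation, spec$spacing)
  subjects <- list()
  offset <- 0L
  for (label in names(config$groups)) {
    gp <- config$groups[[label]]
    subjects <- c(subjects, draw_group_subjects(
      label, gp, offset, derive_seed(master_seed, "subjects", label)))
    offset <- offset + gp$n
  }
  trials_list <- vector("list", length(subjects))
  gaze_list <- vector("list", length(subjects))
  for (si in seq_along(subjects)) {
    sub <- subjects[[si]]
    if (verbose) message("simulating ", sub$subject_id, " (", sub$group, ")")
    session <- generate_session_design(
      spec, derive_seed(master_seed, "stimuli", sub$subject_id))
    res <- simulate_subject_session(sub, session, grid, ci,
                                    master_seed = master_seed)
    trials_list[[si]] <- res$trials
    gaze_list[[si]] <- res$gaze
  }
  subj_df <- do.call(rbind, lapply(subjects, function(s) {
    o <- s$observer
    data.frame(subject_id = s$subject_id, group = s$group, age = s$age,
               sex = s$sex, iq = s$iq,
               sigma_add = o$sigma_add, k_mult = o$k_mult, d0 = o$d0,
               lapse = o$lapse, rt_shift = o$rt_shift,
               gaze_sigma0 = o$gaze_sigma0,
               gaze_noise_slope = o$gaze_noise_slope,
               gaze_mu_x = o$gaze_mu[1], gaze_mu_y = o$gaze_mu[2])
  }))
  structure(list(trials = do.call(rbind, trials_list),
                 gaze = do.call(rbind, gaze_list),
                 subjects = subj_df, master_seed = master_seed),
            class = "cohort")
}

simulate_subject_session <- function(sub, session, grid, contour_indices,
                                     master_seed) {
  obs <- sub$observer
  spec <- session$spec
  template <- contour_template(grid, contour_indices,
                               obs$template_weight_bg, spec$spacing)
  set.seed(derive_seed(master_seed, "behavior", sub$subject_id))
  trials_out <- vector("list", length(session$blocks))
  gaze_out <- vector("list", length(session$blocks))
  for (b in seq_along(session$blocks)) {
    blk <- session$blocks[[b]]
    n <- length(blk$trials)
    delta <- blk$noise_level
    d <- signal_gain(obs, delta)
    gamma <- if (is.null(obs$criterion)) d / 2 else obs$criterion
    sigma_i <- internal_noise_sd(obs, delta)
    s <- vapply(blk$trials, function(tr) {
      d * (tr$stimulus_class == "signal") + external_component(tr, template)
    }, numeric(1))
    yes <- (s + stats::rnorm(n, 0, sigma_i)) > gamma
    lapses <- stats::runif(n) < obs$lapse
    yes[lapses] <- stats::runif(sum(lapses)) < 0.5
    cls <- blk$classes
    correct <- yes == (cls == "signal")
    rt <- simulate_rt(n, obs, delta)
    gz <- simulate_gaze(n, obs, delta)
    trials_out[[b]] <- data.frame(
      subject_id = sub$subject_id, group = sub$group, age = sub$age,
      iq = sub$iq, block = blk$block, pass = blk$pass,
      trial_index = seq_len(n), noise_level = delta, class = cls,
      response = ifelse(yes, "yes", "no"), correct = correct,
      rt_s = rt, decision_stat = s)
    gaze_out[[b]] <- data.frame(
      subject_id = sub$subject_id, group = sub$group, block = blk$block,
      trial_index = seq_len(n), noise_level = delta, class = cls,
      x_deg = gz[, 1], y_deg = gz[, 2])
  }
  list(trials = do.call(rbind, trials_out),
       gaze = do.call(rbind, gaze_out))
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$subjects), "subjects (",
      paste(sprintf("%s n=%d", names(table(x$subjects$group)),
                    as.integer(table(x$subjects$group))), collapse = ", "),
      ")\n")
  cat(" ", nrow(x$trials), "trial rows,", nrow(x$gaze), "gaze points\n")
  invisible(x)
}
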