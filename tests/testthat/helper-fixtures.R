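# Shared fixtures: a coarse specification for cheap stimulus generation
# and a miniature cohort configuration.

# small grid, short contour: same geometry rules, ~100x cheaper to draw
mini_spec <- function(...) {
  stimulus_spec(n_cols = 7, n_rows = 7, spacing = 1.0, contour_length = 4,
                px_per_deg = 8, ...)
}

mini_cohort_config <- function(nA = 2, nB = 2, ...) {
  cohort_config(groups = list(
    ASD = group_params(n = nA, gaze_sigma0_mean = 1.6, k_mult_mean = 0.03),
    TD = group_params(n = nB)),
    ...)
}

# deterministic trial table for behavioral tests
toy_trials <- function() {
  data.frame(
    subject_id = rep(c("S01", "S02"), each = 8),
    group = rep(c("A", "B"), each = 8),
    noise_level = rep(c(10, 45), times = 8),
    class = rep(c("signal", "signal", "noise", "noise"), 4),
    response = rep(c("yes", "no"), 8),
    rt_s = seq(0.3, 1.8, length.out = 16),
    correct = rep(c(TRUE, FALSE, FALSE, TRUE), 4))
}
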