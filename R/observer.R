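# Generative observer: decision statistic, responses, reaction times, gaze.

#' Observer parameters
#'
#' Parameters of the generative observer used by the synthetic cohort.
#' The decision-variable scale is normalised so that the stimulus-driven
#' (external) noise has unit SD; internal noise then has SD
#' \eqn{\sigma_i = \sqrt{\sigma_{add}^2 + (k_{mult}\,\delta)^2}}, i.e. an
#' additive component plus a component growing with the external jitter
#' \eqn{\delta}, and \eqn{\sigma_i/\sigma_e = \sigma_i} directly.
#'
#' @param sigma_add additive internal-noise SD (external-noise-SD units).
#' @param k_mult stimulus-dependent internal-noise coefficient, per degree
#'   of external jitter.
#' @param d0 signal gain at zero jitter: the separation between signal and
#'   noise decision-variable means at delta = 0. The effective separation
#'   at level delta is `d0 * (1 + cos(2 delta)) / 2`.
#' @param criterion decision criterion gamma; `NULL` (default) places it
#'   midway between the expected signal and noise statistics per level
#'   (unbiased observer).
#' @param lapse probability of replacing the decision by a fair coin.
#' @param template_weight_bg weight of the background elements adjacent to
#'   the contour in the matched-filter template (contour elements have
#'   weight 1).
#' @param rt_shift,rt_scale,rt_shape shifted-gamma reaction-time
#'   parameters (seconds; RT = shift + Gamma(shape, scale)).
#' @param rt_noise_slope fractional RT-scale increase per degree of jitter.
#' @param gaze_mu 2-vector, mean gaze offset from screen centre (degrees).
#' @param gaze_sigma0 baseline gaze-position SD per axis (degrees).
#' @param gaze_noise_slope fractional gaze-SD increase per degree of jitter.
#' @param gaze_aspect ratio of horizontal to vertical gaze SD (elongation
#'   of the fixation cloud).
#' @return an object of class `observer_params`.
#' @examples
#' observer_params(sigma_add = 0.8, k_mult = 0.012)
#' @export
observer_params <- function(sigma_add = 0.8, k_mult = 0.015, d0 = 4.0,
                            criterion = NULL, lapse = 0.02,
                            template_weight_bg = 0.5,
                            rt_shift = 0.35, rt_scale = 0.12, rt_shape = 4,
                            rt_noise_slope = 0.008,
                            gaze_mu = c(0, 0), gaze_sigma0 = 1.0,
                            gaze_noise_slope = 0.005, gaze_aspect = 1.5) {
  stopifnot(sigma_add >= 0, k_mult >= 0, lapse >= 0, lapse <= 1,
            rt_shape > 0, rt_scale > 0, gaze_sigma0 > 0,
            length(gaze_mu) == 2, template_weight_bg >= 0, d0 >= 0,
            gaze_aspect > 0)
  structure(
    list(sigma_add = sigma_add, k_mult = k_mult, d0 = d0,
         criterion = criterion, lapse = lapse,
         template_weight_bg = template_weight_bg,
         rt_shift = rt_shift, rt_scale = rt_scale, rt_shape = rt_shape,
         rt_noise_slope = rt_noise_slope,
         gaze_mu = as.numeric(gaze_mu), gaze_sigma0 = gaze_sigma0,
         gaze_noise_slope = gaze_noise_slope, gaze_aspect = gaze_aspect),
    class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("observer_params:\n")
  cat(sprintf("  internal noise: sigma_add %.3f, k_mult %.4f/deg (sigma_i at 45 deg: %.3f)\n",
              x$sigma_add, x$k_mult, internal_noise_sd(x, 45)))
  cat(sprintf("  signal gain d0 %.2f, lapse %.3f, template bg weight %.2f\n",
              x$d0, x$lapse, x$template_weight_bg))
  cat(sprintf("  RT: %.2f + Gamma(%g, %.3f s), slope %.4f/deg\n",
              x$rt_shift, x$rt_shape, x$rt_scale, x$rt_noise_slope))
  cat(sprintf("  gaze: sigma0 %.2f deg, slope %.4f/deg, aspect %.2f\n",
              x$gaze_sigma0, x$gaze_noise_slope, x$gaze_aspect))
  invisible(x)
}

#' Internal-noise SD at a given external-noise level
#'
#' @param observer an [observer_params()].
#' @param delta external jitter in degrees.
#' @return numeric, \eqn{\sqrt{\sigma_{add}^2 + (k_{mult}\delta)^2}}.
#' @export
internal_noise_sd <- function(observer, delta) {
  sqrt(observer$sigma_add^2 + (observer$k_mult * delta)^2)
}

# signal gain at jitter level delta (degrees)
signal_gain <- function(observer, delta) {
  observer$d0 * (1 + cos(2 * delta * pi / 180)) / 2
}

#' Observer template over grid positions
#'
#' The matched-filter template: contour positions with weight 1 plus their
#' adjacent background positions with weight `template_weight_bg`.
#'
#' @param grid grid data frame.
#' @param contour_indices contour element indices.
#' @param weight_bg weight of the adjacent background elements; 0 gives a
#'   contour-only template.
#' @param spacing lattice spacing of `grid`.
#' @return data frame with columns `index` and `weight`.
#' @export
contour_template <- function(grid, contour_indices, weight_bg = 0.5,
                             spacing = 1.044) {
  idx <- contour_indices
  w <- rep(1, length(idx))
  if (weight_bg > 0) {
    nb <- grid_neighbors(grid, contour_indices, spacing)
    idx <- c(idx, nb)
    w <- c(w, rep(weight_bg, length(nb)))
  }
  data.frame(index = idx, weight = w)
}

#' Matched-filter decision statistic
#'
#' The weighted circular match between element orientations and a
#' reference orientation:
#' \deqn{s = \sum_i w_i \cos(2(\theta_i - \theta_{ref})) / \sum_i w_i,}
#' computed over the template positions. `s` is 1 when every template
#' element is at the reference orientation and 0 in expectation over a
#' uniform background. Because cosine is even, balanced +/- delta jitter
#' makes the contour contribution exactly `cos(2 delta)` — zero at 45
#' degrees and negative beyond — which is why the generative observer uses
#' a calibrated signal gain rather than this raw value (see the package
#' vignette).
#'
#' @param orientations element orientations in degrees (full grid vector).
#' @param template data frame from [contour_template()] (`index`,
#'   `weight`).
#' @param ref_angle reference (contour) orientation, degrees.
#' @return numeric scalar in `[-1, 1]`.
#' @examples
#' g <- build_hex_grid(5, 5, 1)
#' tpl <- data.frame(index = 1:3, weight = 1)
#' decision_statistic(rep(60, 25), tpl) # 1
#' @export
decision_statistic <- function(orientations, template, ref_angle = 60) {
  check_columns(template, c("index", "weight"), "template")
  if (nrow(template) == 0L) {
    stop("empty template", call. = FALSE)
  }
  th <- orientations[template$index]
  w <- template$weight
  sum(w * cos(2 * (th - ref_angle) * pi / 180)) / sum(w)
}

# Frozen (stimulus-driven) standardized external-noise component of one
# trial: the background part of the template statistic divided by its
# closed-form SD (Var cos(2U) = 1/2 for U uniform on a half-turn). On
# signal trials the contour contribution is deterministic and excluded; on
# noise trials the contour slots are background draws and included.
external_component <- function(trial, template) {
  w <- template$weight
  is_contour <- template$index %in% trial$contour_indices &
    trial$stimulus_class == "signal"
  wb <- w[!is_contour]
  if (!length(wb)) return(0)
  th <- trial$orientations[template$index[!is_contour]]
  raw <- sum(wb * cos(2 * (th - trial$contour_orientation) * pi / 180))
  raw / sqrt(0.5 * sum(wb^2))
}

#' Simulate one yes/no response
#'
#' Threshold rule on the decision statistic: respond "yes" when
#' `s + eps > gamma`, with internal noise `eps ~ N(0, sigma_i^2)` and
#' `sigma_i` from [internal_noise_sd()]. With probability `lapse` the
#' decision is replaced by a fair coin.
#'
#' @param s decision statistic of the trial.
#' @param observer an [observer_params()].
#' @param delta external jitter level of the trial, degrees.
#' @param criterion decision criterion; defaults to the observer's, which
#'   itself defaults to half the signal gain at `delta` (unbiased).
#' @return character, `"yes"` or `"no"`.
#' @export
simulate_response <- function(s, observer, delta,
                              criterion = observer$criterion) {
  if (is.null(criterion)) criterion <- signal_gain(observer, delta) / 2
  sigma_i <- internal_noise_sd(observer, delta)
  yes <- (s + stats::rnorm(1, 0, sigma_i)) > criterion
  if (observer$lapse > 0 && stats::runif(1) < observer$lapse) {
    yes <- stats::runif(1) < 0.5
  }
  if (yes) "yes" else "no"
}

#' Simulate reaction times
#'
#' Shifted-gamma model: `rt = rt_shift + Gamma(rt_shape, scale)` with
#' `scale = rt_scale * (1 + rt_noise_slope * delta)`, so mean RT grows
#' linearly with the external-noise level.
#'
#' @param n number of trials.
#' @param observer an [observer_params()].
#' @param delta external jitter level, degrees (scalar or length `n`).
#' @return numeric vector of RTs in seconds.
#' @export
simulate_rt <- function(n, observer, delta) {
  scale <- observer$rt_scale * (1 + observer$rt_noise_slope * delta)
  observer$rt_shift + stats::rgamma(n, shape = observer$rt_shape,
                                    scale = scale)
}

#' Simulate per-trial gaze positions
#'
#' One mean-gaze point per trial from a bivariate normal centred on the
#' subject's `gaze_mu`, with axis SDs
#' `gaze_sigma0 * (1 + gaze_noise_slope * delta)` scaled by the elongation
#' `gaze_aspect` horizontally and its inverse vertically. Points are not
#' clipped to the screen; window clipping is an analysis step
#' ([clip_to_window()]).
#'
#' @param n number of trials.
#' @param observer an [observer_params()].
#' @param delta external jitter level, degrees.
#' @return an `n x 2` matrix of (x, y) in degrees.
#' @export
simulate_gaze <- function(n, observer, delta) {
  s <- observer$gaze_sigma0 * (1 + observer$gaze_noise_slope * delta)
  sx <- s * sqrt(observer$gaze_aspect)
  sy <- s / sqrt(observer$gaze_aspect)
  cbind(x = stats::rnorm(n, observer$gaze_mu[1], sx),
        y = stats::rnorm(n, observer$gaze_mu[2], sy))
}
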