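# Spatial point patterns of gaze positions: container, window clipping,
# quadrat test, distances, ellipses, dispersion.

#' Spatial point pattern of gaze positions
#'
#' A set of (x, y) points in degrees of visual angle inside a rectangular
#' observation window, optionally carrying per-point marks (subject,
#' group, noise level, stimulus class). The default window is the screen:
#' `[-20, 20] x [-11.25, 11.25]` degrees (area 900 deg^2).
#'
#' @param x,y point coordinates in degrees.
#' @param window `c(xmin, xmax, ymin, ymax)`.
#' @param marks optional data frame of per-point marks (one row per
#'   point).
#' @return an object of class `point_pattern`.
#' @examples
#' pp <- point_pattern(runif(10, -5, 5), runif(10, -5, 5))
#' pp$n
#' @export
point_pattern <- function(x, y, window = c(-20, 20, -11.25, 11.25),
                          marks = NULL) {
  stopifnot(length(x) == length(y), length(window) == 4,
            window[2] > window[1], window[4] > window[3])
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("point coordinates must be finite", call. = FALSE)
  }
  inside <- x >= window[1] & x <= window[2] &
    y >= window[3] & y <= window[4]
  if (any(!inside)) {
    stop(sum(!inside), " point(s) lie outside the window; use ",
         "clip_to_window() first", call. = FALSE)
  }
  if (!is.null(marks)) {
    stopifnot(is.data.frame(marks), nrow(marks) == length(x))
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 window = as.numeric(window), marks = marks,
                 n = length(x)),
            class = "point_pattern")
}

window_area <- function(window) {
  (window[2] - window[1]) * (window[4] - window[3])
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point_pattern: %d points in [%g, %g] x [%g, %g] (area %g)\n",
              x$n, x$window[1], x$window[2], x$window[3], x$window[4],
              window_area(x$window)))
  if (!is.null(x$marks)) {
    cat("  marks:", paste(names(x$marks), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.point_pattern <- function(x, cex = 0.4, ...) {
  graphics::plot(x$x, x$y, xlim = x$window[1:2], ylim = x$window[3:4],
                 asp = 1, xlab = "x (deg)", ylab = "y (deg)", pch = 16,
                 cex = cex, ...)
  graphics::rect(x$window[1], x$window[3], x$window[2], x$window[4])
  invisible(x)
}

#' Clip gaze points to the screen window
#'
#' Retains only points inside the window (boundary inclusive) and reports
#' the excluded fraction, overall and per group when a `group` mark is
#' available.
#'
#' @param gaze a data frame with columns `x_deg`, `y_deg` and optional
#'   mark columns (`subject_id`, `group`, `noise_level`, `class`).
#' @param window `c(xmin, xmax, ymin, ymax)` in degrees.
#' @return a list: `pattern` (a [point_pattern()] carrying the mark
#'   columns), `excluded_fraction`, and `excluded_by_group` (named vector,
#'   when a group mark exists).
#' @export
clip_to_window <- function(gaze, window = c(-20, 20, -11.25, 11.25)) {
  check_columns(gaze, c("x_deg", "y_deg"), "gaze")
  if (any(!is.finite(gaze$x_deg)) || any(!is.finite(gaze$y_deg))) {
    stop("gaze coordinates must be finite", call. = FALSE)
  }
  inside <- gaze$x_deg >= window[1] & gaze$x_deg <= window[2] &
    gaze$y_deg >= window[3] & gaze$y_deg <= window[4]
  by_group <- NULL
  if ("group" %in% names(gaze)) {
    by_group <- tapply(!inside, gaze$group, mean)
  }
  kept <- gaze[inside, , drop = FALSE]
  marks <- kept[, setdiff(names(kept), c("x_deg", "y_deg")), drop = FALSE]
  if (!ncol(marks)) marks <- NULL
  list(pattern = point_pattern(kept$x_deg, kept$y_deg, window,
                               marks = marks),
       excluded_fraction = mean(!inside),
       excluded_by_group = by_group)
}

#' Quadrat test of complete spatial randomness
#'
#' Partitions the window into `nx * ny` equal-area quadrats and compares
#' the observed counts to the uniform expectation by Pearson's chi-square
#' on `nx * ny - 1` degrees of freedom. Large values indicate clustering
#' or inhomogeneity.
#'
#' @param pattern a [point_pattern()].
#' @param nx,ny quadrat grid dimensions (default 5 x 5, df = 24).
#' @return a list: `chi2`, `df`, `p`, `counts` (ny x nx matrix, row 1 at
#'   the top of the window), `expected`.
#' @examples
#' set.seed(1)
#' pp <- point_pattern(runif(500, -20, 20), runif(500, -11.25, 11.25))
#' quadrat_test(pp)$df # 24
#' @export
quadrat_test <- function(pattern, nx = 5, ny = 5) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (pattern$n < 1L) {
    stop("quadrat test needs at least one point", call. = FALSE)
  }
  w <- pattern$window
  ix <- pmin(nx, 1L + floor((pattern$x - w[1]) / (w[2] - w[1]) * nx))
  iy <- pmin(ny, 1L + floor((pattern$y - w[3]) / (w[4] - w[3]) * ny))
  counts <- table(factor(ny + 1 - iy, levels = seq_len(ny)),
                  factor(ix, levels = seq_len(nx)))
  counts <- matrix(as.integer(counts), nrow = ny, ncol = nx)
  e <- pattern$n / (nx * ny)
  if (e < 5) {
    warning("expected count per quadrat is below 5; the chi-square ",
            "approximation may be poor")
  }
  chi2 <- sum((counts - e)^2 / e)
  df <- nx * ny - 1
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       counts = counts, expected = e)
}

#' Pairwise distances of a set of points
#'
#' All n(n-1)/2 Euclidean distances with their median and quartiles. Used
#' on per-subject mean gaze positions to quantify between-subject
#' dispersion within a group.
#'
#' @param x,y point coordinates.
#' @return a list: `distances`, `median`, `q1`, `q3`, `n_points`.
#' @examples
#' pairwise_distance_summary(c(0, 3), c(0, 4))$median # 5
#' @export
pairwise_distance_summary <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) {
    stop("need at least 2 points for pairwise distances", call. = FALSE)
  }
  d <- as.numeric(stats::dist(cbind(x, y)))
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
  list(distances = d, median = q[2], q1 = q[1], q3 = q[3],
       n_points = length(x))
}

#' Variance ellipse of a 2-D point cloud
#'
#' Eigendecomposition of the sample covariance matrix. The area of the
#' 95%-coverage ellipse of a bivariate normal is
#' `pi * qchisq(0.95, 2) * sqrt(lambda_max * lambda_min)`.
#'
#' @param x,y point coordinates (n >= 3).
#' @param coverage coverage probability of the ellipse (default 0.95).
#' @return an object of class `variance_ellipse`: `center`, `lambda_max`,
#'   `lambda_min`, `orientation_deg` (major-axis angle from horizontal),
#'   `area`, `degenerate` flag, `n`.
#' @export
variance_ellipse <- function(x, y, coverage = 0.95) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) {
    stop("need at least 3 points for a variance ellipse", call. = FALSE)
  }
  S <- stats::cov(cbind(x, y))
  eg <- eigen(S, symmetric = TRUE)
  lmax <- eg$values[1]
  lmin <- max(eg$values[2], 0)
  degenerate <- lmin < 1e-12 * max(lmax, 1e-300)
  q <- stats::qchisq(coverage, df = 2)
  structure(
    list(center = c(mean(x), mean(y)), lambda_max = lmax, lambda_min = lmin,
         orientation_deg = atan2(eg$vectors[2, 1], eg$vectors[1, 1]) * 180 / pi,
         area = pi * q * sqrt(lmax * lmin), coverage = coverage,
         degenerate = degenerate, n = length(x)),
    class = "variance_ellipse")
}

#' @export
print.variance_ellipse <- function(x, ...) {
  cat(sprintf(
    "variance ellipse (%g%% coverage): area %.3g deg^2, var %.3g / %.3g, %s%d points\n",
    100 * x$coverage, x$area, x$lambda_max, x$lambda_min,
    if (x$degenerate) "DEGENERATE, " else "", x$n))
  invisible(x)
}

#' F test comparing two variances
#'
#' Two-sided F ratio test, e.g. for elongation (major vs minor ellipse
#' variance) or group comparisons of gaze variance.
#'
#' @param varA,varB sample variances (> 0).
#' @param nA,nB sample sizes (> 1).
#' @return a list: `F`, `df1`, `df2`, `p`.
#' @export
variance_f_test <- function(varA, nA, varB, nB) {
  if (varA <= 0 || varB <= 0) {
    stop("degenerate: variances must be positive", call. = FALSE)
  }
  stopifnot(nA > 1, nB > 1)
  F <- varA / varB
  df1 <- nA - 1
  df2 <- nB - 1
  p <- 2 * min(stats::pf(F, df1, df2), stats::pf(F, df1, df2,
                                                 lower.tail = FALSE))
  list(F = F, df1 = df1, df2 = df2, p = min(p, 1))
}

#' Per-subject gaze dispersion by noise level
#'
#' Total gaze SD per subject x noise level,
#' `sqrt(var(x) + var(y))`, with Bayesian-bootstrap group comparisons of
#' the subject-level values at each level. Cells with fewer than 2 points
#' are skipped and listed in the output.
#'
#' @param gaze gaze table (`subject_id`, `group`, `noise_level`, `x_deg`,
#'   `y_deg`).
#' @param groups two group labels to compare; defaults to the first two
#'   present.
#' @param n_draws,seed bootstrap settings.
#' @return a list: `cells` (subject x level SDs), `comparison` (per level:
#'   group medians and `p_greater` that the first group exceeds the
#'   second), `skipped` (cells with < 2 points).
#' @export
per_subject_dispersion <- function(gaze, groups = NULL, n_draws = 4000,
                                   seed = NULL) {
  check_columns(gaze, c("subject_id", "group", "noise_level", "x_deg",
                        "y_deg"), "gaze")
  if (!is.null(seed)) set.seed(seed)
  key <- interaction(gaze$subject_id, gaze$noise_level, drop = TRUE)
  rows <- list()
  skipped <- list()
  for (k in levels(key)) {
    sel <- key == k
    n <- sum(sel)
    rec <- data.frame(subject_id = gaze$subject_id[sel][1],
                      group = gaze$group[sel][1],
                      noise_level = gaze$noise_level[sel][1],
                      n_points = n)
    if (n < 2L) {
      skipped[[length(skipped) + 1L]] <- rec
      next
    }
    rec$sd_total <- sqrt(stats::var(gaze$x_deg[sel]) +
                           stats::var(gaze$y_deg[sel]))
    rows[[length(rows) + 1L]] <- rec
  }
  cells <- do.call(rbind, rows)
  if (is.null(groups)) groups <- unique(cells$group)[1:2]
  comp <- list()
  for (lv in sort(unique(cells$noise_level))) {
    vA <- cells$sd_total[cells$group == groups[1] &
                           cells$noise_level == lv]
    vB <- cells$sd_total[cells$group == groups[2] &
                           cells$noise_level == lv]
    if (length(vA) < 2L || length(vB) < 2L) next
    bc <- bayes_boot_compare(vA, vB, "median", n_draws = n_draws)
    comp[[length(comp) + 1L]] <- data.frame(
      noise_level = lv, groupA = groups[1], groupB = groups[2],
      medianA = bc$bootA$estimate, medianB = bc$bootB$estimate,
      p_greater = bc$p_greater)
  }
  list(cells = cells, comparison = do.call(rbind, comp),
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL)
}

#' Correlations between gaze area and performance measures
#'
#' Computes each subject's gaze area (95% variance-ellipse area over all
#' their clipped gaze points) and correlates it with mean accuracy,
#' median (filtered) RT, and IQ.
#'
#' @param gaze gaze table (`subject_id`, `x_deg`, `y_deg`), already
#'   clipped to the screen.
#' @param accuracy data frame `subject_id`, `prop_correct` (subject
#'   means).
#' @param rt data frame `subject_id`, `median_rt`.
#' @param iq data frame `subject_id`, `iq`. Optional (`NULL` to skip).
#' @return a list: `areas` (per-subject), and [pearson_ci()] results
#'   `accuracy`, `rt`, `iq`.
#' @export
gaze_area_correlations <- function(gaze, accuracy, rt = NULL, iq = NULL) {
  check_columns(gaze, c("subject_id", "x_deg", "y_deg"), "gaze")
  check_columns(accuracy, c("subject_id", "prop_correct"), "accuracy")
  sids <- unique(gaze$subject_id)
  areas <- data.frame(subject_id = sids, gaze_area = NA_real_)
  for (i in seq_along(sids)) {
    sel <- gaze$subject_id == sids[i]
    if (sum(sel) < 3L) next
    areas$gaze_area[i] <- variance_ellipse(gaze$x_deg[sel],
                                           gaze$y_deg[sel])$area
  }
  areas <- areas[is.finite(areas$gaze_area), ]
  out <- list(areas = areas)
  m <- merge(areas, accuracy, by = "subject_id")
  out$accuracy <- pearson_ci(m$gaze_area, m$prop_correct)
  if (!is.null(rt)) {
    check_columns(rt, c("subject_id", "median_rt"), "rt")
    m <- merge(areas, rt, by = "subject_id")
    out$rt <- pearson_ci(m$gaze_area, m$median_rt)
  }
  if (!is.null(iq)) {
    check_columns(iq, c("subject_id", "iq"), "iq")
    m <- merge(areas, iq, by = "subject_id")
    out$iq <- pearson_ci(m$gaze_area, m$iq)
  }
  out
}
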