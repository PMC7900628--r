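# Hexagonal element grid and contour path geometry.

#' Stimulus specification
#'
#' Bundles the geometric and photometric parameters of one contour-in-noise
#' display: a hexagonal grid of Gabor elements on a mean-luminance
#' background, a straight 12-element target contour tilted 60 degrees from
#' horizontal, and a set of orientation-jitter (external noise) levels.
#' Defaults describe a 1920 x 1080 display spanning 40 x 22.5 degrees of
#' visual angle (48 px/deg).
#'
#' @param n_cols,n_rows grid dimensions (columns x rows of elements).
#' @param spacing centre-to-centre element spacing, degrees of visual angle.
#' @param gabor_sf carrier spatial frequency, cycles/degree.
#' @param gabor_sigma Gaussian envelope SD, degrees.
#' @param gabor_diameter truncation diameter of each element, degrees
#'   (default 6 envelope SDs).
#' @param contrast peak Michelson contrast of the carrier, in `[0, 1]`.
#' @param contour_length number of contour elements; must be even so the
#'   +/- jitter assignment can be balanced.
#' @param contour_orientation contour tilt, degrees from horizontal; must be
#'   a lattice direction of the grid (0, 60 or 120).
#' @param noise_levels orientation-jitter magnitudes delta, degrees; each
#'   signal contour element is rotated by +delta or -delta.
#' @param double_pass_levels the two noise levels whose blocks are repeated
#'   in a second pass.
#' @param screen_deg screen width and height, degrees.
#' @param px_per_deg display resolution, pixels/degree.
#' @param duration_ms stimulus duration (metadata only; nothing is timed).
#' @return an object of class `stimulus_spec` (a validated list).
#' @seealso [build_hex_grid()], [generate_session_design()]
#' @examples
#' spec <- stimulus_spec()
#' spec$n_cols * spec$n_rows # 975 elements
#' @export
stimulus_spec <- function(n_cols = 39L, n_rows = 25L, spacing = 1.044,
                          gabor_sf = 5.75, gabor_sigma = 0.087,
                          gabor_diameter = 6 * gabor_sigma,
                          contrast = 0.75,
                          contour_length = 12L, contour_orientation = 60,
                          noise_levels = c(0, 10, 20, 30, 45, 60),
                          double_pass_levels = c(10, 45),
                          screen_deg = c(40, 22.5), px_per_deg = 48,
                          duration_ms = 200) {
  n_cols <- check_count(n_cols, "n_cols")
  n_rows <- check_count(n_rows, "n_rows")
  check_positive(spacing, "spacing")
  check_positive(gabor_sf, "gabor_sf")
  check_positive(gabor_sigma, "gabor_sigma")
  check_positive(gabor_diameter, "gabor_diameter")
  contour_length <- check_count(contour_length, "contour_length", min = 2L)
  if (contour_length %% 2L != 0L) {
    stop("`contour_length` must be even for balanced +/- jitter assignment",
         call. = FALSE)
  }
  if (!is.numeric(contrast) || contrast < 0 || contrast > 1) {
    stop("`contrast` must be a Michelson fraction in [0, 1]", call. = FALSE)
  }
  if (any(noise_levels < 0 | noise_levels >= 90)) {
    stop("all `noise_levels` must lie in [0, 90) degrees", call. = FALSE)
  }
  if (!all(double_pass_levels %in% noise_levels)) {
    stop("`double_pass_levels` must be a subset of `noise_levels`",
         call. = FALSE)
  }
  if (length(screen_deg) != 2L || any(screen_deg <= 0)) {
    stop("`screen_deg` must be c(width, height) in degrees", call. = FALSE)
  }
  check_positive(px_per_deg, "px_per_deg")
  structure(
    list(n_cols = n_cols, n_rows = n_rows, spacing = spacing,
         gabor_sf = gabor_sf, gabor_sigma = gabor_sigma,
         gabor_diameter = gabor_diameter, contrast = contrast,
         contour_length = contour_length,
         contour_orientation = contour_orientation,
         noise_levels = as.numeric(noise_levels),
         double_pass_levels = as.numeric(double_pass_levels),
         screen_deg = as.numeric(screen_deg), px_per_deg = px_per_deg,
         duration_ms = duration_ms),
    class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat("Contour-in-noise stimulus specification\n")
  cat(sprintf("  grid: %d x %d elements, spacing %.3f deg (hexagonal)\n",
              x$n_cols, x$n_rows, x$spacing))
  cat(sprintf("  Gabor: %.2f cpd, sigma %.3f deg, diameter %.3f deg, contrast %.2f\n",
              x$gabor_sf, x$gabor_sigma, x$gabor_diameter, x$contrast))
  cat(sprintf("  contour: %d elements at %g deg\n",
              x$contour_length, x$contour_orientation))
  cat(sprintf("  noise levels: %s deg (double pass at %s)\n",
              paste(x$noise_levels, collapse = ", "),
              paste(x$double_pass_levels, collapse = ", ")))
  cat(sprintf("  screen: %g x %g deg at %g px/deg\n",
              x$screen_deg[1], x$screen_deg[2], x$px_per_deg))
  invisible(x)
}

#' Build the hexagonal element grid
#'
#' Element positions sit at the intersections of a hexagonal lattice with
#' horizontal rows: row-to-row vertical pitch is `spacing * sqrt(3)/2` and
#' every second row is shifted by `spacing / 2`, so each interior element has
#' six equidistant neighbours. The bounding box of the grid is centred on
#' the screen centre (0, 0); x grows rightward, y upward, both in degrees.
#'
#' @param n_cols,n_rows grid dimensions.
#' @param spacing nearest-neighbour distance in degrees.
#' @return a data frame with one row per element: `index`, `col`, `row`,
#'   `x`, `y`.
#' @examples
#' g <- build_hex_grid(39, 25, 1.044)
#' nrow(g) # 975
#' @export
build_hex_grid <- function(n_cols, n_rows, spacing) {
  n_cols <- check_count(n_cols, "n_cols")
  n_rows <- check_count(n_rows, "n_rows")
  check_positive(spacing, "spacing")
  col <- rep(seq_len(n_cols), times = n_rows)
  row <- rep(seq_len(n_rows), each = n_cols)
  offset <- ifelse(row %% 2L == 0L, spacing / 2, 0)
  x <- (col - 1L) * spacing + offset
  y <- (row - 1L) * spacing * sqrt(3) / 2
  # centre the bounding box on (0, 0)
  x <- x - (min(x) + max(x)) / 2
  y <- y - (min(y) + max(y)) / 2
  data.frame(index = seq_along(x), col = col, row = row, x = x, y = y)
}

# unit step between consecutive lattice sites along a lattice direction,
# expressed as (delta col, delta row, x shift per row parity change)
lattice_step <- function(spacing, path_angle) {
  a <- path_angle %% 180
  if (isTRUE(all.equal(a, 0))) {
    list(dx = spacing, dy = 0)
  } else if (isTRUE(all.equal(a, 60))) {
    list(dx = spacing / 2, dy = spacing * sqrt(3) / 2)
  } else if (isTRUE(all.equal(a, 120))) {
    list(dx = -spacing / 2, dy = spacing * sqrt(3) / 2)
  } else {
    stop("`path_angle` must be a lattice direction (0, 60 or 120 degrees)",
         call. = FALSE)
  }
}

#' Select the target contour path on the grid
#'
#' Returns the indices of `length` consecutive collinear grid elements
#' along a lattice direction of the hexagonal grid, chosen so that the path
#' centroid is as close as possible to the screen centre. On the default
#' 39 x 25 grid no lattice window of even length is exactly centred (rows
#' sit at integer multiples of the 0.904-degree vertical pitch), so the
#' nearest representable path is used; its centroid is within half a
#' lattice pitch of (0, 0).
#'
#' @param grid a grid data frame from [build_hex_grid()].
#' @param length number of contour elements (even).
#' @param path_angle contour direction in degrees from horizontal; must be
#'   0, 60 or 120 (the lattice directions).
#' @param spacing element spacing used to build `grid`.
#' @return integer vector of `length` grid indices, ordered along the path.
#' @examples
#' g <- build_hex_grid(39, 25, 1.044)
#' idx <- select_contour_path(g, 12, 60, spacing = 1.044)
#' length(idx)
#' @export
select_contour_path <- function(grid, length, path_angle = 60,
                                spacing = 1.044) {
  check_columns(grid, c("index", "col", "row", "x", "y"), "grid")
  length <- check_count(length, "length", min = 2L)
  if (length %% 2L != 0L) {
    stop("contour `length` must be even", call. = FALSE)
  }
  step <- lattice_step(spacing, path_angle)
  tol <- 1e-6
  # successor of each site along the direction, by coordinate lookup
  key <- function(x, y) paste(round(x / tol), round(y / tol))
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(grid))) {
    assign(key(grid$x[i], grid$y[i]), grid$index[i], envir = lookup)
  }
  succ <- rep(NA_integer_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    k <- key(grid$x[i] + step$dx, grid$y[i] + step$dy)
    if (exists(k, envir = lookup, inherits = FALSE)) {
      succ[i] <- get(k, envir = lookup)
    }
  }
  # walk every maximal chain and score all windows of the requested length
  has_pred <- rep(FALSE, nrow(grid))
  has_pred[succ[!is.na(succ)]] <- TRUE
  best <- NULL
  best_d2 <- Inf
  for (start in grid$index[!has_pred]) {
    chain <- integer(0)
    i <- start
    while (!is.na(i)) {
      chain <- c(chain, i)
      i <- succ[i]
    }
    if (base::length(chain) < length) next
    for (w in seq_len(base::length(chain) - length + 1L)) {
      win <- chain[w:(w + length - 1L)]
      cx <- mean(grid$x[win]); cy <- mean(grid$y[win])
      d2 <- cx^2 + cy^2
      if (d2 < best_d2 - tol) {
        best <- win
        best_d2 <- d2
      }
    }
  }
  if (is.null(best)) {
    stop("no lattice path of length ", length,
         " along ", path_angle, " degrees fits inside the grid",
         call. = FALSE)
  }
  best
}

#' Neighbouring grid elements of a set of positions
#'
#' All grid elements at lattice distance one (within tolerance) of any of
#' the given elements, excluding the elements themselves. Used to build the
#' observer template: the background elements immediately adjacent to the
#' contour path.
#'
#' @param grid a grid data frame from [build_hex_grid()].
#' @param indices element indices whose neighbours are sought.
#' @param spacing lattice spacing of `grid`.
#' @return integer vector of neighbour indices (sorted, unique).
#' @export
grid_neighbors <- function(grid, indices, spacing = 1.044) {
  check_columns(grid, c("index", "x", "y"), "grid")
  px <- grid$x[match(indices, grid$index)]
  py <- grid$y[match(indices, grid$index)]
  near <- rep(FALSE, nrow(grid))
  for (i in seq_along(indices)) {
    d2 <- (grid$x - px[i])^2 + (grid$y - py[i])^2
    near <- near | (d2 < (1.05 * spacing)^2 & d2 > (0.5 * spacing)^2)
  }
  setdiff(grid$index[near], indices)
}
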