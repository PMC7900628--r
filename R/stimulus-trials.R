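# Orientation assignment, single trials, blocks, and the double-pass
# session design.

#' Assign element orientations for one trial
#'
#' Background elements (all non-contour positions; all positions on
#' noise-class trials) receive independent orientations uniform on
#' (-90, 90] degrees. On signal trials the contour elements take the
#' contour orientation plus balanced jitter: exactly half are rotated by
#' `+delta` and half by `-delta`, assigned by a random permutation, so the
#' arithmetic mean of the (unwrapped) contour orientations is exactly the
#' contour orientation and their population SD is exactly `delta` at every
#' level.
#'
#' @param n_elements total number of grid elements.
#' @param contour_indices indices of the contour path elements.
#' @param stimulus_class `"signal"` (contour present) or `"noise"`.
#' @param delta orientation-jitter magnitude in degrees (the external noise
#'   level).
#' @param contour_orientation contour tilt in degrees (default 60).
#' @return a list with `orientations` (length `n_elements`, wrapped to
#'   (-90, 90]) and `contour_unwrapped` (the contour values before
#'   wrapping; `NULL` for noise trials).
#' @examples
#' set.seed(1)
#' a <- assign_orientations(975, 1:12, "signal", delta = 45)
#' mean(a$contour_unwrapped) # exactly 60
#' @export
assign_orientations <- function(n_elements, contour_indices,
                                stimulus_class = c("signal", "noise"),
                                delta, contour_orientation = 60) {
  stimulus_class <- match.arg(stimulus_class)
  n_elements <- check_count(n_elements, "n_elements")
  if (!is.numeric(delta) || delta < 0 || delta >= 90) {
    stop("`delta` must be in [0, 90) degrees", call. = FALSE)
  }
  ori <- 90 - stats::runif(n_elements) * 180 # uniform on (-90, 90]
  contour_unwrapped <- NULL
  if (stimulus_class == "signal") {
    nc <- length(contour_indices)
    if (nc < 2L || nc %% 2L != 0L) {
      stop("balanced +/- assignment requires an even number of contour ",
           "elements", call. = FALSE)
    }
    signs <- sample(rep(c(1, -1), each = nc / 2L))
    contour_unwrapped <- contour_orientation + signs * delta
    ori[contour_indices] <- wrap_orientation(contour_unwrapped)
  }
  list(orientations = ori, contour_unwrapped = contour_unwrapped)
}

#' Construct a single trial stimulus
#'
#' Draws one full set of element orientations for a trial of the given
#' class and noise level, using the current RNG state.
#'
#' @param trial_id identifier carried through to the output.
#' @param stimulus_class `"signal"` or `"noise"`.
#' @param delta noise level in degrees.
#' @param n_elements total grid elements.
#' @param contour_indices contour path indices.
#' @param contour_orientation contour tilt, degrees.
#' @return an object of class `trial_stimulus`.
#' @export
make_trial_stimulus <- function(trial_id, stimulus_class, delta,
                                n_elements, contour_indices,
                                contour_orientation = 60) {
  a <- assign_orientations(n_elements, contour_indices, stimulus_class,
                           delta, contour_orientation)
  structure(
    list(trial_id = trial_id, stimulus_class = stimulus_class,
         noise_level = delta, orientations = a$orientations,
         contour_indices = contour_indices,
         contour_unwrapped = a$contour_unwrapped,
         contour_orientation = contour_orientation),
    class = "trial_stimulus")
}

#' @export
print.trial_stimulus <- function(x, ...) {
  cat(sprintf("trial_stimulus: %s trial, noise %g deg, %d elements\n",
              x$stimulus_class, x$noise_level, length(x$orientations)))
  invisible(x)
}

#' Generate one experimental block
#'
#' A block holds `n_signal + n_noise` trials at a single external-noise
#' level, in random order, each with a freshly drawn stimulus (new
#' background orientations and a new +/- jitter permutation).
#'
#' @param spec a [stimulus_spec()].
#' @param noise_level the block's jitter magnitude delta, degrees.
#' @param n_signal,n_noise trial counts per stimulus class (default 30/30).
#' @param seed optional integer seed making the block reproducible.
#' @param grid,contour_indices precomputed geometry; rebuilt from `spec`
#'   when omitted.
#' @return a list of class `trial_block`: `noise_level`, `trials` (list of
#'   `trial_stimulus`), `classes`, `seed`.
#' @examples
#' blk <- generate_block(stimulus_spec(), 10, seed = 1)
#' length(blk$trials) # 60
#' @export
generate_block <- function(spec, noise_level, n_signal = 30L, n_noise = 30L,
                           seed = NULL, grid = NULL, contour_indices = NULL) {
  stopifnot(inherits(spec, "stimulus_spec"))
  n_signal <- check_count(n_signal, "n_signal", min = 0L)
  n_noise <- check_count(n_noise, "n_noise", min = 0L)
  if (!noise_level %in% spec$noise_levels) {
    stop("`noise_level` ", noise_level, " is not one of the configured ",
         "levels", call. = FALSE)
  }
  if (is.null(grid)) grid <- build_hex_grid(spec$n_cols, spec$n_rows, spec$spacing)
  if (is.null(contour_indices)) {
    contour_indices <- select_contour_path(grid, spec$contour_length,
                                           spec$contour_orientation,
                                           spec$spacing)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- n_signal + n_noise
  classes <- sample(rep(c("signal", "noise"), c(n_signal, n_noise)))
  trials <- vector("list", n)
  for (i in seq_len(n)) {
    trials[[i]] <- make_trial_stimulus(
      trial_id = i, stimulus_class = classes[i], delta = noise_level,
      n_elements = spec$n_cols * spec$n_rows,
      contour_indices = contour_indices,
      contour_orientation = spec$contour_orientation)
  }
  structure(list(noise_level = noise_level, trials = trials,
                 classes = classes, seed = seed),
            class = "trial_block")
}

#' Generate the full double-pass session design
#'
#' A session comprises eight blocks: the six noise levels in random order
#' (pass 1), followed by exact stimulus-by-stimulus replicas of the blocks
#' at the two double-pass levels (pass 2, the two repeats in random order,
#' always last). Replica blocks share every per-trial orientation with
#' their pass-1 originals; only the observer's responses can differ.
#'
#' @param spec a [stimulus_spec()].
#' @param seed integer seed; the whole session is a deterministic function
#'   of `spec` and `seed`.
#' @return a list of class `session_design` with elements `blocks` (list;
#'   each block carries `pass` and `block` number) and `spec`.
#' @examples
#' s <- generate_session_design(stimulus_spec(), seed = 1)
#' length(s$blocks) # 8
#' @export
generate_session_design <- function(spec, seed) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (length(spec$double_pass_levels) < 1L ||
      !all(spec$double_pass_levels %in% spec$noise_levels)) {
    stop("double-pass levels missing from the configured noise levels",
         call. = FALSE)
  }
  grid <- build_hex_grid(spec$n_cols, spec$n_rows, spec$spacing)
  ci <- select_contour_path(grid, spec$contour_length,
                            spec$contour_orientation, spec$spacing)
  set.seed(seed)
  level_order <- sample(spec$noise_levels)
  repeat_order <- sample(spec$double_pass_levels)
  block_seeds <- sample.int(2^31 - 2, length(level_order))
  blocks <- vector("list", length(level_order) + length(repeat_order))
  for (b in seq_along(level_order)) {
    blk <- generate_block(spec, level_order[b], seed = block_seeds[b],
                          grid = grid, contour_indices = ci)
    blk$pass <- 1L
    blk$block <- b
    blocks[[b]] <- blk
  }
  for (j in seq_along(repeat_order)) {
    b1 <- which(level_order == repeat_order[j])
    blk <- blocks[[b1]] # identical stimuli, identical order
    blk$pass <- 2L
    blk$block <- length(level_order) + j
    blocks[[length(level_order) + j]] <- blk
  }
  structure(list(blocks = blocks, spec = spec, seed = seed),
            class = "session_design")
}

#' @export
print.session_design <- function(x, ...) {
  lv <- vapply(x$blocks, function(b) b$noise_level, numeric(1))
  ps <- vapply(x$blocks, function(b) b$pass, integer(1))
  cat("Double-pass session design:", length(x$blocks), "blocks\n")
  cat("  noise levels:", paste(lv, collapse = ", "), "\n")
  cat("  passes:      ", paste(ps, collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate the per-element orientations of a trial
#'
#' @param trial a `trial_stimulus`.
#' @param grid the grid the trial was generated on.
#' @return a data frame: `grid_index`, `col`, `row`, `x_deg`, `y_deg`,
#'   `orientation_deg`, `is_contour`.
#' @export
trial_orientation_table <- function(trial, grid) {
  stopifnot(inherits(trial, "trial_stimulus"))
  data.frame(grid_index = grid$index, col = grid$col, row = grid$row,
             x_deg = grid$x, y_deg = grid$y,
             orientation_deg = trial$orientations,
             is_contour = grid$index %in% trial$contour_indices &
               trial$stimulus_class == "signal")
}
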