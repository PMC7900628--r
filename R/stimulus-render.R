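# Pixel rendering of a trial stimulus.

#' Render a trial stimulus to a luminance image
#'
#' Each element is drawn as an odd-symmetric (sine-phase) Gabor: a sinusoid
#' whose stripes run along the element orientation, under a circular
#' Gaussian envelope of SD `gabor_sigma`, truncated at
#' `gabor_diameter / 2`. Sine phase makes every element integrate to zero,
#' so the image mean equals the mid-grey background regardless of element
#' count. Overlapping truncation windows are summed; the result is clipped
#' to `[0, 1]` and clipping events are reported via the `"n_clipped"`
#' attribute.
#'
#' @param spec a [stimulus_spec()].
#' @param trial a `trial_stimulus` from [generate_block()] or
#'   [make_trial_stimulus].
#' @param grid the grid the trial was generated on (rebuilt when omitted).
#' @return a numeric matrix (rows = screen height in px, columns = width)
#'   with values in `[0, 1]` and background 0.5; attribute `n_clipped`
#'   counts clipped pixels.
#' @examples
#' sp <- stimulus_spec(px_per_deg = 8) # coarse rendering for speed
#' blk <- generate_block(sp, 0, n_signal = 1, n_noise = 0, seed = 1)
#' img <- render_stimulus(sp, blk$trials[[1]])
#' @export
render_stimulus <- function(spec, trial, grid = NULL) {
  stopifnot(inherits(spec, "stimulus_spec"), inherits(trial, "trial_stimulus"))
  check_positive(spec$px_per_deg, "px_per_deg")
  if (is.null(grid)) grid <- build_hex_grid(spec$n_cols, spec$n_rows, spec$spacing)
  wpx <- round(spec$screen_deg[1] * spec$px_per_deg)
  hpx <- round(spec$screen_deg[2] * spec$px_per_deg)
  img <- matrix(0, nrow = hpx, ncol = wpx)
  # pixel-centre coordinates in degrees (x rightward, y upward)
  px_x <- ((seq_len(wpx)) - 0.5) / spec$px_per_deg - spec$screen_deg[1] / 2
  px_y <- spec$screen_deg[2] / 2 - ((seq_len(hpx)) - 0.5) / spec$px_per_deg
  radius <- spec$gabor_diameter / 2
  half_px <- ceiling(radius * spec$px_per_deg) + 1L
  amp <- spec$contrast / 2 # modulation about the 0.5 background
  for (i in seq_len(nrow(grid))) {
    cx <- grid$x[i]; cy <- grid$y[i]
    jc <- round((cx + spec$screen_deg[1] / 2) * spec$px_per_deg + 0.5)
    ic <- round((spec$screen_deg[2] / 2 - cy) * spec$px_per_deg + 0.5)
    jj <- max(1L, jc - half_px):min(wpx, jc + half_px)
    ii <- max(1L, ic - half_px):min(hpx, ic + half_px)
    if (!length(jj) || !length(ii)) next
    dx <- px_x[jj] - cx
    dy <- px_y[ii] - cy
    DX <- matrix(dx, nrow = length(ii), ncol = length(jj), byrow = TRUE)
    DY <- matrix(dy, nrow = length(ii), ncol = length(jj))
    r2 <- DX^2 + DY^2
    th <- trial$orientations[i] * pi / 180
    # carrier varies perpendicular to the stripe axis
    u <- -DX * sin(th) + DY * cos(th)
    g <- amp * sin(2 * pi * spec$gabor_sf * u) *
      exp(-r2 / (2 * spec$gabor_sigma^2))
    g[r2 > radius^2] <- 0
    img[ii, jj] <- img[ii, jj] + g
  }
  img <- img + 0.5
  n_clipped <- sum(img < 0 | img > 1)
  img[img < 0] <- 0
  img[img > 1] <- 1
  attr(img, "n_clipped") <- n_clipped
  img
}

#' Write a rendered stimulus to an 8-bit grayscale PNG
#'
#' @param img matrix from [render_stimulus()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_stimulus_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export", call. = FALSE)
  }
  png::writePNG(img, target = path)
  invisible(path)
}
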