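# Internal helpers shared across modules.

#' Wrap angles to the orientation range (-90, 90]
#'
#' Orientations of Gabor elements are axial quantities: an element at
#' \eqn{\theta} and one at \eqn{\theta + 180} are identical. All public
#' functions store orientations wrapped to the half-open interval
#' \eqn{(-90, 90]} degrees, measured counter-clockwise from the screen
#' horizontal.
#'
#' @param theta numeric vector of angles in degrees.
#' @return numeric vector of the same length, in (-90, 90].
#' @examples
#' wrap_orientation(c(120, -90, 105, 60))
#' @export
wrap_orientation <- function(theta) {
  stopifnot(is.numeric(theta))
  out <- ((theta + 90) %% 180) - 90
  out[out == -90] <- 90
  out
}

# argument checks -------------------------------------------------------

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("`", name, "` must be a single positive number", call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    stop("`", name, "` must be a single integer >= ", min, call. = FALSE)
  }
  invisible(as.integer(x))
}

check_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("`", what, "` is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Derive a reproducible child seed from a master seed
#'
#' A counter-based scheme: the master seed and a sequence of labels
#' (strings or integers) are folded into a 31-bit integer by a
#' multiplicative string hash. Any subject/block/trial stream can thus be
#' regenerated in isolation from the master seed and its address, without
#' consuming draws from a shared stream.
#'
#' @param master integer master seed.
#' @param ... labels (character or integer scalars) addressing the stream,
#'   e.g. `"stimuli", subject_id, block`.
#' @return an integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' derive_seed(1, "stimuli", "S01", 3)
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (lab in list(...)) {
    for (code in utf8ToInt(paste0("/", as.character(lab)))) {
      h <- (h * 131 + code) %% m
    }
  }
  as.integer(h)
}
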