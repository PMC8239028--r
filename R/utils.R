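#' Derive a reproducible substream seed from a master seed and a key
#'
#' All stochastic stages draw their RNG state from one master seed via named
#' substreams, so individual stages (cohort generation, each Louvain run,
#' neuron batches) can be re-run independently yet reproducibly.
#'
#' @param master integer master seed.
#' @param key character name of the substream (e.g. `"cohort"`,
#'   `"louvain-run-17"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(key))
  codes <- utf8ToInt(key)
  h <- (master %% 2147483647)
  for (c in codes) {
    # 31-based polynomial rolling hash, kept inside 31-bit range
    h <- (h * 31 + c) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Wraps [withr::with_seed()] so callers never clobber the global RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

#' Encode pixel coordinates as unique string keys
#'
#' Pixels are (x, y) integer coordinate pairs; set operations (intersection,
#' difference) are performed on these keys.
#'
#' @param pixels data.frame with integer columns `x`, `y`.
#' @return Character vector of keys.
#' @keywords internal
pixel_keys <- function(pixels) {
  if (is.null(pixels) || nrow(pixels) == 0L) return(character(0))
  paste(pixels$x, pixels$y, sep = ",")
}

#' Trapezoidal integral on an even grid
#' @param x grid values (ascending, evenly spaced).
#' @param y function values.
#' @return Numeric scalar.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same nodes, used
#' to score recovery of the generator's planted zone groups.
#'
#' @param a,b integer or character label vectors of equal length.
#' @return Numeric ARI in `[-1, 1]`.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}
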