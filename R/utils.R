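# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions never perturb user-level randomness.
#' A `NULL` seed evaluates `expr` with the ambient RNG.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic integer mixing (Knuth multiplicative hash) keeping the
#' result in [1, 2^31 - 2] so it is always a valid R seed.
#' @noRd
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483646) + 1L
}

#' Flatten an items x height x width image array to items x pixels
#'
#' Pixels are ordered row-major (row 1 left-to-right, then row 2, ...),
#' matching both the IDX payload order and the input-node ordering of the
#' layered adjacency matrix.
#' @noRd
flatten_images <- function(images) {
  stopifnot(length(dim(images)) == 3L)
  n <- dim(images)[1L]; h <- dim(images)[2L]; w <- dim(images)[3L]
  out <- matrix(0, n, h * w)
  for (r in seq_len(h)) {
    out[, ((r - 1L) * w + 1L):(r * w)] <- images[, r, ]
  }
  out
}

#' Reshape a row-major pixel vector back to an image grid
#' @noRd
pixel_grid <- function(v, image_shape) {
  matrix(v, nrow = image_shape[1L], ncol = image_shape[2L], byrow = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
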