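# Small numerical helpers shared across the package.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Softmax of a numeric vector
#'
#' Numerically stable softmax; used for the visit-level attention and the
#' two-class risk head.
#'
#' @param x numeric vector of scores.
#' @return numeric vector of the same length, non-negative, summing to 1.
#' @keywords internal
softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

relu <- function(x) pmax(x, 0)

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so package randomness never leaks into the global stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}
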