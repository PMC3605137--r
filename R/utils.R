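## Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Population (1/n) variance
#'
#' Variance with denominator n rather than n - 1, used throughout the
#' variance-decomposition code so that small hand-checkable tables reproduce
#' exactly.
#'
#' @param x Numeric vector.
#' @return Scalar variance.
#' @export
popVar <- function(x) {
  x <- as.numeric(x)
  mean((x - mean(x))^2)
}

## Evaluate `expr` under `seed` without disturbing the caller's RNG state.
## A NULL seed leaves the RNG stream alone.
withSeed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

## Derive a stage seed from a root seed, kept inside 32-bit integer range.
deriveSeed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 1000003 * offset) %% .Machine$integer.max)
}

assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  invisible(x)
}
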