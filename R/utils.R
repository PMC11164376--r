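#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data
#' @useDynLib tonerace, .registration = TRUE
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All user-facing stochastic functions funnel through this so that
# identical (arguments, seed) pairs give identical output.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`rng_seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stream of child seeds (< 2^31) from one master seed.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
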