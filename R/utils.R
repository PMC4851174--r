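#' Derive a reproducible substream seed
#'
#' Mixes a master seed with an arbitrary sequence of integer indices (replicate
#' number, locus number, ...) into a deterministic child seed. Any replicate or
#' locus can therefore be regenerated in isolation, and the first j loci of a
#' large draw are identical to a j-locus draw at the same master seed.
#'
#' Mixing is a multiplicative-congruential hash carried out in double-precision
#' integers modulo 2^31 - 1, so it stays exact (all intermediates < 2^53) and
#' the result always fits a 32-bit R integer.
#'
#' @param master integer master seed
#' @param ... integer indices identifying the substream
#' @return an integer seed in [1, 2^31 - 2]
#' @export
substream_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (v in c(...)) {
    h <- (h * 69069 + as.numeric(v) + 1) %% m
    h <- (h * 6364136223846793 %% m + 1442695040888963 %% m) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so substream draws never disturb the
#' caller's RNG state.
#'
#' @param seed integer seed, or NULL to use the current RNG state
#' @param expr expression to evaluate
#' @keywords internal
with_substream <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' n-th harmonic number
#'
#' @param n positive integer
#' @return sum of 1/k for k = 1..n
#' @export
harmonic_number <- function(n) {
  stopifnot(n >= 1)
  sum(1 / seq_len(n))
}
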