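#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never perturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
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
  })
  set.seed(seed)
  expr
}

#' Derive a child seed from a master seed, staying within 32-bit range
#' @noRd
derive_seed <- function(seed, index) {
  (as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Row-wise softmax with the usual max-shift for stability
#' @noRd
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

sample_skewness <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  if (n < 2L || s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}

sample_kurtosis <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  if (n < 2L || s == 0) return(0)
  mean((x - mean(x))^4) / s^4 - 3
}
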