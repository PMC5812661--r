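# run expr with a locally seeded RNG, restoring the caller's stream
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for integer percent figures, where
#' base R's `round()` rounds half to even.
#'
#' @param x numeric vector
#' @return rounded values
#' @export
roundHalfUp <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
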