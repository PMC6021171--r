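# Internal helpers.

# Deterministic seed splitting: derive independent 31-bit sub-seeds from a
# master seed and a stream label, so each stochastic stage of a pipeline
# gets its own reproducible RNG stream.
splitSeed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(label)))
    h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# simple integral of a Gaussian over histogram bins
gaussBinMass <- function(breaks, mean, sd) {
  diff(pnorm(breaks, mean, sd))
}
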