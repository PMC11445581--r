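# internal helpers

# Evaluate expr with R's RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. All R-level randomness in the generators flows through
# this single helper.
.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hasSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(expr)
}

.assertFinite <- function(x, what) {
  if (anyNA(x) || any(!is.finite(x)))
    stop(what, " must be finite")
  invisible(x)
}
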