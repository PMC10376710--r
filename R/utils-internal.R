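# Internal helpers shared across modules.

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      stop("seed must be a single finite number")
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed deterministically; kept well below .Machine$integer.max.
childSeed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 10007L * as.integer(index)) %% 2000000011L
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
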