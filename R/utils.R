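## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream. `seed = NULL` leaves the current stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a reproducible child seed from a base seed and a stream index,
## kept within the 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a finite number in [%g, %g]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

## The four fluorescence-detectable allelic expression classes, in the
## fixed order used throughout the package.
OBSERVED_CLASSES <- c("none", "monoY", "monoR", "bi")

EXPRESSING_CLASSES <- c("monoY", "monoR", "bi")

CLONE_CLASSES <- c("single_mono_allelic", "mixed_mono_allelic",
                   "bi_allelic_only", "non_expressing")

MODEL_KINDS <- c("cis_only", "sequential", "parallel")
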