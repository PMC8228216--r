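#' @keywords internal
"_PACKAGE"

## Deterministic child-seed derivation. A single root seed spawns per-unit
## substreams (one per male, one per data stream) so each unit's output is
## stable when the cohort grows or shrinks. Kept below 2^31 - 1.
child_seed <- function(seed, index, stream = 0L) {
  s <- (as.numeric(seed) %% 1e6) * 1009 + index * 7919 + stream * 104729
  as.integer(s %% 2147483647)
}

## with_seed: evaluate expr under a local RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (strict_min && x <= min) stopf("'%s' must be > %g", name, min)
  if (!strict_min && x < min) stopf("'%s' must be >= %g", name, min)
  invisible(x)
}
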