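#' @import methods
#' @importFrom stats rnorm runif quantile median sd var predict
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Used everywhere randomness must be reproducible without clobbering the
# session RNG.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-item seed from a master seed and an index; keeps results
# reproducible under any generation order. Kept below .Machine$integer.max.
deriveSeed <- function(master, index) {
  as.integer((as.double(master) * 1000003 + as.double(index) * 7919) %%
               2147483587)
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper)
    stop(sprintf("'%s' = %g is out of range", name, x), call. = FALSE)
  invisible(x)
}

# xlogx with the 0 log 0 = 0 convention; log base 2 throughout the package.
xlog2x <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log2(p[pos])
  out
}
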