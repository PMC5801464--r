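#' @importFrom stats sd median quantile rnorm rpois runif coef residuals t.test setNames
#' @importFrom utils read.delim write.table head
NULL

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route through this so that a
# user-visible seed argument never clobbers the global stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a per-stage seed from a global one; kept below 2^31.
deriveSeed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  offset <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 1009 + offset) %% .Machine$integer.max)
}

assertScalarNumeric <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    stop(sprintf("'%s' must be %s %s", name, if (strict) ">" else ">=", lower),
         call. = FALSE)
  }
  invisible(x)
}
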