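# Internal helpers shared across modules.

# Run code under a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Derive n child seeds (< 2^31) from a master seed, for independent stages.
.deriveSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.assertScalarCount <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != round(x))
    stop(sprintf("'%s' must be a single positive integer", name), call. = FALSE)
  as.integer(x)
}

# Instrumentation: running count of pairwise correlation computations.
.counters <- new.env(parent = emptyenv())
.counters$correlations <- 0

#' Reset the pairwise-correlation computation counter
#'
#' The correlation engine counts every pairwise correlation it computes.
#' The counter backs the complexity contract of F-ACF (a fixed number of
#' correlations per predicted sample, independent of the training-set
#' size) and the linear scaling of brute KNN.
#'
#' @return invisibly, the counter value before the reset.
#' @seealso [correlationCount()]
#' @export
resetCorrelationCount <- function() {
  old <- .counters$correlations
  .counters$correlations <- 0
  invisible(old)
}

#' Read the pairwise-correlation computation counter
#'
#' @return number of pairwise correlations computed since the last
#'   [resetCorrelationCount()].
#' @export
correlationCount <- function() .counters$correlations

.countCorrelations <- function(n) {
  .counters$correlations <- .counters$correlations + n
  invisible(NULL)
}
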