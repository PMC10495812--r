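# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Set the RNG state for a reproducible computation
#'
#' All stochastic functions in the package accept a `seed` argument and call
#' this helper: a non-NULL seed makes the call deterministic, NULL leaves the
#' global RNG stream untouched.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  expr
}

# permutation p-value with the +1 correction so p is never exactly 0
perm_pvalue <- function(perm_stats, observed) {
  n <- length(perm_stats)
  (sum(perm_stats >= observed - 1e-12) + 1) / (n + 1)
}

stop_input <- function(..., call. = FALSE) stop(..., call. = call.)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}
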