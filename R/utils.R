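#' @importFrom stats median rnorm runif rlnorm spline var predict
#' @importFrom utils read.csv write.csv
NULL

#' Derive a stream-specific seed from a master seed
#'
#' All randomness in the package flows from a single integer seed; each module
#' draws from its own deterministic sub-stream so that, e.g., adding trials
#' does not perturb classifier fold assignment.
#'
#' @param seed master integer seed.
#' @param stream small non-negative integer identifying the consumer.
#' @return an integer seed below 2^31.
#' @keywords internal
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 16807) %% 2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_numeric_series <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x)) stopf("`%s` must be a numeric series", name)
  invisible(x)
}

assert_equal_length <- function(a, b, what = "series") {
  if (length(a) != length(b)) {
    stopf("%s must have equal length (%d vs %d)", what, length(a), length(b))
  }
  invisible(NULL)
}

# population (divisor-n) standard deviation; the windowed STD feature and the
# CBSI scale factor both use this convention
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
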