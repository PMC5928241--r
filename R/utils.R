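# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# evaluate `code` under a temporary RNG state; never disturbs the caller's
# stream, so identical (config, seed) pairs are bit-reproducible
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == floor(x)
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

stop_bad_arg <- function(name, msg) {
  stop(sprintf("invalid `%s`: %s", name, msg), call. = FALSE)
}

# beta draw parameterized by mean and concentration; an infinite
# concentration degenerates to the mean exactly
rbeta_mc <- function(n, mean, concentration) {
  out <- numeric(n)
  inf <- is.infinite(concentration)
  out[inf] <- mean[inf]
  if (any(!inf))
    out[!inf] <- stats::rbeta(sum(!inf),
                              mean[!inf] * concentration[!inf],
                              (1 - mean[!inf]) * concentration[!inf])
  out
}

check_fraction <- function(x, name) {
  if (!is_number(x) || x < 0 || x > 1)
    stop_bad_arg(name, "must be a single number in [0, 1]")
  x
}
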