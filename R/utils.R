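#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows row_number n across all_of
NULL

# Finite stand-in for log(0) so prefix sums stay NaN-free; any accumulated
# log-probability below .LOG_FLOOR is treated as exactly zero mass.
.LOG_ZERO <- -1e9
.LOG_FLOOR <- -1e8

log_safe <- function(p) {
  out <- rep(.LOG_ZERO, length(p))
  pos <- p > 0
  out[pos] <- log(p[pos])
  out
}

logsumexp <- function(x) {
  x <- x[x > .LOG_FLOOR]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Derive a stream of 31-bit sub-seeds from one master seed without touching
# the caller's RNG state.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max, n))
}

`%||%` <- rlang::`%||%`
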