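#' @importFrom rlang %||% hash
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rbinom rbeta rgamma runif setNames
NULL

# Round half away from zero (presentation only; internals stay unrounded).
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Present-value factor for amounts accrued mid-cycle: cycle t (1-based)
# is discounted by (1 + rate)^(t - 0.5).
discount_factors <- function(n, rate) {
  stopifnot(rate >= 0)
  (1 + rate)^-(seq_len(n) - 0.5)
}
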