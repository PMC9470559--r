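#' Round half away from zero
#'
#' Decimal rounding with halves rounded up in magnitude (so 0.5 -> 1,
#' 41.15 -> 41.2), matching the convention used in clinical trial reports;
#' base `round()` rounds halves to even. Used for display only — internal
#' computations keep full precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single percentage formatted to 1 dp half-up, as a plain number
pct1 <- function(num, den) {
  if (den == 0) return(NA_real_)
  round_half_up(100 * num / den, 1)
}
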