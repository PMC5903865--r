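#' @keywords internal
"_PACKAGE"

#' Percentage of classified units, printed-precision rounding
#'
#' Convenience for reporting classification fractions (e.g. excited units out
#' of all recorded units) as percentages rounded half-up to a fixed number of
#' decimals, matching how such fractions are conventionally printed.
#'
#' @param n Numerator count.
#' @param total Denominator count (> 0).
#' @param digits Decimal places (default 1).
#' @return Percentage as a number.
#' @export
fraction_pct <- function(n, total, digits = 1) {
  stopifnot(total > 0, n >= 0, n <= total)
  p <- 100 * n / total
  # round half up at the target precision
  floor(p * 10^digits + 0.5) / 10^digits
}
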