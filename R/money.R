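# Money is carried through the engine as integer euro-cents so that payer
# splits are exact and conservation (ss + remaining = total) holds to the
# cent without floating drift.

#' Convert euros to integer cents
#'
#' @param x numeric vector of euro amounts.
#' @return integer vector of cents.
#' @keywords internal
#' @noRd
as_cents <- function(x) {
  as.integer(round(x * 100))
}

#' Convert integer cents back to euros
#' @noRd
cents_to_eur <- function(cents) {
  cents / 100
}

# Deterministic commercial rounding (half away from zero) for fractional-cent
# intermediate values such as tier * total. base round() is half-to-even,
# which would make the engine's cent attribution depend on parity.
#' @noRd
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Reimbursement share of an integer-cent amount, computed exactly: the rate
# is carried as integer basis points (0.35 -> 3500) so rate x cents is an
# exact integer and the half-up rounding point is unambiguous. Avoids the
# half-cent instabilities of binary-float products like 0.35 * 1030.
#' @noRd
mul_rate_cents <- function(rate, cents) {
  bp <- round(rate * 1e4)
  as.integer((bp * as.numeric(cents) + 5e3) %/% 1e4)
}

#' Format a euro amount at two decimals
#' @noRd
format_eur <- function(x) {
  sprintf("%.2f", x)
}
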