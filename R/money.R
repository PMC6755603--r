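#' Money helpers: integer-cent arithmetic and locale-aware formatting
#'
#' Cost breakdowns are held internally as integer cent values (stored in
#' doubles, exact far beyond any total arising here) so that category sums
#' and sample totals are exact; conversion to euros and rounding happen only
#' at presentation. Rounding is commercial half-up, not the banker's rounding
#' of [round()].
#'
#' @param eur,cents numeric vectors of euro / cent amounts.
#' @param x numeric euro amount(s) to format or round.
#' @param digits number of decimal places for [round_half_up()].
#' @param locale `"default"` for `1,234,567.89` or `"german"` for
#'   `1.234.567,89` (the convention of German reimbursement tables).
#' @param symbol append a euro sign (`" €"`) when formatting.
#' @return `as_cents()` integer cent values; `as_eur()` euros;
#'   `format_eur()` character; `parse_eur()` numeric euros.
#' @examples
#' as_cents(13.37)
#' format_eur(260704250.62, locale = "german")
#' parse_eur("260.704.250,62 €", locale = "german")
#' @name money
NULL

#' @rdname money
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @rdname money
#' @export
as_cents <- function(eur) {
  sign(eur) * floor(abs(eur) * 100 + 0.5)
}

#' @rdname money
#' @export
as_eur <- function(cents) cents / 100

#' @rdname money
#' @export
format_eur <- function(x, locale = c("default", "german"), symbol = FALSE) {
  locale <- match.arg(locale)
  big <- if (locale == "german") "." else ","
  dec <- if (locale == "german") "," else "."
  out <- formatC(round_half_up(x, 2), format = "f", digits = 2,
                 big.mark = big, decimal.mark = dec)
  out <- trimws(out)
  if (symbol) out <- paste0(out, " €")
  out
}

#' @rdname money
#' @export
parse_eur <- function(x, locale = c("default", "german")) {
  locale <- match.arg(locale)
  x <- gsub("€", "", x, fixed = TRUE)
  x <- gsub("\\s", "", x)
  if (locale == "german") {
    x <- gsub(".", "", x, fixed = TRUE)
    x <- gsub(",", ".", x, fixed = TRUE)
  } else {
    x <- gsub(",", "", x, fixed = TRUE)
  }
  as.numeric(x)
}
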