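#' Month and rounding helpers
#'
#' Calendar months are represented throughout the package as `Date` values
#' pinned to the first day of the month. `ym()` builds such a month,
#' `month_seq()` enumerates a contiguous range, and `month_position()`
#' returns the month-of-year position in `[0, 12)` used by the cyclic
#' seasonal basis.
#'
#' @param year,month Integer year and month (1--12).
#' @return `ym()` a `Date`; `month_seq()` a `Date` vector; `month_position()`
#'   a numeric vector in `[0, 12)`.
#' @examples
#' ym(2020, 3)
#' month_seq(ym(2018, 11), ym(2019, 2))
#' @export
ym <- function(year, month) {
  stopifnot(all(month >= 1 & month <= 12))
  as.Date(sprintf("%04d-%02d-01", year, month))
}

#' @rdname ym
#' @param from,to First and last month (`Date`, first of month).
#' @export
month_seq <- function(from, to) {
  from <- first_of_month(from)
  to <- first_of_month(to)
  if (to < from) stop("`to` precedes `from` in month_seq()", call. = FALSE)
  seq(from, to, by = "1 month")
}

#' @rdname ym
#' @param x A `Date` vector.
#' @export
month_position <- function(x) {
  as.numeric(format(as.Date(x), "%m")) - 1
}

first_of_month <- function(x) {
  x <- as.Date(x)
  as.Date(format(x, "%Y-%m-01"))
}

# signed whole-month difference b - a, both first-of-month Dates
months_between <- function(a, b) {
  a <- as.Date(a); b <- as.Date(b)
  ya <- as.integer(format(a, "%Y")); ma <- as.integer(format(a, "%m"))
  yb <- as.integer(format(b, "%Y")); mb <- as.integer(format(b, "%m"))
  12L * (yb - ya) + (mb - ma)
}

days_in_month <- function(x) {
  x <- first_of_month(x)
  as.integer(seq(x[1], by = "1 month", length.out = 2)[2] - x[1]) # scalar use only
}

days_in_month_vec <- function(x) {
  x <- first_of_month(x)
  nxt <- first_of_month(as.Date(x) + 31)
  as.integer(nxt - x)
}

#' Round half away from zero
#'
#' Plain decimal rounding with ties going away from zero (the convention used
#' for reported one-decimal rates and deviations), as opposed to base R's
#' round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector.
#' @examples
#' round_half_away(-7.15, 1) # -7.2
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Disclosure-control rounding to multiples of 5
#'
#' Rounds counts to the nearest multiple of 5 (ties away from zero), the
#' statistical disclosure control convention for small-count suppression in
#' published health-service outputs. Intended only for reported counts, never
#' for values entering a model.
#'
#' @param counts Numeric vector of counts.
#' @return Numeric vector of counts rounded to multiples of 5.
#' @examples
#' disclosure_round(c(7, 8, 49303412))
#' @export
disclosure_round <- function(counts) {
  5 * round_half_away(counts / 5)
}

z95 <- qnorm(0.975)
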