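#' Calendar-month date arithmetic
#'
#' Risk horizons and exclusion windows are defined in calendar months, not in
#' fixed 30-day blocks: a "t-month" window ends on the same day-of-month t
#' months later, with the day clamped to the length of the target month
#' (e.g. Jan 31 + 1 month = Feb 28/29). Clamping avoids the multi-day drift a
#' 30-day month would accumulate over a 60-month horizon.
#'
#' @param date a `Date` vector.
#' @param n integer number of months to add (may be negative); scalar or a
#'   vector recycled against `date`.
#' @return a `Date` vector.
#' @examples
#' add_months(as.Date("2001-01-31"), 1) # 2001-02-28
#' add_months(as.Date("2000-03-15"), -24) # 1998-03-15
#' @export
add_months <- function(date, n) {
  stopifnot(inherits(date, "Date"))
  n <- as.integer(n)
  lt <- as.POSIXlt(date)
  y <- lt$year + 1900L
  m0 <- lt$mon + n # 0-based month, possibly out of [0, 11]
  y2 <- y + m0 %/% 12L
  m2 <- m0 %% 12L
  d2 <- pmin(lt$mday, days_in_month(y2, m2 + 1L))
  as.Date(sprintf("%04d-%02d-%02d", y2, m2 + 1L, d2))
}

days_in_month <- function(year, month) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- base[month]
  leap <- (year %% 4L == 0L & year %% 100L != 0L) | year %% 400L == 0L
  d[month == 2L & leap] <- 29L
  d
}

#' Elapsed time between dates in average months
#'
#' Continuous months (mean Gregorian month of 30.4375 days), used for
#' time-to-cancer binning and reporting. Horizon labels themselves use exact
#' calendar arithmetic via [add_months()].
#'
#' @param from,to `Date` vectors.
#' @return numeric vector of (possibly fractional) months.
#' @export
months_between <- function(from, to) {
  as.numeric(difftime(to, from, units = "days")) / 30.4375
}

years_between <- function(from, to) {
  as.numeric(difftime(to, from, units = "days")) / 365.25
}
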