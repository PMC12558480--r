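#' Partial calendar dates
#'
#' FAERS date fields are digit strings of varying completeness: `yyyymmdd`,
#' `yyyymm`, or `yyyy`. Rather than coercing incomplete values to a fictitious
#' day (or dropping them), the package keeps dates as canonical digit strings
#' and tags each with an explicit precision; downstream operations declare the
#' precision they need. Roughly half of real time-to-onset data is
#' unreconstructable from full-precision dates, so partial dates are the norm,
#' not an edge case.
#'
#' `pd_parse()` normalizes raw field text to a canonical partial date (or `NA`
#' if empty/implausible). `pd_precision()` returns `"day"`, `"month"`, or
#' `"year"`. `pd_year()` extracts the year as an integer. `pd_as_date()`
#' converts day-precision values to [Date] (`NA` otherwise). `pd_days_between()`
#' gives whole days from `from` to `to`, defined only when both carry day
#' precision.
#'
#' @param x,from,to Character vectors of raw or canonical partial dates.
#' @return `pd_parse()` a character vector of canonical partial dates;
#'   `pd_precision()` a character vector; `pd_year()` an integer vector;
#'   `pd_as_date()` a `Date`; `pd_days_between()` a numeric vector of days.
#' @examples
#' pd_parse(c("20200105", "202001", "2020", "", "2020-01-05"))
#' pd_precision(c("20200105", "202001", "2020"))
#' pd_days_between("20200101", "20200105")
#' @name partial_dates
NULL

#' @rdname partial_dates
#' @export
pd_parse <- function(x) {
  x <- stringr::str_remove_all(as.character(x), "[^0-9]")
  x[is.na(x) | x == ""] <- NA_character_
  n <- nchar(x)
  # anything other than 4/6/8 digits is unusable; a 6/8-digit value with an
  # impossible month or day degrades to the precision that is still valid
  x[!is.na(n) & !n %in% c(4L, 6L, 8L)] <- NA_character_
  yr <- suppressWarnings(as.integer(substr(x, 1L, 4L)))
  x[!is.na(yr) & (yr < 1900L | yr > 2199L)] <- NA_character_
  n <- nchar(x)
  mo <- suppressWarnings(as.integer(substr(x, 5L, 6L)))
  bad_mo <- !is.na(n) & n >= 6L & (is.na(mo) | mo < 1L | mo > 12L)
  x[bad_mo] <- substr(x[bad_mo], 1L, 4L)
  n <- nchar(x)
  dy <- suppressWarnings(as.integer(substr(x, 7L, 8L)))
  bad_dy <- !is.na(n) & n == 8L & (is.na(dy) | dy < 1L | dy > 31L)
  x[bad_dy] <- substr(x[bad_dy], 1L, 6L)
  x
}

#' @rdname partial_dates
#' @export
pd_precision <- function(x) {
  dplyr::case_when(
    is.na(x) ~ NA_character_,
    nchar(x) == 8L ~ "day",
    nchar(x) == 6L ~ "month",
    nchar(x) == 4L ~ "year",
    TRUE ~ NA_character_
  )
}

#' @rdname partial_dates
#' @export
pd_year <- function(x) {
  out <- suppressWarnings(as.integer(substr(x, 1L, 4L)))
  out[is.na(x)] <- NA_integer_
  out
}

#' @rdname partial_dates
#' @export
pd_as_date <- function(x) {
  out <- rep(as.Date(NA), length(x))
  day <- !is.na(x) & nchar(x) == 8L
  out[day] <- as.Date(x[day], format = "%Y%m%d")
  out
}

#' @rdname partial_dates
#' @export
pd_days_between <- function(from, to) {
  as.numeric(pd_as_date(to) - pd_as_date(from))
}

# Sort key comparable across precisions: partial dates padded with "00",
# missing sorts before everything (used by dedup, where a version without a
# receipt date loses to any dated version).
pd_sort_key <- function(x) {
  key <- stringr::str_pad(ifelse(is.na(x), "", x), 8L, "right", "0")
  key[is.na(x)] <- "00000000"
  key
}

format_ymd <- function(date) format(date, "%Y%m%d")
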