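#' Normalise a calendar date that may be partial
#'
#' Spontaneous-report databases carry dates at mixed precision: a report may
#' give a full day (\code{"20200401"}), only a month (\code{"202004"}) or only
#' a year (\code{"2020"}). Dates are kept at their reported precision as
#' digit strings of 4, 6 or 8 characters; nothing is imputed. Separators
#' (\code{-}, \code{/}, \code{.}) are stripped. Strings that do not resolve to
#' a plausible year/month/day prefix become \code{NA}.
#'
#' @param x character (or numeric) vector of raw date values.
#' @return character vector of normalised partial dates (\code{"YYYY"},
#'   \code{"YYYYMM"} or \code{"YYYYMMDD"}), \code{NA} where unparseable.
#' @examples
#' normalize_partial_date(c("2020-04-01", "202004", "2020", "n/a"))
#' @export
normalize_partial_date <- function(x) {
  x <- as.character(x)
  x[!is.na(x)] <- gsub("[-/. ]", "", trimws(x[!is.na(x)]))
  x[!is.na(x) & !grepl("^[0-9]{4,8}$", x)] <- NA_character_
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  xok <- x[ok]
  n <- nchar(xok)
  yr <- substr(xok, 1L, 4L)
  mo <- ifelse(n >= 6L, substr(xok, 5L, 6L), "")
  dy <- ifelse(n >= 8L, substr(xok, 7L, 8L), "")
  good_yr <- yr >= "1900" & yr <= "2199"
  good_mo <- mo == "" | (mo >= "01" & mo <= "12")
  good_dy <- dy == "" | (dy >= "01" & dy <= "31")
  res <- ifelse(!good_yr, NA_character_,
         ifelse(!good_mo, yr,
         ifelse(!good_dy, paste0(yr, mo), substr(xok, 1L, 8L))))
  # odd lengths (5 or 7 digits) truncate to the last full component
  res[!is.na(res) & n == 5L] <- yr[!is.na(res) & n == 5L]
  res[!is.na(res) & n == 7L] <- paste0(yr, mo)[!is.na(res) & n == 7L]
  out[ok] <- res
  out
}

#' Test whether a partial date is complete to the day
#'
#' @param x character vector of normalised partial dates.
#' @return logical vector: \code{TRUE} where the date has year, month and day
#'   and forms a valid calendar date.
#' @export
is_complete_date <- function(x) {
  ok <- !is.na(x) & nchar(x) == 8L
  ok[ok] <- !is.na(as.Date(x[ok], format = "%Y%m%d"))
  ok
}

#' Convert complete partial dates to Date
#'
#' Partial (year- or month-precision) values become \code{NA}: no imputation.
#'
#' @param x character vector of normalised partial dates.
#' @return \code{Date} vector.
#' @export
partial_as_date <- function(x) {
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- is_complete_date(x)
  out[ok] <- as.Date(x[ok], format = "%Y%m%d")
  out
}

# format a Date vector back to YYYYMMDD strings
format_ymd <- function(d) format(d, "%Y%m%d")
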