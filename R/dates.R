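## FAERS date fields are variable-resolution numerics: YYYY, YYYYMM or
## YYYYMMDD. Anything else is treated as absent.

#' Parse FAERS-style partial dates
#'
#' Accepts 4-digit (year), 6-digit (year+month) and 8-digit (full day)
#' numeric strings and returns one row per input with the components and
#' the achieved resolution. Malformed values (wrong length, impossible
#' month/day) yield an all-NA row rather than an error.
#'
#' @param x character or numeric vector of date strings.
#' @return data.frame with columns `year`, `month`, `day` (integer or NA)
#'   and `resolution` (one of "YEAR", "MONTH", "DAY", or NA when absent or
#'   unparseable).
#' @examples
#' parse_faers_date(c("2021", "202103", "20210308", "bad"))
#' @export
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x) | x == "" | !grepl("^[0-9]+$", x)] <- NA_character_
  nc <- nchar(x)
  year <- month <- day <- rep(NA_integer_, length(x))
  res <- rep(NA_character_, length(x))

  ok4 <- !is.na(x) & nc == 4L
  year[ok4] <- as.integer(x[ok4])
  res[ok4] <- "YEAR"

  ok6 <- !is.na(x) & nc == 6L
  year[ok6] <- as.integer(substr(x[ok6], 1, 4))
  month[ok6] <- as.integer(substr(x[ok6], 5, 6))
  res[ok6] <- "MONTH"

  ok8 <- !is.na(x) & nc == 8L
  year[ok8] <- as.integer(substr(x[ok8], 1, 4))
  month[ok8] <- as.integer(substr(x[ok8], 5, 6))
  day[ok8] <- as.integer(substr(x[ok8], 7, 8))
  res[ok8] <- "DAY"

  bad_month <- !is.na(month) & (month < 1L | month > 12L)
  bad_day <- !is.na(day) & (day < 1L | day > 31L)
  bad <- bad_month | bad_day
  year[bad] <- NA_integer_; month[bad] <- NA_integer_; day[bad] <- NA_integer_
  res[bad] <- NA_character_
  ## day present only if month present, by construction of the three branches
  data.frame(year = year, month = month, day = day, resolution = res,
             stringsAsFactors = FALSE)
}

#' Format partial dates back to FAERS numeric strings
#'
#' Inverse of [parse_faers_date()]: a "YEAR" row becomes 4 digits, "MONTH"
#' 6 digits, "DAY" 8 digits; NA rows become NA. Round-trips exactly.
#'
#' @param pd data.frame as returned by [parse_faers_date()].
#' @return character vector.
#' @export
format_faers_date <- function(pd) {
  out <- rep(NA_character_, nrow(pd))
  i <- which(pd$resolution == "YEAR")
  out[i] <- sprintf("%04d", pd$year[i])
  i <- which(pd$resolution == "MONTH")
  out[i] <- sprintf("%04d%02d", pd$year[i], pd$month[i])
  i <- which(pd$resolution == "DAY")
  out[i] <- sprintf("%04d%02d%02d", pd$year[i], pd$month[i], pd$day[i])
  out
}

## Ordering key used inside deduplication only: absent month/day pad with 01,
## absent date sorts first.
date_sort_key <- function(x) {
  pd <- parse_faers_date(x)
  m <- pd$month; m[is.na(m)] <- 1L
  d <- pd$day; d[is.na(d)] <- 1L
  key <- pd$year * 10000L + m * 100L + d
  key[is.na(pd$resolution) | is.na(key)] <- -1L
  key
}

## Date objects for day-resolution values, NA otherwise (no imputation).
faers_date_as_date <- function(x) {
  pd <- parse_faers_date(x)
  out <- rep(as.Date(NA), nrow(pd))
  i <- which(pd$resolution == "DAY")
  if (length(i)) {
    d <- as.Date(sprintf("%04d-%02d-%02d", pd$year[i], pd$month[i], pd$day[i]),
                 format = "%Y-%m-%d")
    out[i] <- d # impossible combos (Feb 30) come back NA from as.Date
  }
  out
}
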