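## Date and quarter helpers for FAERS-style 8-digit date strings.

#' Test whether a date string is a complete, valid YYYYMMDD date
#'
#' FAERS date fields may be complete (`YYYYMMDD`), partial (`YYYYMM`, `YYYY`)
#' or empty. Only complete, calendar-valid dates qualify for day-resolution
#' arithmetic such as time-to-onset.
#'
#' @param x character vector of date strings (NA allowed).
#' @return logical vector.
#' @export
is_complete_date <- function(x) {
  ok <- !is.na(x) & grepl("^[0-9]{8}$", x)
  ok[ok] <- !is.na(as.Date(x[ok], format = "%Y%m%d"))
  ok
}

#' Convert YYYYMMDD strings to Date
#'
#' Partial or malformed dates become `NA`.
#'
#' @param x character vector.
#' @return `Date` vector.
#' @export
parse_faers_date <- function(x) {
  out <- rep(as.Date(NA), length(x))
  ok <- is_complete_date(x)
  out[ok] <- as.Date(x[ok], format = "%Y%m%d")
  out
}

#' Calendar quarter of an 8-digit date string
#'
#' @param x character vector of YYYYMMDD (or at least YYYYMM) strings.
#' @return character vector like `"2021Q3"`; `NA` where the year/month cannot
#'   be read.
#' @export
quarter_of <- function(x) {
  ok <- !is.na(x) & grepl("^[0-9]{6}", x)
  out <- rep(NA_character_, length(x))
  yr <- substr(x[ok], 1, 4)
  mo <- as.integer(substr(x[ok], 5, 6))
  valid <- !is.na(mo) & mo >= 1 & mo <= 12
  res <- rep(NA_character_, sum(ok))
  res[valid] <- paste0(yr[valid], "Q", (mo[valid] - 1L) %/% 3L + 1L)
  out[ok] <- res
  out
}

## quarter index on a single integer scale (1 unit per quarter)
quarter_index <- function(q) {
  stopifnot(all(grepl("^[0-9]{4}Q[1-4]$", q)))
  4L * as.integer(substr(q, 1, 4)) + as.integer(substr(q, 6, 6))
}

#' Enumerate quarters in a window
#'
#' @param from,to quarter strings like `"2020Q3"`, inclusive.
#' @return character vector of quarters.
#' @export
quarter_seq <- function(from, to) {
  i <- quarter_index(from)
  j <- quarter_index(to)
  if (j < i) stop("quarter window is not ordered: ", from, " > ", to)
  idx <- seq(i, j)
  yr <- (idx - 1L) %/% 4L
  qq <- idx - 4L * yr
  paste0(yr, "Q", qq)
}

#' Is a quarter inside a window?
#'
#' @param q character vector of quarter labels (`NA` allowed, returns FALSE).
#' @param window length-2 character vector `(first, last)`, inclusive.
#' @return logical vector.
#' @export
quarter_in_window <- function(q, window) {
  ok <- !is.na(q) & grepl("^[0-9]{4}Q[1-4]$", q)
  out <- rep(FALSE, length(q))
  i <- quarter_index(window[1])
  j <- quarter_index(window[2])
  qi <- quarter_index(q[ok])
  out[ok] <- qi >= i & qi <= j
  out
}

## first and last day of a quarter label, as Date
quarter_bounds <- function(q) {
  yr <- as.integer(substr(q, 1, 4))
  qq <- as.integer(substr(q, 6, 6))
  first <- as.Date(sprintf("%04d-%02d-01", yr, (qq - 1L) * 3L + 1L))
  nxt <- as.Date(sprintf("%04d-%02d-01", yr + (qq == 4L), ifelse(qq == 4L, 1L, qq * 3L + 1L)))
  list(first = first, last = nxt - 1L)
}

## Date -> YYYYMMDD string
format_faers_date <- function(d) format(d, "%Y%m%d")

#' Harmonize a FAERS age to years
#'
#' Applies the FAERS age-unit code: `YR` years, `DEC` decades, `MON` months,
#' `WK` weeks, `DY` days, `HR` hours. Unparseable ages or unknown codes give
#' `NA`.
#'
#' @param age numeric or character vector of age values.
#' @param age_cod character vector of unit codes; empty/NA treated as years.
#' @return numeric vector of ages in years.
#' @export
age_in_years <- function(age, age_cod) {
  a <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(ifelse(is.na(age_cod), "YR", age_cod)))
  cod[cod == ""] <- "YR"
  mult <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25, DY = 1 / 365.25,
            HR = 1 / (24 * 365.25))
  m <- mult[cod]
  out <- a * as.numeric(m)
  out[is.na(m)] <- NA_real_
  out
}
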