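# Internal date conventions shared by every module.
#
# All dates are base `Date` objects internally.  Register files may carry
# year-only dates; these are completed to July 1 of that year (midpoint
# convention, consistent with annual-resolution analyses) and tagged with a
# precision flag so writers can round-trip the original field.

DAYS_PER_YEAR <- 365.25

#' Age in (fractional) years at a date
#' @param date,birth `Date` vectors.
#' @return numeric years, `(date - birth) / 365.25`.
#' @keywords internal
#' @noRd
age_years <- function(date, birth) {
  as.numeric(date - birth) / DAYS_PER_YEAR
}

# June 15 of a calendar year: the annual reference date at which pools are
# evaluated and at which observation episodes are split.
june15 <- function(year) {
  as.Date(sprintf("%04d-06-15", as.integer(year)))
}

year_of <- function(date) as.integer(format(date, "%Y"))

# The year whose June-15 reference date is the most recent one at or before
# `date`; rows starting before June 15 carry the previous year's sex ratio.
ref_year <- function(date) {
  y <- year_of(date)
  ifelse(date >= june15(y), y, y - 1L)
}

decade_of <- function(date) {
  (year_of(date) %/% 10L) * 10L
}

# Parse a date field that may be an ISO date, a bare year, or an unknown
# sentinel ("" or NA).  Returns list(date = Date, prec = character) where
# prec is one of "day", "year", "unknown".
parse_flex_date <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- trimws(x)
  prec <- rep("day", length(x))
  prec[x == ""] <- "unknown"
  prec[grepl("^\\d{3,4}$", x)] <- "year"
  out <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  is_day <- prec == "day"
  if (any(is_day)) {
    parsed <- as.Date(x[is_day], format = "%Y-%m-%d")
    if (anyNA(parsed)) {
      bad <- x[is_day][is.na(parsed)]
      stop("unparseable date value(s): ", paste(utils::head(bad, 5), collapse = ", "),
           call. = FALSE)
    }
    out[is_day] <- parsed
  }
  is_year <- prec == "year"
  if (any(is_year)) {
    out[is_year] <- as.Date(sprintf("%04d-07-01", as.integer(x[is_year])))
  }
  list(date = out, prec = prec)
}

# Re-emit a date in the form it arrived in (ISO date, bare year, or "").
format_flex_date <- function(date, prec) {
  out <- character(length(date))
  out[prec == "unknown"] <- ""
  d <- prec == "day"
  out[d] <- format(date[d], "%Y-%m-%d")
  y <- prec == "year"
  out[y] <- format(date[y], "%Y")
  out
}
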