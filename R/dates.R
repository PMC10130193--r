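#' Parse possibly-partial dates with an explicit precision marker
#'
#' Spontaneous-report databases record dates at whatever precision the
#' reporter supplied: full day (`"2016-04-01"` or `"20160401"`), year-month
#' (`"2016-04"` or `"201604"`), or year only (`"2016"`). Partial dates are
#' kept (anchored to the first day of the period) but flagged so that
#' downstream steps that need exact day counts, such as time-to-onset, can
#' exclude them.
#'
#' @param x character vector of date strings.
#' @return a tibble with columns `date` (class `Date`; `NA` when missing or
#'   unparseable) and `precision` (`"day"`, `"month"`, `"year"` or
#'   `"missing"`).
#' @export
#' @examples
#' parse_partial_date(c("2016-04-01", "201604", "2016", "", "garbled"))
parse_partial_date <- function(x) {
  x <- str_trim(as.character(x))
  x[is.na(x)] <- ""
  digits <- gsub("[-/]", "", x)
  precision <- dplyr::case_when(
    x == "" ~ "missing",
    grepl("^[0-9]{8}$", digits) ~ "day",
    grepl("^[0-9]{6}$", digits) ~ "month",
    grepl("^[0-9]{4}$", digits) ~ "year",
    TRUE ~ "unparseable"
  )
  iso <- dplyr::case_when(
    precision == "day"   ~ paste0(substr(digits, 1, 4), "-", substr(digits, 5, 6), "-", substr(digits, 7, 8)),
    precision == "month" ~ paste0(substr(digits, 1, 4), "-", substr(digits, 5, 6), "-01"),
    precision == "year"  ~ paste0(digits, "-01-01"),
    TRUE ~ NA_character_
  )
  date <- as.Date(iso, format = "%Y-%m-%d")
  # a well-formed string with an impossible calendar date (e.g. month 13)
  # is unparseable too
  bad <- !is.na(iso) & is.na(date)
  precision[bad] <- "unparseable"
  n_bad <- sum(precision == "unparseable")
  if (n_bad > 0) {
    warn(sprintf("%d date value(s) could not be parsed; kept as missing", n_bad))
    precision[precision == "unparseable"] <- "missing"
  }
  tibble(date = date, precision = precision)
}

# inverse of parse_partial_date for serializing synthetic tables
format_partial_date <- function(date, precision) {
  out <- dplyr::case_when(
    precision == "missing" | is.na(date) ~ "",
    precision == "day" ~ format(date, "%Y-%m-%d"),
    precision == "month" ~ format(date, "%Y%m"),
    precision == "year" ~ format(date, "%Y"),
    TRUE ~ ""
  )
  out
}
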