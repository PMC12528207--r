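#' Parse calendar-period labels
#'
#' Period labels are either a single year (`"1751"`) or a year range joined by
#' a hyphen or an en-dash (`"1751-1754"`, `"1751–1754"`). Single years are
#' treated as degenerate one-year periods so 1x1 tables load unchanged.
#'
#' @param x Character vector of period labels (or integer years).
#' @return A tibble with columns `period` (canonical label, en-dash),
#'   `period_start`, `period_end` (integer calendar years).
#' @examples
#' parse_period("1751-1754")
#' parse_period(c("2020–2023", "1751"))
#' @export
parse_period <- function(x) {
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^([0-9]{1,4})(?:\\s*[-–]\\s*([0-9]{1,4}))?$", x))
  bad <- vapply(m, length, 1L) == 0L | !nzchar(x)
  if (any(bad)) {
    abort(sprintf(
      "Unparseable period label(s): %s (expected 'YYYY' or 'YYYY-YYYY').",
      paste(sQuote(unique(x[bad])), collapse = ", ")
    ), class = "smcorr_parse_error")
  }
  start <- as.integer(vapply(m, `[`, "", 2L))
  end_raw <- vapply(m, `[`, "", 3L)
  end <- ifelse(nzchar(end_raw), suppressWarnings(as.integer(end_raw)), start)
  if (any(end < start)) {
    abort("Period end year precedes start year.", class = "smcorr_parse_error")
  }
  tibble(
    period = period_label(start, end),
    period_start = start,
    period_end = end
  )
}

#' Canonical period label
#'
#' @param start,end Integer calendar years (`end` may equal `start`).
#' @return Character labels using an en-dash, or the bare year when degenerate.
#' @export
period_label <- function(start, end = start) {
  ifelse(end == start,
    as.character(start),
    paste0(start, "–", end)
  )
}

# strictly increasing, non-overlapping check used by surface/fit validators
check_periods_ordered <- function(starts, ends, what = "periods") {
  if (is.unsorted(starts, strictly = TRUE)) {
    abort(sprintf("%s must be strictly increasing by start year.", what),
          class = "smcorr_order_error")
  }
  if (any(head(ends, -1) >= tail(starts, -1))) {
    abort(sprintf("%s overlap.", what), class = "smcorr_order_error")
  }
  invisible(TRUE)
}
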