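#' Read an HMD-style period Mx file into a mortality surface
#'
#' Parses the Human Mortality Database plain-text layout for period central
#' death rates: an optional preamble, then a whitespace-separated table whose
#' header names at least `Year`, `Age`, and the requested sex column. `Year`
#' cells are single years or ranges (`1751-1754`, hyphen or en-dash); the
#' `110+` open age class is kept as age 110 with `open_age = TRUE`; the HMD
#' missing marker `"."` (and, with a warning, any other non-numeric token)
#' becomes a missing rate.
#'
#' @param path Path to the Mx text file.
#' @param column Which rate column to read: `"Female"`, `"Male"` or `"Total"`.
#'   The combined-sex `"Total"` series is the default.
#' @param population Label attached to the surface; defaults to the file name.
#' @return A mortality surface: a tibble with one row per (age, period) cell
#'   and columns `population`, `period`, `period_start`, `period_end`, `age`,
#'   `open_age`, `rate` (rate per person-year, `NA` when missing), ordered by
#'   period then age.
#' @seealso [write_hmd_mx()] for the inverse, [fit_gompertz_periods()] for the
#'   next pipeline stage.
#' @export
read_hmd_mx <- function(path, column = "Total", population = NULL) {
  stopifnot(is.character(column), length(column) == 1L)
  if (is.null(population)) {
    population <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  toks <- lapply(lines, function(l) strsplit(trimws(l), "[ \t]+")[[1]])
  hdr_i <- which(vapply(
    toks, function(t) all(c("Year", "Age") %in% t), logical(1)
  ))[1]
  if (is.na(hdr_i)) {
    abort("No header row naming both 'Year' and 'Age' found.",
          class = "smcorr_parse_error")
  }
  header <- toks[[hdr_i]]
  if (!column %in% header) {
    abort(sprintf(
      "Unknown column %s; file provides: %s.",
      sQuote(column), paste(header, collapse = ", ")
    ), class = "smcorr_column_error")
  }
  rows <- toks[seq_along(toks) > hdr_i]
  rows <- rows[vapply(rows, length, 1L) > 0L]
  if (!length(rows)) {
    abort("Mx file has a header but no data rows.", class = "smcorr_parse_error")
  }
  if (any(vapply(rows, length, 1L) != length(header))) {
    abort("Data row with a different number of fields than the header.",
          class = "smcorr_parse_error")
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- header

  per <- parse_period(mat[, "Year"])
  age_tok <- trimws(mat[, "Age"])
  open <- grepl("\\+$", age_tok)
  age_num <- suppressWarnings(as.integer(sub("\\+$", "", age_tok)))
  if (anyNA(age_num)) {
    abort(sprintf(
      "Unparseable age token(s): %s.",
      paste(sQuote(unique(age_tok[is.na(age_num)])), collapse = ", ")
    ), class = "smcorr_parse_error")
  }

  rate_tok <- trimws(mat[, column])
  rate <- suppressWarnings(as.numeric(rate_tok))
  soft_missing <- is.na(rate) & !(rate_tok %in% c(".", "", "NA"))
  if (any(soft_missing)) {
    warn(sprintf(
      "%d non-numeric rate cell(s) (e.g. %s) treated as missing.",
      sum(soft_missing), sQuote(rate_tok[soft_missing][1])
    ))
  }
  if (any(rate < 0, na.rm = TRUE)) {
    abort("Negative mortality rate encountered.", class = "smcorr_parse_error")
  }

  surface <- tibble(
    population = population,
    period = per$period,
    period_start = per$period_start,
    period_end = per$period_end,
    age = age_num,
    open_age = open,
    rate = rate
  )
  dup <- duplicated(surface[, c("period", "age")])
  if (any(dup)) {
    d <- surface[dup, ][1, ]
    abort(sprintf("Duplicate (age, period) cell: age %d, period %s.",
                  d$age, d$period), class = "smcorr_duplicate_error")
  }
  surface <- arrange(surface, .data$period_start, .data$age)
  pers <- distinct(surface, .data$period_start, .data$period_end)
  check_periods_ordered(pers$period_start, pers$period_end, "Surface periods")
  if (is.unsorted(unique(surface$age), strictly = TRUE)) {
    abort("Ages must be strictly increasing.", class = "smcorr_order_error")
  }
  surface
}

#' Write a mortality surface in the HMD Mx dialect
#'
#' Inverse of [read_hmd_mx()]: writes `Year Age Female Male Total` with the
#' surface's rates in the `Total` column (the sex-specific columns are filled
#' with the missing marker `"."`), so simulated surfaces feed the same reader
#' as downloaded data.
#'
#' @param surface A mortality surface tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hmd_mx <- function(surface, path) {
  year <- ifelse(surface$period_end == surface$period_start,
                 as.character(surface$period_start),
                 paste0(surface$period_start, "-", surface$period_end))
  age <- ifelse(surface$open_age, paste0(surface$age, "+"),
                as.character(surface$age))
  rate <- ifelse(is.na(surface$rate), ".",
                 formatC(surface$rate, format = "g", digits = 17))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("%s, Death rates (period 1x5)", surface$population[1]),
    "",
    sprintf("%-11s %-7s %-12s %-12s %-12s", "Year", "Age",
            "Female", "Male", "Total"),
    sprintf("%-11s %-7s %-12s %-12s %-12s", year, age, ".", ".", rate)
  ), con)
  invisible(path)
}

#' Write a per-period Gompertz parameter table as CSV
#'
#' Produces the pipeline's parameter-table artifact: one row per period with
#' display-rounded columns (`a` to 4 decimals, `ln_m0` to 2, `r2` to 4,
#' `first_diff` to 4, `sign` = `"N"`/`""`/`"x"`) followed by full-precision
#' machine-readable columns (`a_full`, `first_diff_full`, `ln_m0_full`,
#' `r2_full`), so display rounding never destroys information.
#'
#' @param fits Period-ordered Gompertz fit tibble (see
#'   [fit_gompertz_periods()]).
#' @param diffs Slope first-difference records aligned to `fits` (see
#'   [first_differences()]); computed from `fits` when `NULL`. A single fit
#'   gets an undefined difference.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_params_table <- function(fits, diffs = NULL, path) {
  if (is.null(diffs)) {
    diffs <- if (nrow(fits) >= 2L) {
      first_differences(fits)
    } else {
      tibble(period = fits$period, diff = NA_real_, flag = "UNDEFINED")
    }
  }
  if (nrow(diffs) != nrow(fits) || !identical(diffs$period, fits$period)) {
    abort("Slope-difference records are not aligned with the fits.",
          class = "smcorr_alignment_error")
  }
  out <- tibble(
    period = fits$period,
    a = round(fits$alpha, 4),
    first_diff = round(diffs$diff, 4),
    sign = unname(c(NEG = "N", NONNEG = "", UNDEFINED = "x")[diffs$flag]),
    ln_m0 = round(fits$ln_m0, 2),
    r2 = round(fits$r2, 4),
    a_full = fits$alpha,
    first_diff_full = diffs$diff,
    ln_m0_full = fits$ln_m0,
    r2_full = fits$r2
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a Gompertz parameter table
#'
#' Accepts either the full artifact written by [write_params_table()] (whose
#' `*_full` columns are then used verbatim) or any CSV with at least `period`,
#' `a` and `ln_m0` columns — e.g. a published parameter table typed by hand.
#' Rows are reordered by period start year; a missing `r2` column is
#' tolerated.
#'
#' @param path CSV path.
#' @param population Population label for the returned fits (default: file
#'   name).
#' @return A Gompertz fit tibble with columns `population`, `period`,
#'   `period_start`, `period_end`, `alpha`, `ln_m0`, `r2`, ordered by period.
#' @export
read_params_table <- function(path, population = NULL) {
  if (is.null(population)) {
    population <- sub("\\.[^.]*$", "", basename(path))
  }
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("period", "a", "ln_m0"), names(d))
  if (length(missing_cols)) {
    abort(sprintf("Parameter table is missing mandatory column(s): %s.",
                  paste(sQuote(missing_cols), collapse = ", ")),
          class = "smcorr_column_error")
  }
  per <- parse_period(d$period)
  tibble(
    population = population,
    period = per$period,
    period_start = per$period_start,
    period_end = per$period_end,
    alpha = if ("a_full" %in% names(d)) d$a_full else d$a,
    ln_m0 = if ("ln_m0_full" %in% names(d)) d$ln_m0_full else d$ln_m0,
    r2 = if ("r2_full" %in% names(d)) {
      d$r2_full
    } else if ("r2" %in% names(d)) d$r2 else NA_real_
  ) %>%
    arrange(.data$period_start)
}

#' Published per-period Gompertz parameters for Sweden and France
#'
#' Convenience accessor for the parameter tables shipped with the package:
#' least-squares Gompertz estimates (`a`, `ln(m0)`, `R^2`) over ages 40–95
#' from Human Mortality Database `Total` period rates, Sweden 1751–2023
#' (55 five-year periods) and France 1815–2021 (42 periods).
#'
#' @param population `"sweden"` or `"france"`.
#' @return A Gompertz fit tibble (see [read_params_table()]).
#' @examples
#' fit_sm(example_params("sweden"))
#' @export
example_params <- function(population = c("sweden", "france")) {
  population <- match.arg(population)
  path <- system.file("extdata",
                      paste0(population, "_gompertz_params.csv"),
                      package = "smcorr", mustWork = TRUE)
  read_params_table(path, population = population)
}
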