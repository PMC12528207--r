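#' First differences of the Gompertz slope series
#'
#' `diff = alpha(t) - alpha(t-1)` between consecutive periods, computed on
#' full-precision slopes. A strictly negative difference is flagged `"NEG"` —
#' the aging rate fell, a change inconsistent with rotation-type (SM)
#' development; zero or positive differences are `"NONNEG"`; the first period
#' of a series has no predecessor and is `"UNDEFINED"` with a missing diff.
#'
#' @param fits Gompertz fit tibble ordered by period (at least 2 rows, with
#'   `period`, `period_start`, `alpha`).
#' @return Tibble with one row per fit: `population` (if present), `period`,
#'   `diff`, `flag`.
#' @examples
#' first_differences(example_params("sweden"))
#' @export
first_differences <- function(fits) {
  stopifnot(all(c("period", "alpha") %in% names(fits)))
  if (nrow(fits) < 2L) {
    abort("Need at least 2 period fits to difference.",
          class = "smcorr_degenerate_error")
  }
  starts <- if ("period_start" %in% names(fits)) {
    fits$period_start
  } else {
    parse_period(fits$period)$period_start
  }
  if (is.unsorted(starts, strictly = TRUE)) {
    abort("Fits must be ordered by strictly increasing period start year.",
          class = "smcorr_order_error")
  }
  d <- c(NA_real_, diff(fits$alpha))
  out <- tibble(
    period = fits$period,
    diff = d,
    flag = dplyr::case_when(
      is.na(d) ~ "UNDEFINED",
      d < 0 ~ "NEG",
      TRUE ~ "NONNEG"
    )
  )
  if ("population" %in% names(fits)) {
    out <- dplyr::bind_cols(tibble(population = fits$population), out)
  }
  out
}

#' Periods flagged SM-inconsistent in every population
#'
#' Intersects the `"NEG"`-flagged periods of several slope-difference series:
#' a period qualifies only if it is present in every series and flagged
#' negative in every series. Periods absent from any series are excluded;
#' matching is by canonical period label.
#'
#' @param series A list of [first_differences()] tibbles, one per population
#'   (at least 2).
#' @return Character vector of period labels in chronological order.
#' @export
concordant_negative_periods <- function(series) {
  stopifnot(is.list(series), length(series) >= 2L)
  neg_sets <- lapply(series, function(s) s$period[s$flag == "NEG"])
  common <- Reduce(intersect, neg_sets)
  if (!length(common)) return(character(0))
  common[order(parse_period(common)$period_start)]
}
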