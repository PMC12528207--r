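#' Extract (age, ln rate) points for one period
#'
#' Selects the usable observations for a period-level Gompertz fit: ages
#' inside the inclusive window whose rates are present and strictly positive
#' (the log of a zero or missing rate is undefined, so such cells are dropped,
#' with a message naming them). The age coordinate is the integer age-class
#' label, i.e. the lower bound of \[x, x+1); set `midpoint = TRUE` to use
#' x + 0.5 instead for sensitivity analysis.
#'
#' @param surface A mortality surface tibble (see [read_hmd_mx()]).
#' @param period Canonical period label present in the surface.
#' @param age_window Inclusive integer age range, default `c(40, 95)`.
#' @param midpoint Use age-class midpoints as the age coordinate.
#' @return A tibble with columns `age` (regression coordinate) and `ln_rate`.
#' @export
extract_log_rate_points <- function(surface, period, age_window = c(40, 95),
                                    midpoint = FALSE) {
  if (!period %in% surface$period) {
    abort(sprintf("Period %s not present in surface %s.",
                  sQuote(period), sQuote(surface$population[1])),
          class = "smcorr_missing_period_error")
  }
  rows <- filter(surface, .data$period == !!period,
                 .data$age >= age_window[1], .data$age <= age_window[2])
  dropped <- filter(rows, is.na(.data$rate) | .data$rate <= 0)
  if (nrow(dropped)) {
    inform(sprintf("Period %s: excluded %d cell(s) with missing/zero rate (ages %s).",
                   period, nrow(dropped),
                   paste(dropped$age, collapse = ", ")))
  }
  pts <- filter(rows, !is.na(.data$rate), .data$rate > 0)
  if (nrow(pts) < 3L) {
    abort(sprintf(
      "Period %s has only %d usable point(s) in ages [%d, %d]; need at least 3.",
      period, nrow(pts), age_window[1], age_window[2]
    ), class = "smcorr_degenerate_error")
  }
  tibble(
    age = pts$age + if (midpoint) 0.5 else 0,
    ln_rate = log(pts$rate)
  )
}

#' Fit the Gompertz log-linear model to one period's points
#'
#' Ordinary (unweighted) least squares of ln mortality rate on age:
#' `ln mu(x) = ln_m0 + alpha * x`. `alpha` is the aging rate (per year of
#' age), `ln_m0` the log intensity extrapolated to age 0, and `r2` the
#' coefficient of determination `1 - SSE/SST` (defined as 1 when all ln rates
#' are equal, in which case `alpha` is 0). Point estimation only — no
#' inference is attached.
#'
#' @param points Tibble with columns `age` and `ln_rate`
#'   (see [extract_log_rate_points()]); at least 3 points on at least 2
#'   distinct ages.
#' @return One-row tibble: `alpha`, `ln_m0`, `r2`, `n_ages`, `age_min`,
#'   `age_max`.
#' @examples
#' pts <- tibble::tibble(age = 40:95, ln_rate = -7 + 0.07 * (40:95))
#' fit_gompertz(pts)
#' @export
fit_gompertz <- function(points) {
  stopifnot(all(c("age", "ln_rate") %in% names(points)))
  if (nrow(points) < 3L) {
    abort(sprintf("Need at least 3 points to fit a Gompertz line; got %d.",
                  nrow(points)), class = "smcorr_degenerate_error")
  }
  if (length(unique(points$age)) < 2L) {
    abort("All points share one age; the Gompertz slope is undefined.",
          class = "smcorr_degenerate_error")
  }
  m <- lm(ln_rate ~ age, data = points)
  sse <- sum(resid(m)^2)
  sst <- sum((points$ln_rate - mean(points$ln_rate))^2)
  tibble(
    alpha = unname(coef(m)[["age"]]),
    ln_m0 = unname(coef(m)[["(Intercept)"]]),
    r2 = if (sst == 0) 1 else 1 - sse / sst,
    n_ages = nrow(points),
    age_min = min(points$age),
    age_max = max(points$age)
  )
}

#' Fit Gompertz parameters for every period of a surface
#'
#' Runs [extract_log_rate_points()] and [fit_gompertz()] period by period over
#' the age window. Periods with fewer than 3 usable points are skipped with a
#' warning rather than aborting the run.
#'
#' @inheritParams extract_log_rate_points
#' @return Gompertz fit tibble, one row per successfully fitted period, in
#'   period order: `population`, `period`, `period_start`, `period_end`,
#'   `alpha`, `ln_m0`, `r2`, `n_ages`, `age_min`, `age_max`.
#' @export
fit_gompertz_periods <- function(surface, age_window = c(40, 95),
                                 midpoint = FALSE) {
  pers <- distinct(surface, .data$period, .data$period_start, .data$period_end)
  pers <- arrange(pers, .data$period_start)
  if (!nrow(pers)) {
    abort("Surface contains no periods.", class = "smcorr_degenerate_error")
  }
  fits <- purrr::pmap(pers, function(period, period_start, period_end) {
    res <- tryCatch(
      fit_gompertz(extract_log_rate_points(surface, period, age_window,
                                           midpoint = midpoint)),
      smcorr_degenerate_error = function(e) {
        warn(sprintf("Skipping period %s: %s", period, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(res)) return(NULL)
    dplyr::bind_cols(
      tibble(population = surface$population[1], period = period,
             period_start = period_start, period_end = period_end),
      res
    )
  })
  fits <- bind_rows(fits)
  if (!nrow(fits)) {
    abort("No period could be fitted.", class = "smcorr_degenerate_error")
  }
  fits
}

#' Predicted log mortality intensity under a Gompertz fit
#'
#' @param fit One-row Gompertz fit (any tibble/list with `alpha` and `ln_m0`).
#' @param age Age(s) in years.
#' @return `ln_m0 + alpha * age`.
#' @export
predict_ln_mu <- function(fit, age) {
  fit$ln_m0 + fit$alpha * age
}
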