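#' Fit the Strehler–Mildvan correlation across periods
#'
#' Second-level ordinary least squares of the Gompertz intercept on the
#' Gompertz slope, `ln m0 = YA - A * alpha`: if successive period Gompertz
#' lines rotate about a fixed point, the point's age `A` is minus the
#' regression slope and `YA` is the log mortality intensity there. The fit
#' also carries the per-period residuals and the residual band: the
#' regression line shifted by the maximum (`r_max`) and minimum (`r_min`)
#' residual on the ln scale, whose width is `band_ratio = exp(r_max - r_min)`
#' — the ratio of the upper to the lower band line at any fixed `alpha` on
#' the intensity (log-axis) scale.
#'
#' The regression direction is `ln_m0` on `alpha`, never the reverse and not
#' orthogonal regression, because the rotation model states the intercept as
#' a function of the slope.
#'
#' @param fits Gompertz fit tibble (at least columns `alpha`, `ln_m0`, and
#'   ideally `period`); at least 3 rows with at least 2 distinct `alpha`
#'   values.
#' @param population Population label; taken from `fits` when present.
#' @return An object of class `sm_fit`: a list with elements `population`,
#'   `slope`, `A_years` (= -slope), `YA`, `r2`, `n`, `r_max`, `r_min`,
#'   `band_ratio`, and `data` — the input rows with `fitted` and `residual`
#'   columns, in input order. Use [tidy()] / [glance()] / [autoplot()] on it.
#' @examples
#' fit_sm(example_params("sweden"))
#' @export
fit_sm <- function(fits, population = NULL) {
  stopifnot(all(c("alpha", "ln_m0") %in% names(fits)))
  if (is.null(population)) {
    population <- if ("population" %in% names(fits)) fits$population[1] else ""
  }
  if (nrow(fits) < 3L) {
    abort(sprintf("Need at least 3 period fits for the SM regression; got %d.",
                  nrow(fits)), class = "smcorr_degenerate_error")
  }
  if (length(unique(fits$alpha)) < 2L) {
    abort("All Gompertz slopes are equal: the SM points fall on a vertical line and the rotation age is undefined.",
          class = "smcorr_vertical_error")
  }
  m <- lm(ln_m0 ~ alpha, data = fits)
  r <- unname(resid(m))
  sse <- sum(r^2)
  sst <- sum((fits$ln_m0 - mean(fits$ln_m0))^2)
  data <- mutate(as_tibble(fits),
                 fitted = unname(fitted(m)), residual = r)
  structure(list(
    population = population,
    slope = unname(coef(m)[["alpha"]]),
    A_years = -unname(coef(m)[["alpha"]]),
    YA = unname(coef(m)[["(Intercept)"]]),
    r2 = if (sst == 0) 1 else 1 - sse / sst,
    n = nrow(fits),
    r_max = max(r),
    r_min = min(r),
    band_ratio = exp(max(r) - min(r)),
    data = data
  ), class = "sm_fit")
}

#' Residual-band width ratio of an SM fit
#'
#' `exp(r_max - r_min)`: the ratio between the upper and lower band lines on
#' the log-intensity axis. Always `>= 1`; equal to 1 exactly when all
#' residuals coincide. Invariant under a constant shift of all `ln_m0`.
#'
#' @param smfit An [fit_sm()] result.
#' @return The dimensionless band ratio.
#' @export
band_ratio <- function(smfit) {
  stopifnot(inherits(smfit, "sm_fit"))
  exp(smfit$r_max - smfit$r_min)
}

#' Log mortality intensity at the rotation-point age
#'
#' Evaluates a period's Gompertz line at the SM rotation age `A`:
#' `ln_m0 + alpha * A_years`. Under perfect rotation this is `YA` for every
#' period; in general it equals `YA` plus that period's SM residual, so
#' intercept shocks reappear here with their sign.
#'
#' @param fit Gompertz fit row(s) with `alpha` and `ln_m0`.
#' @param smfit An [fit_sm()] result supplying `A_years`.
#' @return Log intensity value(s) at age `A`.
#' @export
rotation_point_intensity <- function(fit, smfit) {
  stopifnot(inherits(smfit, "sm_fit"))
  fit$ln_m0 + fit$alpha * smfit$A_years
}

#' Intersection age of two Gompertz lines
#'
#' The age at which two period lines cross:
#' `(ln_m0_1 - ln_m0_2) / (alpha_2 - alpha_1)`. On perfect rotation data
#' every pair intersects at the common rotation age.
#'
#' @param fit1,fit2 One-row Gompertz fits.
#' @return Age in years.
#' @export
intersection_age <- function(fit1, fit2) {
  if (fit1$alpha == fit2$alpha) {
    abort("The two Gompertz lines are parallel (equal slopes); no intersection age.",
          class = "smcorr_parallel_error")
  }
  (fit1$ln_m0 - fit2$ln_m0) / (fit2$alpha - fit1$alpha)
}

#' @export
print.sm_fit <- function(x, ...) {
  cat(sprintf("Strehler-Mildvan fit%s (%d periods)\n",
              if (nzchar(x$population)) paste0(": ", x$population) else "",
              x$n))
  cat(sprintf("  slope        %8.1f  (rotation age A = %.1f years)\n",
              x$slope, x$A_years))
  cat(sprintf("  YA           %8.2f  (ln intensity at the rotation point)\n",
              x$YA))
  cat(sprintf("  R^2          %8.3f\n", x$r2))
  cat(sprintf("  band L2/L1   %8.2f\n", x$band_ratio))
  invisible(x)
}

#' Tidy the per-period detail of an SM fit
#'
#' @param x An `sm_fit`.
#' @param ... Unused.
#' @return The per-period tibble with `fitted` and `residual` columns.
#' @method tidy sm_fit
#' @export
tidy.sm_fit <- function(x, ...) {
  x$data
}

#' One-row summary of an SM fit
#'
#' @param x An `sm_fit`.
#' @param ... Unused.
#' @return Tibble: `population`, `n`, `slope`, `A_years`, `YA`, `r2`,
#'   `r_max`, `r_min`, `band_ratio`.
#' @method glance sm_fit
#' @export
glance.sm_fit <- function(x, ...) {
  tibble(
    population = x$population, n = x$n, slope = x$slope,
    A_years = x$A_years, YA = x$YA, r2 = x$r2,
    r_max = x$r_max, r_min = x$r_min, band_ratio = x$band_ratio
  )
}

#' Write an SM fit as JSON
#'
#' Full-precision machine-readable export: scalars `population`, `A_years`,
#' `YA`, `r2`, `band_ratio` plus `residuals` keyed by period label.
#'
#' @param smfit An `sm_fit`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sm_json <- function(smfit, path) {
  stopifnot(inherits(smfit, "sm_fit"))
  res <- smfit$data$residual
  names(res) <- if ("period" %in% names(smfit$data)) {
    smfit$data$period
  } else {
    as.character(seq_along(res))
  }
  jsonlite::write_json(list(
    population = smfit$population,
    A_years = smfit$A_years,
    YA = smfit$YA,
    r2 = smfit$r2,
    band_ratio = smfit$band_ratio,
    residuals = as.list(res)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
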