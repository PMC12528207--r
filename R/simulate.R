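#' Describe a rotation-model mortality simulation
#'
#' Builds the full description of a synthetic mortality surface with the
#' structure the SM analysis assumes: every period's log mortality is
#' `ln mu(x, t) = YA_true + alpha_t * (x - A_true) + delta_t`, i.e. Gompertz
#' lines rotating about the fixed point `(A_true, YA_true)`, with optional
#' period-specific intercept shocks `delta_t` and observation noise.
#'
#' The defaults are the shipped reference scenario: 26 five-year periods,
#' ages 40–95, rotation point (100 years, -0.6), aging rate rising linearly
#' from 0.06 to 0.11 per year of age — a range matching long-run European
#' series — and exposure 1e6 person-years per cell.
#'
#' @param A_true Rotation-point age in years.
#' @param YA_true Log mortality intensity at the rotation point.
#' @param alpha_schedule Per-period Gompertz slopes (per year of age).
#' @param age_range Inclusive integer age range simulated.
#' @param period_labels Optional period labels; defaults to consecutive
#'   five-year periods starting 1900.
#' @param exposure Person-years at risk per (age, period) cell; strictly
#'   positive scalar.
#' @param noise_model `"none"`, `"poisson"` (deaths ~ Poisson(exposure * mu),
#'   rate = deaths / exposure, zero-death cells missing) or `"lognormal"`
#'   (additive Normal(0, sigma^2) on the ln rate).
#' @param sigma Lognormal noise SD on the ln scale (required when
#'   `noise_model = "lognormal"`).
#' @param shocks Named numeric vector: period label -> intercept offset
#'   `delta` on the ln scale.
#' @param seed Integer seed; simulation is reproducible given the spec.
#' @return An object of class `simulation_spec` (a validated list).
#' @export
simulation_spec <- function(A_true = 100, YA_true = -0.6,
                            alpha_schedule = seq(0.06, 0.11,
                                                 length.out = 26),
                            age_range = c(40, 95),
                            period_labels = NULL,
                            exposure = 1e6,
                            noise_model = c("none", "poisson", "lognormal"),
                            sigma = NULL,
                            shocks = NULL,
                            seed = 1L) {
  noise_model <- match.arg(noise_model)
  n_per <- length(alpha_schedule)
  if (is.null(period_labels)) {
    starts <- 1900 + 5 * (seq_len(n_per) - 1)
    period_labels <- period_label(starts, starts + 4)
  }
  if (length(period_labels) != n_per) {
    abort("alpha_schedule and period_labels must have equal length.",
          class = "smcorr_spec_error")
  }
  if (anyDuplicated(period_labels)) {
    abort("Period labels must be unique.", class = "smcorr_spec_error")
  }
  if (!is.numeric(exposure) || length(exposure) != 1L || exposure <= 0) {
    abort("Exposure must be a single strictly positive number.",
          class = "smcorr_spec_error")
  }
  if (noise_model == "lognormal") {
    if (is.null(sigma) || sigma < 0) {
      abort("Lognormal noise requires sigma >= 0.", class = "smcorr_spec_error")
    }
  } else {
    sigma <- NULL
  }
  if (!is.null(shocks)) {
    if (is.null(names(shocks)) || !all(names(shocks) %in% period_labels)) {
      abort("Shocks must be named by period labels present in the schedule.",
            class = "smcorr_spec_error")
    }
  }
  structure(list(
    A_true = A_true, YA_true = YA_true,
    alpha_schedule = as.numeric(alpha_schedule),
    age_range = as.integer(age_range),
    period_labels = as.character(period_labels),
    exposure = exposure,
    noise_model = noise_model,
    sigma = sigma,
    shocks = shocks,
    seed = as.integer(seed)
  ), class = "simulation_spec")
}

#' Simulate a mortality surface from a rotation-model spec
#'
#' Generates the noiseless log intensities
#' `YA_true + alpha_t * (x - A_true) + delta_t` and overlays the requested
#' observation noise. Randomness is drawn from one sub-stream per period
#' (seeded from `seed` and the period's position in the schedule), so adding
#' or removing trailing periods does not perturb the others.
#'
#' @param spec A [simulation_spec()].
#' @param population Label for the generated surface.
#' @return An object of class `sm_simulation`: list with `surface` (a
#'   mortality surface tibble as from [read_hmd_mx()]), `truth` (the spec),
#'   and `true_ln_mu` (tibble `period`, `age`, `ln_mu` of noiseless values).
#' @examples
#' sim <- simulate_surface(simulation_spec())
#' fit_sm(fit_gompertz_periods(sim$surface))
#' @export
simulate_surface <- function(spec, population = "simulated") {
  stopifnot(inherits(spec, "simulation_spec"))
  ages <- seq(spec$age_range[1], spec$age_range[2])
  per <- parse_period(spec$period_labels)
  check_periods_ordered(per$period_start, per$period_end,
                        "Simulated periods")
  cells <- purrr::imap(spec$alpha_schedule, function(alpha_t, i) {
    delta <- 0
    if (!is.null(spec$shocks)) {
      hit <- match(spec$period_labels[i], names(spec$shocks))
      if (!is.na(hit)) delta <- spec$shocks[[hit]]
    }
    ln_mu <- spec$YA_true + alpha_t * (ages - spec$A_true) + delta
    set.seed((spec$seed + 7919L * i) %% .Machine$integer.max)
    rate <- switch(spec$noise_model,
      none = exp(ln_mu),
      poisson = {
        deaths <- rpois(length(ages), spec$exposure * exp(ln_mu))
        r <- deaths / spec$exposure
        r[deaths == 0] <- NA_real_  # ln(0) undefined; mirrors sparse HMD cells
        r
      },
      lognormal = exp(ln_mu + rnorm(length(ages), 0, spec$sigma))
    )
    tibble(
      population = population,
      period = per$period[i],
      period_start = per$period_start[i],
      period_end = per$period_end[i],
      age = ages,
      open_age = FALSE,
      rate = rate,
      ln_mu = ln_mu
    )
  })
  all <- bind_rows(cells) %>% arrange(.data$period_start, .data$age)
  structure(list(
    surface = select(all, -"ln_mu"),
    truth = spec,
    true_ln_mu = select(all, "period", "age", "ln_mu")
  ), class = "sm_simulation")
}

#' Parameter-recovery report for a simulated analysis
#'
#' Compares a pipeline result against the simulation truth: signed errors of
#' the recovered rotation point, per-period aging-rate errors, and — for each
#' shocked period — whether the SM residual carries the same sign as the
#' injected intercept offset.
#'
#' @param output An [simulate_surface()] result.
#' @param smfit The [fit_sm()] object computed from `output$surface` via
#'   [fit_gompertz_periods()].
#' @return List of class `recovery_report`: `summary` (one-row tibble with
#'   `A_error`, `YA_error`, `r2`), `alpha_errors` (tibble `period`,
#'   `alpha_true`, `alpha_fit`, `error`), `shocks` (tibble `period`, `delta`,
#'   `residual`, `sign_match`; zero rows when unshocked).
#' @export
recovery_report <- function(output, smfit) {
  stopifnot(inherits(output, "sm_simulation"), inherits(smfit, "sm_fit"))
  truth <- output$truth
  fit_d <- smfit$data
  if (!all(fit_d$period %in% truth$period_labels)) {
    abort("SM fit contains periods absent from the simulation spec.",
          class = "smcorr_alignment_error")
  }
  idx <- match(fit_d$period, truth$period_labels)
  alpha_errors <- tibble(
    period = fit_d$period,
    alpha_true = truth$alpha_schedule[idx],
    alpha_fit = fit_d$alpha,
    error = fit_d$alpha - truth$alpha_schedule[idx]
  )
  shocks <- if (is.null(truth$shocks)) {
    tibble(period = character(0), delta = numeric(0),
           residual = numeric(0), sign_match = logical(0))
  } else {
    sh <- tibble(period = names(truth$shocks),
                 delta = as.numeric(truth$shocks))
    sh <- left_join(sh, select(fit_d, "period", "residual"), by = "period")
    mutate(sh, sign_match = sign(.data$residual) == sign(.data$delta))
  }
  structure(list(
    summary = tibble(
      A_error = smfit$A_years - truth$A_true,
      YA_error = smfit$YA - truth$YA_true,
      r2 = smfit$r2
    ),
    alpha_errors = alpha_errors,
    shocks = shocks
  ), class = "recovery_report")
}

#' Write / read a simulation spec as JSON
#'
#' @param spec A [simulation_spec()].
#' @param path JSON path.
#' @return `write_simulation_spec()` returns `path` invisibly;
#'   `read_simulation_spec()` returns the validated `simulation_spec`.
#' @export
write_simulation_spec <- function(spec, path) {
  stopifnot(inherits(spec, "simulation_spec"))
  x <- unclass(spec)
  x$shocks <- as.list(x$shocks)  # keep period-label names through JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_simulation_spec
#' @export
read_simulation_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  simulation_spec(
    A_true = x$A_true, YA_true = x$YA_true,
    alpha_schedule = x$alpha_schedule,
    age_range = x$age_range,
    period_labels = x$period_labels,
    exposure = x$exposure,
    noise_model = x$noise_model,
    sigma = x$sigma,
    shocks = if (length(x$shocks)) unlist(x$shocks) else NULL,
    seed = x$seed
  )
}
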