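Package: smcorr
Title: Strehler-Mildvan Correlation Analysis of Long-Term Period Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the Strehler-Mildvan (SM) analysis of long-term
    period mortality: reading Human Mortality Database style 1x5 Mx files,
    per-period least-squares fitting of the Gompertz log-linear mortality
    model over a configurable age window, the second-level SM regression of
    the Gompertz intercept on the slope (whose negative slope estimates the
    rotation-point age), residual-band construction on the log scale,
    first-difference diagnostics of the aging-rate series with cross-country
    concordance of SM-inconsistent periods, and a seeded rotation-model
    simulator for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
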