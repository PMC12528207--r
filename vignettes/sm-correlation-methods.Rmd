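---
title: "Methods: the Strehler–Mildvan correlation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Strehler–Mildvan correlation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcorr)
```

## The two-level model

`smcorr` analyses a period mortality surface — age-specific central death
rates `Mx` on a 1-year-age by (typically) 5-year-period grid — in two
stacked ordinary least-squares regressions.

**Level 1 (Gompertz).** For each calendar period, the log rate is regressed
on age over an inclusive window, by default ages 40–95:

$$\ln \mu(x) = \ln m_0 + \alpha\, x$$

`Mx` values are used directly as the mortality intensity — no smoothing,
actuarial transformation, or Makeham background term. The fit is unweighted
least squares, used strictly for point estimation: mortality residuals are
known to be non-normal and U-shaped over age, so no standard errors or
inference are attached, and the fit quality is summarised only by the
coefficient of determination.

**Level 2 (Strehler–Mildvan).** Treating each period as one observation
$(\alpha_t, \ln m_{0,t})$, the intercept is regressed on the slope:

$$\ln m_0(\alpha) = Y_A - A\,\alpha$$

If the period Gompertz lines intersect at a common point, they rotate about
$(A, Y_A)$: the age at which intensity is invariant over time, and the log
intensity there. The regression direction is fixed — intercept on slope —
because the rotation model states $\ln m_0$ as a function of $\alpha$;
reversing it or using orthogonal regression would estimate a different
functional and is deliberately not offered.

**Residual band.** The SM scatter is enclosed by two lines parallel to the
regression line, shifted by the maximum and minimum residual ($r_{max}$,
$r_{min}$) on the ln scale. We summarise the band width as

$$L_2/L_1 = \exp(r_{max} - r_{min}) \ge 1,$$

the vertical ratio between the two edges at any fixed $\alpha$ once the
intensity axis is drawn logarithmically. The band is only defined verbally
in the descriptive literature; this reading was chosen because it is
invariant to where along the $\alpha$ axis the ratio is read and to constant
shifts of all intercepts, and it reproduces the published width ratios for
Sweden and France from their parameter tables (checked in the test suite).

**Slope diagnostics.** The first difference
$\Delta\alpha_t = \alpha_t - \alpha_{t-1}$ is computed on full-precision
slopes; $\Delta\alpha_t < 0$ (strictly) is flagged `NEG` — the aging rate
fell, which rotation-type development does not produce. A zero difference is
`NONNEG`: ties break toward consistency with the model, since only genuine
decreases are evidence against it. Cross-population concordance intersects
the `NEG` period labels of several series; matching is by exact canonical
label, with no fuzzy alignment of differing period grids.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `age_window` | [40, 95] | years | linearity of ln-mortality holds from mid-life; very old ages are sparse and noisy |
| `column` | `"Total"` | — | combined-sex schedule |
| `midpoint` | `FALSE` | — | age coordinate is the class label (lower bound of [x, x+1)); midpoint x + 0.5 shifts the intercept by α/2 and is offered for sensitivity only |
| `exposure` (simulator) | 1e6 | person-years/cell | national-scale cell sizes; Poisson noise is then small but visible |

The label-vs-midpoint choice changes `ln_m0` by a constant per period and
therefore cannot change SM slopes fitted across periods with similar
$\alpha$ ranges materially; the label convention is the default because the
published parameter magnitudes are reproduced under it.

## Numerical choices and degenerate inputs

- Both regressions go through `stats::lm`; the test suite checks them
  against an independent normal-equations solver at $10^{-10}$ relative
  tolerance on randomized small instances.
- $R^2 = 1 - SSE/SST$, with the convention $R^2 = 1$ when $SST = 0$ (a
  perfectly flat response is fitted perfectly by the degenerate line).
- Zero or missing rate cells are excluded, never imputed — $\ln 0$ is
  undefined — and each exclusion is reported with age and period. A period
  needs at least 3 usable points and 2 distinct ages; failing periods are
  skipped with a warning in the whole-surface fit but abort a single-period
  fit.
- The SM fit requires at least 3 period fits and 2 distinct slopes; equal
  slopes make the rotation age undefined (vertical SM scatter) and raise a
  specific error, as do parallel lines in the pairwise
  `intersection_age()`.
- Period labels are canonicalised with an en-dash (`1751–1754`); hyphens are
  accepted on input, single years become degenerate one-period intervals.
  Written tables carry display-rounded columns (slope 4 dp, intercept 2 dp,
  $R^2$ 4 dp) *and* full-precision columns, because flags and second-level
  fits computed from rounded values differ subtly from those computed from
  full precision: one published France cell prints a +0.0001 slope change
  yet a negative sign flag, which only unrounded inputs can explain. Flags
  are therefore always computed on the values as given, and never forced to
  agree with a printed sign column.

## What the simulator emulates — and what it does not

`simulation_spec()` defaults encode the reference scenario used throughout
the tests: 26 five-year periods, ages 40–95, rotation point
$(A, Y_A) = (100\ \text{years}, -0.6)$, aging rate rising linearly
0.06 → 0.11 per year of age (the range spanned by the long Swedish series),
exposure $10^6$ person-years per cell. Noise models:

- `none` — rates are exactly $\exp(\ln\mu)$; the pipeline must invert the
  construction to machine precision.
- `poisson` — deaths $\sim$ Poisson(exposure · μ), rate = deaths/exposure;
  zero-death cells become missing, mirroring both the positivity filter and
  the behaviour of sparse historical data.
- `lognormal(σ)` — additive Gaussian noise on the ln rate.

Each period draws from its own seeded sub-stream, so truncating the period
set does not perturb the remaining periods. The generator produces exact
Gompertz schedules with independent cell noise: it does **not** emulate the
U-shaped age-residual pattern of real mortality, cohort effects, cause-of-
death composition, or correlated shocks across neighbouring periods. Passing
recovery tests therefore demonstrates that the estimation chain is correct
and well-conditioned under the model's own assumptions — not that real data
satisfy those assumptions. The published long-run series are the evidence
for the latter, and the no-inference stance of the fits reflects exactly
that gap.

Recovery scale used in the tests: noise-free inversion at 26 periods,
Poisson recovery at 30 periods × 56 ages × exposure $10^6$ (rotation age
recovered within ±2 years; a 200-replicate study of that design puts the
spread near ±0.1 years), and a 300-replicate reduced-scale check of the
Poisson cell mean. These sizes keep each property a sub-second computation
while leaving the assertions far from their tolerance edges.

## Design choices where the design was open

- **Rates as intensities.** Central death rates enter as $\mu(x)$ without
  transformation; the 1×5 layout already averages over the period.
- **Band definition frozen** as exp(max − min residual) after validating it
  against the published width ratios; alternatives (e.g. ratio of extreme
  *fitted-plus-residual* values at a reference α) depend on axis position
  and were rejected.
- **Zero diff is not flagged.** Only strict decreases contradict rotation.
- **One orchestration entry point.** `run_pipeline()` plus a thin CLI
  wrapper; every stage is also a plain function, and a parameter CSV (for
  instance a published table typed by hand) can enter mid-pipeline through
  `read_params_table()`.

## Known limitations

- No Gompertz–Makeham term, Poisson maximum-likelihood fitting, weighting,
  or confidence intervals — point estimation only, by design.
- Reproducing a specific published per-period parameter table from raw HMD
  files can be sensitive to that study's unstated handling of sparse
  old-age cells in early data; the shipped tables carry the published
  estimates themselves, so the second-level statistics are reproducible
  without the registration-gated raw files.
- Concordance requires identical period grids; populations tabulated on
  shifted periods would need re-tabulation upstream.
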