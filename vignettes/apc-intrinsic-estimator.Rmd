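---
title: "Age-period-cohort decomposition with the intrinsic estimator: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-period-cohort decomposition with the intrinsic estimator: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcie)
```

## The model and its assumptions

`apcie` decomposes a mortality-rate surface observed on an age-group ×
calendar-year grid into additive age, period and birth-cohort effects
on the log-rate scale. Writing $D_{ijk}$ for deaths and $N_{ijk}$ for
person-years in age group $i$, period $j$ and cohort $k$,

$$\ln(D_{ijk}/N_{ijk}) = \mu + \alpha_i + \beta_j + \gamma_k,
\qquad \textstyle\sum_i \alpha_i = \sum_j \beta_j = \sum_k \gamma_k = 0.$$

The Poisson likelihood with log person-years offset is appropriate for
a rare event over large populations: cause-specific mortality rates of
order $10^{-5}$–$10^{-4}$ make the binomial-to-Poisson approximation
negligible relative to sampling noise. The model assumes effects are
additive (no age × period interaction) and that the grid is complete,
closed and equal-width: open-ended age groups such as 85+ are rejected
outright because they have no defined cohort diagonal.

### Cohort indexing and the period-sampling rule

With $A$ age groups and $P$ periods there are $C = A + P - 1$ cohort
diagonals, indexed $k = (A - i) + j$ so that $k = 1$ is the oldest
cohort. Diagonals are true single-width birth cohorts only when the
period spacing equals the age-interval width: a 5-year age group
observed in a single calendar year spans 5 birth years, whereas 5-year
age groups averaged over 5-year periods span 10. The package therefore
ingests the full annual table and exposes `subsample_periods()` as an
explicit step — `fit_ie()` refuses a table whose period spacing differs
from the age width. Cohort labels are closed birth-year ranges
back-dated from the earliest period and the oldest age interval
(e.g. 1990 − 84 = 1906 and 1990 − 80 = 1910 give cohort 1 the label
1906–1910). The canonical layout — 13 five-year age groups 20–84 by the
six years 1990, 1995, ..., 2015 — yields 18 cohorts and 37 expanded
category effects. The six modelled years are exposed as configuration
(`start_year`, `step`) rather than hard-coded.

## Identification and the intrinsic estimator

The structural dependency cohort = period − age makes the effect-coded
design matrix $X$ (with the last category of each block as reference)
rank-deficient by exactly one: its null space is spanned by a single
vector $B_0$, the linear-trend trade-off between the three time scales.
Any solution can be shifted by $c B_0$ without changing a single fitted
rate, so age/period/cohort *linear trends* are inherently
exchangeable; only deviations from linearity are unambiguous.

The intrinsic estimator picks the unique representative orthogonal to
$B_0$ — equivalently, the minimum-Euclidean-norm coefficient vector.
`fit_ie()` implements it by fitting the Poisson GLM on $XV$, where $V$
is an orthonormal basis (QR of $[B_0, I]$) of the complement of $B_0$,
and mapping back as $\theta = Vw$. The reported `model_rank` is
$q - 1 = 34$ estimable directions for the canonical layout; the
expanded effects table always reports the $13 + 6 + 18 = 37$ category
effects, with the intercept reported separately rather than as a 38th
row, matching the convention of counting category effects and listing
the intercept alongside them.

Users should read IE output with the standard caveat: the minimum-norm
constraint is a mathematical, not substantive, identification choice,
and the estimand is the projection of any "true" parameter vector onto
the complement of $B_0$. The package makes this concrete:
`make_true_params(..., orthogonalize = TRUE)` produces simulation truth
that *is* its own projection, and the test suite verifies that
non-orthogonalized truth is recovered at its projection, not at itself.

## Numerical choices

* **Null vector.** Full SVD of $X$ with singular values below
  $\max(m, q)\,\varepsilon\,\sigma_{\max}$ treated as zero; an error of
  class `apcie_identification_error` reports the dimension if it is not
  exactly 1. The intercept coordinate (zero analytically) is zeroed and
  the vector renormalized; the sign is fixed so the first nonzero
  coordinate is positive. The closed-form linear-trend direction is
  kept in the test suite as an independent cross-check, not as the
  implementation.
* **IRLS.** `stats::glm.fit` with starting means
  $N \cdot \sum D / \sum N$ (equivalent to initializing the intercept
  at the log crude rate with zero effects), relative deviance tolerance
  $10^{-10}$, cap 100 iterations; non-convergence raises
  `apcie_convergence_error` carrying the last deviance.
* **Deviance.** $2\sum[D\ln(D/\hat D) - (D - \hat D)]$ with the $D=0$
  term defined as $2\hat D$; zero-death cells are legal inputs and no
  continuity correction is applied.
* **Fit statistics.** $\mathrm{BIC} = \mathrm{deviance} - (n -
  \mathrm{rank})\ln n$: this is the convention under which a deviance
  of 1.246 on 78 cells at rank 34 gives −190.449, so it is treated as
  normative. The per-observation AIC is $(-2\ell + 2k)/n$ with
  $k = \mathrm{rank} + 1$ on the full Poisson log-likelihood; other AIC
  conventions in circulation differ by data-dependent constants that
  cannot be pinned down from summary statistics alone, so the raw
  log-likelihood is reported too.
* **No standard errors.** The fit object reserves no fields for
  standard errors or confidence bands; IE inference is deliberately out
  of scope.

## Effect post-processing

`numerical_diff()` differences an effect curve, labelling the change
from $t$ to $t+1$ at $t$ (the convention used when the change curve is
plotted against the effect curve). `relative_risk()`,
`percent_decline()`, `net_change()` and `annualized_change()` implement
the usual summary arithmetic on the log-rate scale; machine outputs
keep full precision and only report-style summaries round risk ratios
to two decimals. Narrative "phase" labels (e.g. a gradual versus rapid
decline era) are accepted purely as plot annotations supplied by the
analyst — no change-point algorithm is included, and none is implied.

## The synthetic-data generator

`sim_config()` + `make_true_params()` + `simulate_table()` generate
Poisson Lexis tables with known ground truth so every stage is testable
without external mortality data.

* **Effect shapes.** Each dimension's true effects are a centred
  Gaussian random walk (innovation scale `effect_scale`, default 0.1
  log-rate units per category step). A random walk, unlike white noise,
  produces smooth curves comparable to estimated age/period/cohort
  effect series, and keeps differentiation output well behaved.
* **Baseline.** Default intercept $\ln(10^{-4})$, the middle of the
  rate range typical of female breast-cancer mortality.
* **Study emulation.** `emulate_study = TRUE` reproduces the canonical
  layout: 13 age groups 20–84 × annual years 1990–2015, per-cell
  person-years $3\times 10^{7}$ (the order of a national female 5-year
  age-group population), and a per-year offset absorbed into the period
  effects that pins the *expected* crude rate of each year to the
  geometric path from 6.83 to 12.07 per 100,000. The calibration is
  exact in expectation — `expected_counts()` reproduces the endpoints
  to machine precision — while realized tables scatter around it with
  Poisson noise.
* **Seeding.** One integer seed drives everything: the parameter draw
  uses `set.seed(seed)` and the Poisson noise `set.seed(seed + 1)`, so
  a full experiment is reproducible from one number and noise can be
  varied while the truth is held fixed.

What the generator does *not* emulate: overdispersion, age
misreporting, coverage error, population projection, or any secular
structure beyond additive APC effects plus the crude-rate calibration.
Passing recovery tests therefore demonstrate correctness of the
estimator under its own model, not robustness of APC conclusions on
real vital-statistics data — in particular, the annual-resolution
emulated table is richer than the 6-period model fitted to it, so such
fits legitimately show large deviances.

## Problem sizes used by the tests

Recovery experiments use an A = 5 × P = 4 grid with $10^{8}$
person-years per cell and a baseline rate of $10^{-3}$, giving roughly
$10^{5}$ expected deaths per cell so that Monte-Carlo error (about
0.003 on the log scale even for the single-cell corner cohorts) sits
well inside the 0.01 acceptance band. The null-structure check uses
$10^{9}$ person-years at rate $10^{-4}$ for the same reason. The
mean-recovery property uses 1000 replicates of a 3 × 3 grid; the
null-space sweep covers every grid up to 10 × 10. The whole suite runs
in a few seconds on one core.

## Known limitations

* The IE constraint does not "solve" the identification problem; it
  selects one representative, and linear-trend statements inherit that
  choice. Cross-method comparison (drift parameterizations, estimable
  functions) is out of scope.
* The first and last cohort effects are each informed by a single grid
  cell and are the least stable quantities in any APC fit; the
  simulation tests show exactly this through their wider Monte-Carlo
  spread.
* No standard errors, no overdispersion handling, no age
  standardization, no interpolation of missing cells: incomplete grids
  are an error, not an imputation problem.
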