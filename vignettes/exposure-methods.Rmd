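---
title: "Methods: spatial ozone exposure estimation and lung-function association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial ozone exposure estimation and lung-function association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ozonelung)
```

## The problem

Epidemiological studies of ambient ozone usually assign each participant
the concentration measured at a fixed monitor, although people live between
monitors and the pollutant field varies smoothly in space. This package
implements the standard ladder of exposure-estimation methods — network
averaging, nearest monitor, inverse distance weighting (IDW), and ordinary
kriging — together with the machinery needed to evaluate them
(leave-one-monitor-out cross-validation) and to carry their output into an
age-stratified health model for spirometric lung function (FVC and FEV1).
All coordinates are planar kilometres: at the spatial scale targeted here
(a coastal industrial bay a few tens of km across) Euclidean distance on a
local projection is accurate and no geodesy is needed.

## Daily exposure metric

The health-relevant summary of hourly ozone is the **daily maximum 8-hour
moving average**: the largest of the 17 means of 8 consecutive hours that
fit inside a calendar day (window starts at hours 0–16). Confining windows
to the calendar day is what makes the window count 17; a trailing
cross-midnight variant would have 24 windows and blur the assignment of a
day's exposure to a single date. Missing hours are handled by
regulatory-style completeness rules, chosen because monitoring data
conventions, not the health model, govern them:

* a window is valid if **≥ 6 of its 8 hours** are present (mean over the
  present hours; no imputation),
* a day is valid if **≥ 13 of the 17 windows** are valid; otherwise the
  monitor-day is missing and is dropped — never imputed — downstream.

## Interpolation methods

For a day with monitor values \(z(s_i)\) and a target residence \(s_0\):

* **Simple averaging** assigns every subject the arithmetic mean of all
  reporting monitors. It is spatially flat and serves as the baseline.
* **Nearest monitor** assigns the value of the closest reporting monitor.
  Exact distance ties are broken by the lowest monitor id so results are
  deterministic.
* **IDW** uses weights \(\lambda_i \propto 1/d_i^p\) with **p = 1 by
  default**. Power 2 is the more common GIS convention, but the plain
  \(1/d\) weighting is the variant this pipeline is built around; the
  exponent is exposed as an argument. A point within \(10^{-9}\) km of a
  monitor receives that monitor's value exactly (the weight would
  otherwise overflow).
* **Ordinary kriging** solves the semivariogram-based best-linear-unbiased
  prediction system with the unbiasedness constraint
  \(\sum_i \lambda_i = 1\), using a **spherical** semivariogram
  \(\gamma(h) = c_0 + c_1(1.5\,h/a - 0.5\,(h/a)^3)\) for \(h \le a\) and
  \(c_0 + c_1\) beyond the range \(a\). Kriging also yields a prediction
  variance. Unlike the first three methods, kriging may extrapolate
  outside the range of the day's monitor values; that is expected
  behaviour, not an error.

Monitors missing on a day are dropped from that day's system. With a
single reporting monitor all four methods collapse to its value (kriging
and IDW fall back to the nearest-value rule there).

### Variogram estimation

The empirical semivariogram uses the classical Matheron estimator over
monitor pairs binned by separation: **6 equal-width bins on
(0, max_lag]** with **max_lag = half the network diameter** by default,
both standard geostatistical practice for sparse networks. The spherical
model is fit by weighted least squares with the per-bin pair counts as
weights. For a fixed range the model is linear in \((c_0, c_1)\), so those
are profiled out in closed form with nonnegativity enforced on the
boundary; the range is found by a 25-point multistart grid over
\((0, 2\,\text{max\_lag}]\) followed by bounded `nlminb` refinement. This
profiled search has no local-minimum trouble on noiseless forward-model
bins (the tests require recovery to 1e-4 relative there).

A 10-monitor network yields only 45 pairs per day, so per-day fits can
fail (fewer than 3 non-empty bins, or no pairs within max_lag). The
**fallback chain** is: daily fit → pooled all-days fit → pure nugget at
the pooled sample variance. The chain keeps every pipeline run total; the
number of fallback days is recorded on the prediction object and in the
pipeline log. A `variogram_policy("pooled")` short-circuits to the pooled
fit, which is markedly faster in replicate studies and appropriate when
the field's spatial structure is assumed stable over days.

### Numerical edge cases

* A **flat fitted model** (\(c_0 = c_1 = 0\), which arises on a constant
  panel where every empirical semivariance is zero) makes the kriging
  matrix singular. Any weights summing to one are then optimal; the
  implementation returns the symmetric equal-weight solution — the network
  mean with zero variance — which is also the pure-nugget limit.
* A numerically singular system is retried once with a diagonal ridge of
  \(10^{-10}(c_0 + c_1)\); if still singular, a degenerate-geometry error
  is raised.
* With \(c_0 = 0\) kriging is an exact interpolator: at a monitor location
  the prediction is forced to that monitor's value with variance 0,
  avoiding round-off at distance \(\approx 0\).

## Cross-validation

Each monitor in turn is withheld; the remaining monitors predict at its
location for every day, and the measured/predicted pairs are scored by

\[ \mathrm{RMSE} = \sqrt{\tfrac1p \sum (x_{meas} - x_{pred})^2}, \qquad
   \mathrm{COD} = \sqrt{\tfrac1p \sum
   \left(\tfrac{x_{meas} - x_{pred}}{x_{meas} + x_{pred}}\right)^2}. \]

Both include the square root — COD is then bounded in [0, 1] with 0 for
identical series, which is the defining property of the statistic. Pairs
with zero sum (possible only if both values are exactly 0 ppb) are dropped
with a recorded count rather than erroring. For kriging the variogram is
refit **without the withheld monitor**, so the excluded station cannot
leak into its own prediction. Scores are pooled over all monitor-day pairs
at once, and per-monitor rows are reported alongside; pooling convention
matters little for balanced panels but both views are emitted.

## Lag assembly and IQR scaling

Six lag structures relative to the test date: 0, 1, 2 days, and the
averages 0–1, 1–2, 0–2 days. Completeness follows the least-surprising
rule: single-day lags need that day, two-day averages need both days, and
the three-day average tolerates one missing day (mean of the two present).
Regression effects are reported per **interquartile range** of exposure
(linear-interpolation quantiles, R type 7, stated in output headers since
quantile conventions differ). By default one pooled IQR — computed over
all methods and lags together — scales the whole grid, mirroring the
common practice of quoting a single IQR per pollutant; per-cell IQRs are
available by option.

## Health association model

OLS of FVC or FEV1 (litres) on assigned exposure (ppb) plus covariates.
The default adjustment set — **age, sex, height, weight** — is the
standard spirometry set; it is configurable because adjustment sets in
this literature are rarely identical. Fits are run for every outcome ×
method × lag × age-group cell (strata 9–14, 15–64, ≥ 65, plus All: 192
cells with 2 outcomes, 4 methods, 6 lags). Per-cell failures (too few
complete cases, constant exposure, rank deficiency) are reported as `NA`
rows with the error message attached, never aborting the grid. p-values
are raw, flagged at 0.05 and 0.001; with 192 correlated tests a
multiplicity correction would be defensible, so a Benjamini–Hochberg
column is emitted for the reader, but flags follow the raw convention this
analysis style uses.

## The synthetic-data generator

The generator emulates the study conditions the pipeline targets, and its
defaults are fixed to them:

* **Network**: 10 monitors uniform on a 30 km square (a coastal-bay-scale
  domain; about 0.01 monitor/km²).
* **Daily field**: each day, a Gaussian random field with spherical
  covariance (default nugget 5, partial sill 100 ppb², range 15 km) drawn
  jointly at monitors and residences, added to a regional AR(1) daily mean
  (mean 30 ppb, innovation SD 10 ppb, coefficient 0.6). The nugget acts as
  independent site-day noise.
* **Hours**: the daily level plus a fixed zero-mean sinusoid peaking at
  15:00 (amplitude 15 ppb) plus N(0, 2 ppb) noise, truncated at 0 ppb
  (concentrations are nonnegative). Nothing is claimed about real
  within-day chemistry — only the daily max 8-h metric matters downstream,
  and the sinusoid gives it a realistic mean around 42 ppb (level + ~0.82
  × amplitude).
* **Cohort**: 2283 subjects split 200/1419/664 across the strata, with
  stratum-plausible ages, sex ratios, heights and weights; test dates
  uniform over days 3..n so lags 0–2 always exist. Lung function is
  stratum baseline + linear covariate terms + *effect slope × true
  exposure* + correlated Gaussian noise (SD 0.30 L), where the true
  exposure is the 0–2-day average of the latent field value at the
  residence. Default slopes: −0.0075 (FVC) and −0.0070 (FEV1) L/ppb in
  children, −0.0035 L/ppb on FEV1 in the elderly, 0 elsewhere — i.e. a
  child-concentrated deficit of roughly −0.13 L per ~17 ppb IQR.
  Baselines are set so stratum outcome means land near 2.26/3.23/2.39 L
  (FVC); they are calibration targets only, not an acceptance surface.

All randomness flows from one master seed through named substreams
(network, residences, field, hourly, cohort), so identical configs give
bit-identical output and enlarging the cohort does not perturb the monitor
placement. The `true_exposure_ppb` column and the ground-truth matrix make
parameter recovery checkable: with zero noise the injected slope is
recovered exactly by OLS, and with noise the 95% CI should cover it at
nominal rate.

**What the generator does not emulate**: real topography and land use,
NOx/VOC photochemistry, meteorology, seasonality beyond the AR(1) mean,
time-activity patterns (everyone is exposed at home), and
spirometry-protocol error structure. Tests passing on this generator show
the *machinery* is correct and well calibrated; they do not validate any
substantive claim about real populations.

## Problem sizes used by the test suite

Simulation-based checks run at sizes chosen to make Monte Carlo error
small relative to the margins being tested while keeping the suite quick:
50 leave-one-out replicates of 30-day, 10-monitor panels for the method
ordering (smooth field, range ≈ half the network diameter, moderate
nugget — conditions under which spatial interpolation should help);
500 pooled days for variogram recovery (range required within 30%);
500 null replicates (n = 120) for type-I calibration and 200 replicates
(n = 600) for CI coverage; and a 900-subject, 60-day end-to-end run with a
child-only slope of −0.010 L/ppb for the stratified-pattern check. The
acceptance script runs the full default scale (2283 subjects, 365 days).

## Known limitations

* Kriging assumes an unknown constant mean and isotropic,
  second-order-stationary residuals; no universal kriging, anisotropy, or
  alternative variogram forms (Gaussian, exponential).
* The per-day variogram fit on 45 pairs is noisy by construction; the
  fallback chain trades variance for bias toward the pooled structure.
* The health model is plain OLS per cell — no mixed effects, splines, or
  case-crossover designs — and exposure measurement error from
  interpolation attenuates slopes; effect estimates on interpolated
  exposure are therefore expected to be smaller in magnitude than the
  injected truth.
* COD treats 0 + 0 pairs as undefined; they are dropped, which is
  immaterial for strictly positive ozone but worth knowing for other uses.
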