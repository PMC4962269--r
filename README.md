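# ozonelung

Exposure misclassification is a central worry when relating ambient air
pollution to health outcomes: most cohorts are assigned the value of one
nearby monitor, which ignores the spatial structure of the pollutant field.
`ozonelung` implements, as a tested and reusable R pipeline, the full chain
from hourly ozone measurements at a sparse monitor network to age-stratified
lung-function effect estimates at residential locations — the workflow used
in spatial-interpolation exposure-assessment studies of industrial coastal
areas. It is aimed at environmental epidemiologists and exposure scientists
who want to compare interpolation choices on the same cohort, and at
methodologists who need a fully synthetic test bed with known injected
effects.

## What it computes

**Daily metric.** Hourly ozone is reduced to the regulatory-style daily
maximum 8-hour moving average: the largest of the 17 within-day window means

```
M_d = max over s = 0..16 of (1/8) * sum_{h=s}^{s+7} z_d(h)
```

with completeness rules (a window needs ≥ 6 of its 8 hours, a day needs
≥ 13 of the 17 windows).

**Four exposure-estimation methods.** For each day, ozone at a residence
`s0` is estimated from monitor values `z(si)` by

1. *simple averaging* — the network mean, identical for all subjects;
2. *nearest monitor* — `z(s_nearest)` (Euclidean distance, km);
3. *inverse distance weighting* — `Σ λi z(si)` with `λi ∝ 1/di` (power 1,
   configurable);
4. *ordinary kriging* — BLUP weights solving the augmented system
   `Γ λ + μ1 = γ0, Σ λi = 1`, with `γ(h)` a spherical semivariogram
   `γ(h) = c0 + c1 (1.5 h/a − 0.5 (h/a)³)` fit to the empirical (Matheron)
   semivariogram by pair-count-weighted least squares.

**Validation.** Leave-one-monitor-out cross-validation scored by
`RMSE = sqrt(mean((x_meas − x_pred)²))` and the coefficient of divergence
`COD = sqrt(mean(((x_meas − x_pred)/(x_meas + x_pred))²))` (0 = identical
series, 1 = maximal divergence).

**Health model.** Exposures are assembled for six lags (0, 1, 2 days and
the 0–1, 1–2, 0–2-day averages relative to each subject's lung-function
test date) and entered in OLS regressions of FVC and FEV1 (litres) adjusted
for age, sex, height and weight, stratified by age group (9–14, 15–64,
≥ 65, All). Effects are reported per interquartile-range increase in ozone
with Wald 95% CIs.

Because no real monitoring or cohort data are distributed, a synthetic-data
module simulates the whole study: spatially correlated daily ozone fields
with a configurable spherical variogram, an AR(1) regional mean and a fixed
diurnal cycle, plus a cohort whose lung function carries known injected
ozone slopes — so every stage can be checked against ground truth.

## Worked example

```r
library(ozonelung)

cfg   <- sim_config(n_days = 60, n_subjects = 500, seed = 1)
study <- simulate_study(cfg)                 # monitors, hourly ozone, cohort
panel <- build_daily_panel(study$hourly)     # daily max 8-h metric
panel
#> <daily_panel> 10 monitor(s) x 60 day(s), 600/600 cells valid
#>   dates 2009-01-01 .. 2009-03-01; ppb range 0.0 .. 89.2

cv <- crossval_summary(panel, study$network, policy = variogram_policy("daily"))
subset(cv, monitor_id == "ALL")
#>     method monitor_id n_pairs rmse_ppb   cod
#>    nearest        ALL     600    10.45 0.173
#>        idw        ALL     600     9.19 0.145
#>    kriging        ALL     600     9.09 0.146
```

Kriging reconstructs the withheld monitors best, inverse distance weighting
is close behind, and the single nearest monitor is clearly worse — the
ordering the cross-validation stage is designed to expose.

```r
loc <- study$cohort[, c("subject_id", "x_km", "y_km")]
assignments <- do.call(rbind, lapply(
  c("simple_average", "nearest", "idw", "kriging"),
  function(m) assign_exposure(
    predict_all(panel, study$network, loc, method = m), study$cohort)))

grid <- run_full_grid(study$cohort, assignments)
subset(grid, outcome == "fvc_l" & method == "kriging" & lag == "0-2d",
       c(age_group, n, beta_per_iqr, ci_low, ci_high, p_value))
#>  age_group   n beta_per_iqr ci_low ci_high p_value
#>       9-14  44      -0.1367 -0.301   0.028    0.10
#>      15-64 311      -0.0057 -0.063   0.052    0.85
#>       >=65 145       0.0553 -0.023   0.134    0.17
#>        All 500       0.0322 -0.020   0.085    0.23
```

The generator injects a negative ozone slope on lung function in children
only; the kriging 0–2-day cell shows the correspondingly largest negative
per-IQR estimate in the 9–14 stratum (−0.14 L per IQR here; with only 44
children at this demonstration scale the CI still crosses zero — the full
2283-subject default makes it significant).

An end-to-end run that writes every stage to CSV (with a manifest of row
counts and checksums) is

```r
run_pipeline(pipeline_config(out_dir = "run1"))
```

or, from a shell, `Rscript inst/scripts/ozone-pipeline.R run-all --config
config.yml`.

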