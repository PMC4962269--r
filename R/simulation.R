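#' Simulation configuration
#'
#' Settings for the synthetic monitoring-and-cohort generator, defaulting to
#' the study conditions the pipeline targets: 10 monitors on a 30 km
#' coastal-bay-scale square, a year of hourly ozone with a mid-afternoon
#' diurnal peak and spatially correlated day-to-day fields, and a cohort of
#' 2283 subjects split 200/1419/664 across the 9-14, 15-64 and >=65 age
#' strata, with a negative ozone effect on lung function injected in
#' children (and a weaker one on FEV1 in the elderly).
#'
#' @param n_monitors number of monitoring stations (default 10).
#' @param extent_km side of the square study domain (km, default 30).
#' @param n_days number of simulated days (default 365; must be >= 3 so
#'   lags 0-2 resolve).
#' @param variogram_true [variogram_model()] of the daily spatial field
#'   (ppb^2 / km); default nugget 5, partial sill 100, range 15 km.
#' @param diurnal_amplitude amplitude of the fixed sinusoidal within-day
#'   profile (ppb, default 15; peak at 15:00).
#' @param regional_mean long-run regional daily ozone level (ppb, default
#'   30; the daily max 8-h metric then averages around 42 ppb).
#' @param regional_sd innovation SD of the regional daily mean (ppb).
#' @param ar1_coefficient AR(1) coefficient of the regional daily mean,
#'   |value| < 1.
#' @param hourly_noise_sd SD of independent hourly measurement noise (ppb).
#' @param n_subjects cohort size (default 2283).
#' @param age_fractions proportions of children/adults/elderly summing to 1.
#' @param effect_slopes list with numeric elements `fvc_l` and `fev1_l`,
#'   each length 3 (children, adults, elderly): true change in litres per
#'   1 ppb of the 0-2-day average latent exposure.
#' @param outcome_noise_sd residual SD of the lung-function outcomes (L).
#' @param duplicate_policy `"jitter"` (default) nudges coincident locations
#'   by 1e-6 km when the field covariance is singular; `"fail"` errors.
#' @param seed master integer seed; all draws derive from it through named
#'   substreams so e.g. changing the cohort size does not perturb the
#'   ozone field.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_monitors = 10,
                       extent_km = 30,
                       n_days = 365,
                       variogram_true = variogram_model(5, 100, 15),
                       diurnal_amplitude = 15,
                       regional_mean = 30,
                       regional_sd = 10,
                       ar1_coefficient = 0.6,
                       hourly_noise_sd = 2,
                       n_subjects = 2283,
                       age_fractions = c(200, 1419, 664) / 2283,
                       effect_slopes = list(
                         fvc_l = c(-0.0075, 0, 0),
                         fev1_l = c(-0.0070, 0, -0.0035)),
                       outcome_noise_sd = 0.30,
                       duplicate_policy = c("jitter", "fail"),
                       seed = 1L) {
  duplicate_policy <- match.arg(duplicate_policy)
  cfg <- list(n_monitors = as.integer(n_monitors), extent_km = extent_km,
              n_days = as.integer(n_days), variogram_true = variogram_true,
              diurnal_amplitude = diurnal_amplitude,
              regional_mean = regional_mean, regional_sd = regional_sd,
              ar1_coefficient = ar1_coefficient,
              hourly_noise_sd = hourly_noise_sd,
              n_subjects = as.integer(n_subjects),
              age_fractions = age_fractions,
              effect_slopes = effect_slopes,
              outcome_noise_sd = outcome_noise_sd,
              duplicate_policy = duplicate_policy,
              seed = as.integer(seed))
  if (cfg$n_monitors < 1L || cfg$n_subjects < 1L || cfg$n_days < 1L)
    stop_ozl("counts must be >= 1", "ozl_invalid_config")
  if (cfg$extent_km <= 0)
    stop_ozl("extent_km must be positive", "ozl_invalid_config")
  if (!inherits(cfg$variogram_true, "variogram_model"))
    stop_ozl("variogram_true must be a variogram_model", "ozl_invalid_config")
  if (abs(cfg$ar1_coefficient) >= 1)
    stop_ozl("|ar1_coefficient| must be < 1", "ozl_invalid_config")
  if (length(cfg$age_fractions) != 3L ||
      abs(sum(cfg$age_fractions) - 1) > 1e-9 || any(cfg$age_fractions < 0))
    stop_ozl("age_fractions must be three nonnegative proportions summing to 1",
             "ozl_invalid_config")
  if (!all(c("fvc_l", "fev1_l") %in% names(cfg$effect_slopes)) ||
      any(lengths(cfg$effect_slopes[c("fvc_l", "fev1_l")]) != 3L))
    stop_ozl("effect_slopes needs fvc_l and fev1_l, each of length 3",
             "ozl_invalid_config")
  if (cfg$diurnal_amplitude < 0 || cfg$hourly_noise_sd < 0 ||
      cfg$regional_sd < 0 || cfg$outcome_noise_sd < 0)
    stop_ozl("scale parameters must be nonnegative", "ozl_invalid_config")
  class(cfg) <- "sim_config"
  cfg
}

# fixed diurnal profile: zero-mean sinusoid peaking at 15:00
diurnal_profile <- function() -cos(2 * pi * ((0:23) - 3) / 24)

# max 8-h-window mean of the diurnal profile: converts a daily field level
# into the latent daily max 8-h metric (before hourly noise)
diurnal_max8_factor <- function() {
  p <- diurnal_profile()
  max(vapply(1:17, function(s) mean(p[s:(s + 7)]), numeric(1)))
}

study_origin <- as.Date("2009-01-01")

#' Generate a synthetic monitor network
#'
#' Stations uniformly placed on the square study domain; deterministic for
#' a given config seed.
#'
#' @param config a [sim_config()].
#' @return a [monitor_network()] with ids `M01`, `M02`, ...
#' @export
generate_monitor_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "network"))
  n <- config$n_monitors
  monitor_network(sprintf("M%02d", seq_len(n)),
                  x_km = stats::runif(n, 0, config$extent_km),
                  y_km = stats::runif(n, 0, config$extent_km))
}

#' Generate synthetic residential locations
#'
#' @param config a [sim_config()].
#' @return data.frame `subject_id`, `x_km`, `y_km` (uniform on the domain).
#' @export
generate_residences <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "residences"))
  n <- config$n_subjects
  data.frame(subject_id = sprintf("S%05d", seq_len(n)),
             x_km = stats::runif(n, 0, config$extent_km),
             y_km = stats::runif(n, 0, config$extent_km),
             stringsAsFactors = FALSE)
}

# joint daily field draw at monitor + residence locations:
# regional AR(1) mean + Gaussian random field with spherical covariance
# (nugget as independent site-day noise), truncated later at the hourly step
simulate_daily_latent <- function(network, residences, config) {
  vt <- config$variogram_true
  x <- c(network$x_km, residences$x_km)
  y <- c(network$y_km, residences$y_km)
  d <- cross_dist(x, y, x, y)
  Sigma <- spherical_cov(d, vt)
  diag(Sigma) <- vt$psill + vt$nugget
  L <- try(chol(Sigma), silent = TRUE)
  if (inherits(L, "try-error")) {
    if (config$duplicate_policy == "fail")
      stop_ozl("singular field covariance (duplicate locations?); set duplicate_policy = 'jitter'",
               "ozl_degenerate_geometry")
    ridge <- 1e-8 * (vt$psill + vt$nugget + 1)
    L <- chol(Sigma + diag(ridge, nrow(Sigma)))
  }

  set.seed(substream_seed(config$seed, "field"))
  n_loc <- length(x); n_days <- config$n_days
  # regional AR(1) daily mean, initialised at stationarity
  innov <- stats::rnorm(n_days, 0, config$regional_sd)
  m <- numeric(n_days)
  phi <- config$ar1_coefficient
  m[1] <- config$regional_mean + innov[1] / sqrt(1 - phi^2)
  for (t in seq_len(n_days)[-1])
    m[t] <- config$regional_mean + phi * (m[t - 1] - config$regional_mean) + innov[t]
  z <- crossprod(L, matrix(stats::rnorm(n_loc * n_days), n_loc, n_days))
  sweep(z, 2, m, "+")
}

#' Simulate hourly ozone at monitors and latent exposure at residences
#'
#' Each day a Gaussian random field with the configured spherical
#' covariance is drawn jointly at the monitor and residence locations and
#' added to a regional AR(1) daily mean. Hourly monitor values are the
#' daily level shaped by a fixed sinusoidal diurnal profile peaking at
#' 15:00 plus independent hourly noise, truncated at 0 ppb. The ground
#' truth records, for every residence and day, the latent daily max
#' 8-h-equivalent value (daily level + diurnal contribution, no noise) —
#' the quantity the interpolation stage tries to recover.
#'
#' @param network a [monitor_network()].
#' @param residences data.frame with `x_km`, `y_km` (and optionally
#'   `subject_id`), possibly zero rows.
#' @param config a [sim_config()].
#' @return list with `hourly` (long data.frame monitor_id/date/hour/ppb),
#'   `daily_monitor_latent` (monitors x days matrix of latent daily metric
#'   values), and `ground_truth` (list: `true_daily_exposure`
#'   subjects x days matrix, `dates`, `residences`,
#'   `true_effect_slopes`).
#' @export
simulate_ozone_field <- function(network, residences, config) {
  stopifnot(inherits(config, "sim_config"), inherits(network, "monitor_network"))
  residences <- as.data.frame(residences)
  n_mon <- nrow(network); n_res <- nrow(residences)
  z <- simulate_daily_latent(network, residences, config)
  dmax8 <- config$diurnal_amplitude * diurnal_max8_factor()
  dates <- study_origin + seq_len(config$n_days) - 1L

  z_mon <- z[seq_len(n_mon), , drop = FALSE]
  rownames(z_mon) <- network$id
  daily_latent <- pmax(z_mon + dmax8, 0)
  colnames(daily_latent) <- as.character(dates)

  set.seed(substream_seed(config$seed, "hourly"))
  prof <- config$diurnal_amplitude * diurnal_profile()
  n_days <- config$n_days
  # hourly array: monitor x day base level + profile + noise
  base <- z_mon[rep(seq_len(n_mon), each = 24), , drop = FALSE]
  hourly_vals <- base + prof +
    stats::rnorm(length(base), 0, config$hourly_noise_sd)
  hourly_vals <- pmax(hourly_vals, 0)
  hourly <- data.frame(
    monitor_id = rep(rep(network$id, each = 24), times = n_days),
    date = rep(dates, each = 24 * n_mon),
    hour = rep(0:23, times = n_mon * n_days),
    ppb = as.vector(hourly_vals),
    stringsAsFactors = FALSE)

  gt <- NULL
  if (n_res > 0) {
    true_daily <- z[n_mon + seq_len(n_res), , drop = FALSE] + dmax8
    rownames(true_daily) <- residences$subject_id %||%
      sprintf("S%05d", seq_len(n_res))
    colnames(true_daily) <- as.character(dates)
    gt <- list(true_daily_exposure = true_daily, dates = dates,
               residences = residences,
               true_effect_slopes = config$effect_slopes)
  }
  list(hourly = hourly, daily_monitor_latent = daily_latent,
       dates = dates, ground_truth = gt)
}

#' Simulate a daily metric panel directly
#'
#' Draws the latent daily fields at the monitors only and returns them as a
#' [daily_panel()], bypassing the hourly layer. Convenient for studying the
#' interpolation and cross-validation stages on their own.
#'
#' @inheritParams simulate_ozone_field
#' @return a [daily_panel()] (values truncated at 0 ppb).
#' @export
simulate_daily_panel <- function(network, config) {
  z <- simulate_daily_latent(network, data.frame(x_km = numeric(0), y_km = numeric(0)),
                             config)
  rownames(z) <- network$id
  dmax8 <- config$diurnal_amplitude * diurnal_max8_factor()
  dates <- study_origin + seq_len(config$n_days) - 1L
  daily_panel(pmax(z + dmax8, 0), dates)
}

# stratum parameter tables loosely matched to the cohort the generator
# emulates (three age strata; spirometry declines in the elderly)
stratum_params <- function() {
  data.frame(
    group = c("9-14", "15-64", ">=65"),
    male_prob = c(0.475, 0.465, 0.345),
    height_mean = c(145.4, 162.3, 155.2), height_sd = c(8.5, 8.6, 8.5),
    weight_mean = c(37.8, 57.4, 57.1), weight_sd = c(9.9, 11.6, 9.9),
    fvc_target = c(2.26, 3.23, 2.39), fev1_target = c(1.92, 2.69, 1.82),
    age_slope_fvc = c(0.05, -0.010, -0.015),
    age_slope_fev1 = c(0.04, -0.012, -0.018),
    age_center = c(12, 40, 74),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort with a known injected ozone effect
#'
#' Ages are drawn within the three strata according to the configured
#' fractions; sex, height and weight come from stratum-plausible normal
#' distributions; test dates are uniform over days 3..n_days so that lags
#' 0-2 always exist. Lung function is built as
#' stratum baseline + covariate terms + effect_slope x true exposure +
#' correlated Gaussian noise, where the true exposure is the 0-2-day
#' average of the latent daily value at the subject's residence. With zero
#' slopes and zero noise the outcome equals the deterministic baseline +
#' covariate part exactly, which is what makes parameter-recovery tests
#' possible.
#'
#' @param config a [sim_config()].
#' @param ground_truth the `ground_truth` element of
#'   [simulate_ozone_field()] output (must cover all subjects).
#' @return cohort data.frame: `subject_id`, `x_km`, `y_km`, `test_date`,
#'   `age`, `age_group`, `sex`, `height_cm`, `weight_kg`, `fvc_l`,
#'   `fev1_l`, and the per-subject `true_exposure_ppb` used in the outcome
#'   model.
#' @export
generate_cohort <- function(config, ground_truth) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_days < 3L)
    stop_ozl("n_days must be >= 3 so lags 0-2 resolve", "ozl_invalid_config")
  td <- ground_truth$true_daily_exposure
  n <- config$n_subjects
  if (is.null(td) || nrow(td) < n)
    stop_ozl("ground truth does not cover all subjects", "ozl_invalid_config")

  set.seed(substream_seed(config$seed, "cohort"))
  counts <- round(n * config$age_fractions)
  counts[3] <- n - counts[1] - counts[2]
  pars <- stratum_params()
  grp <- rep(pars$group, times = counts)

  age <- numeric(n)
  idx <- split(seq_len(n), rep(1:3, times = counts))
  age[idx[[1]]] <- sample(9:14, counts[1], replace = TRUE)
  age[idx[[2]]] <- sample(15:64, counts[2], replace = TRUE)
  age[idx[[3]]] <- pmin(95, pmax(65, round(stats::rnorm(counts[3], 74.2, 5.6))))

  g <- match(grp, pars$group)
  sex <- ifelse(stats::runif(n) < pars$male_prob[g], "male", "female")
  height <- stats::rnorm(n, pars$height_mean[g], pars$height_sd[g])
  weight <- pmax(15, stats::rnorm(n, pars$weight_mean[g], pars$weight_sd[g]))
  day_index <- sample(3:config$n_days, n, replace = TRUE)

  # true exposure: 0-2-day average of the latent residence value
  true_expo <- (td[cbind(seq_len(n), day_index)] +
                td[cbind(seq_len(n), day_index - 1L)] +
                td[cbind(seq_len(n), day_index - 2L)]) / 3

  expected_expo <- config$regional_mean +
    config$diurnal_amplitude * diurnal_max8_factor()
  covar_fvc <- 0.030 * (height - pars$height_mean[g]) +
    0.004 * (weight - pars$weight_mean[g]) +
    0.12 * (sex == "male") +
    pars$age_slope_fvc[g] * (age - pars$age_center[g])
  covar_fev1 <- 0.025 * (height - pars$height_mean[g]) +
    0.003 * (weight - pars$weight_mean[g]) +
    0.10 * (sex == "male") +
    pars$age_slope_fev1[g] * (age - pars$age_center[g])

  sl_fvc <- config$effect_slopes$fvc_l[g]
  sl_fev1 <- config$effect_slopes$fev1_l[g]
  base_fvc <- pars$fvc_target[g] - sl_fvc * expected_expo
  base_fev1 <- pars$fev1_target[g] - sl_fev1 * expected_expo

  # correlated outcome noise (shared + specific components) keeps
  # FVC >= FEV1 violations rare
  rho <- 0.8
  common <- stats::rnorm(n, 0, config$outcome_noise_sd * sqrt(rho))
  e_fvc <- common + stats::rnorm(n, 0, config$outcome_noise_sd * sqrt(1 - rho))
  e_fev1 <- common + stats::rnorm(n, 0, config$outcome_noise_sd * sqrt(1 - rho))

  fvc <- base_fvc + covar_fvc + sl_fvc * true_expo + e_fvc
  fev1 <- base_fev1 + covar_fev1 + sl_fev1 * true_expo + e_fev1
  fvc <- pmax(fvc, 0.3)
  fev1 <- pmax(pmin(fev1, fvc), 0.2 * fvc)

  res <- ground_truth$residences
  data.frame(subject_id = rownames(td)[seq_len(n)],
             x_km = res$x_km[seq_len(n)], y_km = res$y_km[seq_len(n)],
             test_date = ground_truth$dates[day_index],
             age = age, age_group = factor(grp, levels = pars$group),
             sex = sex, height_cm = height, weight_kg = weight,
             fvc_l = fvc, fev1_l = fev1,
             true_exposure_ppb = unname(true_expo),
             stringsAsFactors = FALSE)
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper producing everything the pipeline consumes: network,
#' hourly ozone, daily latent values, residences, ground truth and cohort.
#'
#' @param config a [sim_config()].
#' @return list: `network`, `hourly`, `dates`, `daily_monitor_latent`,
#'   `ground_truth`, `cohort`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  network <- generate_monitor_network(config)
  residences <- generate_residences(config)
  field <- simulate_ozone_field(network, residences, config)
  cohort <- generate_cohort(config, field$ground_truth)
  list(network = network, hourly = field$hourly, dates = field$dates,
       daily_monitor_latent = field$daily_monitor_latent,
       ground_truth = field$ground_truth, cohort = cohort, config = config)
}
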