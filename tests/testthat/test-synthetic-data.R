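test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_monitors = 0), class = "ozl_invalid_config")
  expect_error(sim_config(extent_km = -1), class = "ozl_invalid_config")
  expect_error(sim_config(ar1_coefficient = 1), class = "ozl_invalid_config")
  expect_error(sim_config(age_fractions = c(0.5, 0.5, 0.5)),
               class = "ozl_invalid_config")
  expect_error(generate_cohort(sim_config(n_days = 2),
                               list(true_daily_exposure = matrix(1, 5, 2))),
               class = "ozl_invalid_config")
})

test_that("monitor network generation is bounded, distinct and deterministic", {
  cfg <- sim_config(n_days = 3, n_subjects = 5, seed = 1)
  net <- generate_monitor_network(cfg)
  expect_equal(nrow(net), 10)
  expect_true(all(net$x_km >= 0 & net$x_km <= 30))
  expect_true(all(net$y_km >= 0 & net$y_km <= 30))
  expect_equal(anyDuplicated(net[, c("x_km", "y_km")]), 0L)
  expect_identical(net, generate_monitor_network(cfg))
  net1 <- generate_monitor_network(sim_config(n_monitors = 1, n_days = 3,
                                              n_subjects = 5))
  expect_equal(nrow(net1), 1)
})

test_that("whole-study simulation is deterministic and substreams are isolated", {
  cfg <- sim_config(n_monitors = 4, n_days = 6, n_subjects = 20, seed = 33)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$hourly, s2$hourly)
  expect_identical(s1$cohort, s2$cohort)
  # changing the cohort size must not perturb the monitor placement or the
  # hourly ozone at the monitors beyond the joint-field dimensionality
  cfg_big <- sim_config(n_monitors = 4, n_days = 6, n_subjects = 35, seed = 33)
  s3 <- simulate_study(cfg_big)
  expect_identical(s1$network, s3$network)
})

test_that("degenerate diurnal settings behave as documented", {
  cfg <- sim_config(n_monitors = 3, n_days = 4, n_subjects = 3,
                    diurnal_amplitude = 0, hourly_noise_sd = 0, seed = 2)
  net <- generate_monitor_network(cfg)
  res <- generate_residences(cfg)
  sim <- simulate_ozone_field(net, res, cfg)
  # all 24 hourly values of a day equal that day's level
  spread <- tapply(sim$hourly$ppb,
                   paste(sim$hourly$monitor_id, sim$hourly$date),
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))

  # truncation: zero regional mean, zero amplitude -> nothing below 0
  cfg0 <- sim_config(n_monitors = 3, n_days = 30, n_subjects = 3,
                     regional_mean = 0, diurnal_amplitude = 0, seed = 4)
  sim0 <- simulate_ozone_field(net, res, cfg0)
  expect_true(all(sim0$hourly$ppb >= 0))
})

test_that("simulated fields carry the configured spatial correlation structure", {
  # monitors 1 km apart must correlate more strongly day-to-day than
  # monitors far beyond the range
  cfg <- sim_config(n_monitors = 3, n_days = 300, n_subjects = 1,
                    variogram_true = variogram_model(0, 100, 10),
                    regional_sd = 0, diurnal_amplitude = 0,
                    regional_mean = 60, hourly_noise_sd = 0, seed = 6)
  net <- monitor_network(c("M01", "M02", "M03"), c(0, 1, 28), c(0, 0, 0))
  sim <- simulate_ozone_field(net, data.frame(x_km = numeric(0), y_km = numeric(0)), cfg)
  pan <- build_daily_panel(sim$hourly)
  r_near <- cor(pan$values["M01", ], pan$values["M02", ])
  r_far <- cor(pan$values["M01", ], pan$values["M03", ])
  # theoretical spherical correlations: 1 - 1.5(0.1) + 0.5(0.001) = 0.8505; 0 at 28 km
  expect_gt(r_near, r_far + 0.3)
  expect_equal(r_near, 0.8505, tolerance = 0.12)
})

test_that("empirical semivariogram of simulated daily fields matches the model", {
  cfg <- sim_config(n_monitors = 10, n_days = 550, n_subjects = 1,
                    variogram_true = variogram_model(0, 100, 10),
                    regional_sd = 0, regional_mean = 60,
                    diurnal_amplitude = 0, seed = 10)
  net <- generate_monitor_network(cfg)
  pan <- simulate_daily_panel(net, cfg)
  bins <- empirical_semivariogram(pan$values, net, n_bins = 6, max_lag = 12)
  truth <- spherical_gamma(bins$lag_km, cfg$variogram_true)
  in_range <- bins$lag_km <= 10
  expect_true(all(abs(bins$gamma[in_range] - truth[in_range]) / truth[in_range] < 0.15))
})

test_that("cohort strata, dates and outcome construction follow the config", {
  cfg <- sim_config(n_monitors = 3, n_days = 30, n_subjects = 2283, seed = 8)
  net <- generate_monitor_network(cfg)
  res <- generate_residences(cfg)
  sim <- simulate_ozone_field(net, res, cfg)
  coh <- generate_cohort(cfg, sim$ground_truth)
  counts <- table(coh$age_group)
  expect_true(all(abs(counts - c(200, 1419, 664)) <= 1))
  expect_true(all(coh$test_date >= sim$dates[3]))
  expect_true(all(coh$fvc_l >= coh$fev1_l))
  expect_true(all(coh$fvc_l > 0))

  # zero effect, zero noise: outcomes are exactly baseline + covariate terms,
  # hence independent of exposure
  cfg0 <- sim_config(n_monitors = 3, n_days = 30, n_subjects = 300,
                     effect_slopes = list(fvc_l = c(0, 0, 0), fev1_l = c(0, 0, 0)),
                     outcome_noise_sd = 0, seed = 9)
  sim0 <- simulate_ozone_field(generate_monitor_network(cfg0),
                               generate_residences(cfg0), cfg0)
  coh0 <- generate_cohort(cfg0, sim0$ground_truth)
  kids <- coh0[coh0$age_group == "9-14", ]
  fit <- lm(fvc_l ~ true_exposure_ppb + age + sex + height_cm + weight_kg,
            data = kids)
  expect_lt(abs(coef(fit)[["true_exposure_ppb"]]), 1e-10)
})

test_that("injected slope is recovered exactly from noiseless data", {
  slope <- -0.006
  cfg <- sim_config(n_monitors = 3, n_days = 30, n_subjects = 400,
                    effect_slopes = list(fvc_l = c(slope, slope, slope),
                                         fev1_l = c(slope, slope, slope)),
                    outcome_noise_sd = 0, seed = 12)
  sim <- simulate_ozone_field(generate_monitor_network(cfg),
                              generate_residences(cfg), cfg)
  coh <- generate_cohort(cfg, sim$ground_truth)
  kids <- coh[coh$age_group == "9-14", ]
  fit <- lm(fvc_l ~ true_exposure_ppb + age + sex + height_cm + weight_kg,
            data = kids)
  expect_equal(coef(fit)[["true_exposure_ppb"]], slope, tolerance = 1e-7)
})
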