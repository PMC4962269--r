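synthetic_regression_cohort <- function(n, slope, noise_sd, seed,
                                        iqr_target = NULL) {
  set.seed(seed)
  expo <- runif(n, 20, 80)
  age <- sample(9:14, n, replace = TRUE)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  height <- rnorm(n, 150, 8)
  weight <- rnorm(n, 40, 8)
  fvc <- 2.3 + 0.03 * (height - 150) + 0.1 * (sex == "male") +
    slope * expo + rnorm(n, 0, noise_sd)
  list(cohort = data.frame(subject_id = seq_len(n), age = age, sex = sex,
                           height_cm = height, weight_kg = weight,
                           fvc_l = fvc, fev1_l = fvc * 0.85),
       exposure = expo)
}

test_that("a noiseless injected slope is recovered exactly and scales by IQR", {
  d <- synthetic_regression_cohort(200, slope = -0.006, noise_sd = 0, seed = 1)
  # noiseless by design: summary.lm warns about the perfect fit
  est <- suppressWarnings(fit_association(d$cohort, d$exposure, outcome = "fvc_l"))
  expect_equal(est$beta_per_ppb, -0.006, tolerance = 1e-8)
  expect_equal(est$beta_per_iqr, -0.006 * est$iqr_ppb, tolerance = 1e-10)
  expect_equal(est$beta_per_iqr / est$iqr_ppb, est$beta_per_ppb)

  # scale equivariance: exposure in other units leaves beta_per_iqr unchanged
  est2 <- suppressWarnings(fit_association(d$cohort, d$exposure * 10, outcome = "fvc_l"))
  expect_equal(est2$beta_per_ppb, est$beta_per_ppb / 10, tolerance = 1e-10)
  expect_equal(est2$beta_per_iqr, est$beta_per_iqr, tolerance = 1e-8)
})

test_that("degenerate designs raise informative errors", {
  d <- synthetic_regression_cohort(50, slope = 0, noise_sd = 0.2, seed = 2)
  expect_error(fit_association(d$cohort, rep(40, 50), outcome = "fvc_l"),
               class = "ozl_degenerate_exposure")
  expect_error(fit_association(d$cohort[1:5, ], d$exposure[1:5],
                               outcome = "fvc_l"),
               class = "ozl_insufficient_data")
  # an exact copy of a covariate makes the design rank deficient
  coh <- d$cohort; coh$height2 <- coh$height_cm
  expect_error(fit_association(coh, d$exposure, outcome = "fvc_l",
                               covariates = c("age", "sex", "height_cm",
                                              "weight_kg", "height2")),
               class = "ozl_rank_deficient")
})

test_that("type-I error is calibrated near 5% under the null", {
  reps <- 400
  p <- numeric(reps)
  for (r in seq_len(reps)) {
    d <- synthetic_regression_cohort(120, slope = 0, noise_sd = 0.25,
                                     seed = 1000 + r)
    p[r] <- fit_association(d$cohort, d$exposure, outcome = "fvc_l")$p_value
  }
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.08)
})

test_that("95% CI covers the true slope at nominal rate", {
  reps <- 200
  slope <- -0.005
  cover <- logical(reps)
  for (r in seq_len(reps)) {
    d <- synthetic_regression_cohort(120, slope = slope, noise_sd = 0.25,
                                     seed = 5000 + r)
    est <- fit_association(d$cohort, d$exposure, outcome = "fvc_l")
    truth_iqr <- slope * est$iqr_ppb
    cover[r] <- est$ci_low <= truth_iqr && truth_iqr <= est$ci_high
  }
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("an irrelevant covariate barely moves the estimate", {
  deltas <- ses <- numeric(50)
  for (r in 1:50) {
    d <- synthetic_regression_cohort(150, slope = -0.004, noise_sd = 0.2,
                                     seed = 7000 + r)
    coh <- d$cohort
    set.seed(100 + r); coh$junk <- rnorm(nrow(coh))
    e1 <- fit_association(coh, d$exposure, outcome = "fvc_l")
    e2 <- fit_association(coh, d$exposure, outcome = "fvc_l",
                          covariates = c("age", "sex", "height_cm",
                                         "weight_kg", "junk"))
    deltas[r] <- abs(e2$beta_per_iqr - e1$beta_per_iqr)
    ses[r] <- e1$se_per_ppb * e1$iqr_ppb
  }
  expect_lt(mean(deltas), mean(ses))
})

test_that("the effects grid covers 192 cells and never aborts on bad cells", {
  cfg <- sim_config(n_monitors = 4, n_days = 20, n_subjects = 250, seed = 17)
  st <- simulate_study(cfg)
  pan <- daily_panel(st$daily_monitor_latent, st$dates)
  assignments <- do.call(rbind, lapply(
    c("simple_average", "nearest", "idw", "kriging"),
    function(m) assign_exposure(
      predict_all(pan, st$network, st$cohort[, c("subject_id", "x_km", "y_km")],
                  method = m, policy = variogram_policy("pooled")),
      st$cohort)))
  grid <- run_full_grid(st$cohort, assignments)
  expect_equal(nrow(grid), 2 * 4 * 6 * 4)
  expect_true(all(grid$ci_low <= grid$beta_per_iqr + 1e-12, na.rm = TRUE))
  expect_true(all(grid$beta_per_iqr <= grid$ci_high + 1e-12, na.rm = TRUE))
  # pooled IQR: a single scaling constant across the whole grid
  expect_equal(length(unique(na.omit(grid$iqr_ppb))), 1L)
  expect_true(all(grid$sig_flag %in% c("", "*", "**")))
})
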