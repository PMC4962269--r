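#' Age strata used for stratified analysis
#'
#' Children 9-14 years, adults 15-64, elderly 65 and over.
#'
#' @param age numeric ages in years (>= 9).
#' @return factor with levels `"9-14"`, `"15-64"`, `">=65"`.
#' @export
assign_age_groups <- function(age) {
  if (any(age < 9, na.rm = TRUE))
    stop_ozl("ages below 9 are outside the study strata", "ozl_invalid_config")
  cut(age, breaks = c(9, 15, 65, Inf), right = FALSE,
      labels = c("9-14", "15-64", ">=65"))
}

#' Multivariable association between ozone exposure and lung function
#'
#' Ordinary least squares of a spirometric outcome (litres) on assigned
#' ozone exposure (ppb) adjusted for covariates (by default age, sex,
#' height and weight, the standard spirometry adjustment set). The slope is
#' estimated per ppb and rescaled to the change per interquartile-range
#' increase in ozone; the 95% CI is Wald from the t distribution on the
#' residual degrees of freedom, with a two-sided p-value.
#'
#' @param cohort data.frame with the outcome and covariate columns.
#' @param exposure numeric vector of assigned exposures (ppb), aligned with
#'   `cohort` rows.
#' @param outcome outcome column name, `"fvc_l"` or `"fev1_l"`.
#' @param covariates character vector of adjustment columns present in
#'   `cohort` (factors allowed).
#' @param iqr the IQR (ppb) used for effect scaling; default the IQR of the
#'   complete-case exposures. Pass a pooled IQR to keep the scaling common
#'   across methods and lags.
#' @return one-row data.frame: `outcome`, `n`, `iqr_ppb`, `beta_per_ppb`,
#'   `se_per_ppb`, `beta_per_iqr`, `ci_low`, `ci_high` (per IQR, L),
#'   `p_value`.
#' @export
fit_association <- function(cohort, exposure,
                            outcome = c("fvc_l", "fev1_l"),
                            covariates = c("age", "sex", "height_cm", "weight_kg"),
                            iqr = NULL) {
  outcome <- match.arg(outcome)
  missing_cols <- setdiff(c(outcome, covariates), names(cohort))
  if (length(missing_cols))
    stop_ozl(paste("cohort lacks columns:", paste(missing_cols, collapse = ", ")),
             "ozl_invalid_config")
  df <- cohort[, c(outcome, covariates), drop = FALSE]
  df$.exposure <- as.numeric(exposure)
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  if (nrow(df) < 10L)
    stop_ozl("fewer than 10 complete cases", "ozl_insufficient_data")
  if (stats::sd(df$.exposure) == 0)
    stop_ozl("exposure is constant; no slope is identifiable", "ozl_degenerate_exposure")

  form <- stats::reformulate(c(".exposure", covariates), response = outcome)
  fit <- stats::lm(form, data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop_ozl(paste("design is rank deficient; aliased terms:",
                   paste(bad, collapse = ", ")), "ozl_rank_deficient")
  }
  sm <- summary(fit)$coefficients
  beta <- sm[".exposure", "Estimate"]
  se <- sm[".exposure", "Std. Error"]
  dfree <- fit$df.residual
  if (is.null(iqr)) iqr <- exposure_iqr(df$.exposure)
  tcrit <- stats::qt(0.975, dfree)
  p <- 2 * stats::pt(abs(beta / se), dfree, lower.tail = FALSE)
  data.frame(outcome = outcome, n = nrow(df), iqr_ppb = iqr,
             beta_per_ppb = beta, se_per_ppb = se,
             beta_per_iqr = beta * iqr,
             ci_low = (beta - tcrit * se) * iqr,
             ci_high = (beta + tcrit * se) * iqr,
             p_value = p, stringsAsFactors = FALSE)
}

#' Fit the full method x lag x age-group effects grid
#'
#' Runs [fit_association()] for every combination of outcome (FVC, FEV1),
#' exposure-estimation method, lag, and age group (the three strata plus
#' `"All"`): with 4 methods and 6 lags this is 96 fits per outcome, 192
#' rows in total. Effects are scaled by a single pooled IQR computed over
#' all assigned exposures (matching the convention of reporting one IQR for
#' the pollutant), or per cell. Cells whose fit fails (too few cases,
#' constant exposure) are emitted with `NA` estimates and the error message
#' in `note`, never aborting the grid. Significance flags: `*` p < 0.05,
#' `**` p < 0.001; a Benjamini-Hochberg adjusted p-value is also reported
#' but not used for flagging.
#'
#' @param cohort cohort data.frame with `subject_id`, `age`, outcomes and
#'   covariates; an `age_group` column is derived from `age` if absent.
#' @param assignments long data.frame from [assign_exposure()] with columns
#'   `subject_id`, `method`, `lag`, `ppb` (all methods and lags stacked).
#' @param outcomes outcome columns to fit.
#' @param covariates adjustment set passed to [fit_association()].
#' @param iqr_policy `"pooled"` (one IQR for the whole grid, default) or
#'   `"per_cell"`.
#' @return data.frame with one row per grid cell: `outcome`, `method`,
#'   `lag`, `age_group`, `n`, `iqr_ppb`, `beta_per_iqr`, `ci_low`,
#'   `ci_high`, `p_value`, `p_bh`, `sig_flag`, `note`.
#' @export
run_full_grid <- function(cohort, assignments,
                          outcomes = c("fvc_l", "fev1_l"),
                          covariates = c("age", "sex", "height_cm", "weight_kg"),
                          iqr_policy = c("pooled", "per_cell")) {
  iqr_policy <- match.arg(iqr_policy)
  if (!all(c("subject_id", "method", "lag", "ppb") %in% names(assignments)))
    stop_ozl("assignments must have columns subject_id, method, lag, ppb",
             "ozl_invalid_config")
  if (!"age_group" %in% names(cohort))
    cohort$age_group <- assign_age_groups(cohort$age)
  pooled_iqr <- exposure_iqr(assignments$ppb)

  methods <- unique(assignments$method)
  lags <- unique(assignments$lag)
  groups <- c(levels(cohort$age_group), "All")
  rows <- list()
  for (out_col in outcomes) for (m in methods) for (lg in lags) {
    a <- assignments[assignments$method == m & assignments$lag == lg, ]
    expo <- a$ppb[match(as.character(cohort$subject_id), a$subject_id)]
    for (g in groups) {
      sel <- if (g == "All") rep(TRUE, nrow(cohort)) else cohort$age_group == g
      iqr <- if (iqr_policy == "pooled") pooled_iqr else NULL
      est <- try(fit_association(cohort[sel, , drop = FALSE], expo[sel],
                                 outcome = out_col, covariates = covariates,
                                 iqr = iqr), silent = TRUE)
      if (inherits(est, "try-error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          outcome = out_col, method = m, lag = lg, age_group = g,
          n = sum(sel), iqr_ppb = NA_real_, beta_per_iqr = NA_real_,
          ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
          note = conditionMessage(attr(est, "condition")),
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          outcome = out_col, method = m, lag = lg, age_group = g,
          n = est$n, iqr_ppb = est$iqr_ppb, beta_per_iqr = est$beta_per_iqr,
          ci_low = est$ci_low, ci_high = est$ci_high, p_value = est$p_value,
          note = "", stringsAsFactors = FALSE)
      }
    }
  }
  grid <- do.call(rbind, rows)
  grid$p_bh <- stats::p.adjust(grid$p_value, method = "BH")
  grid$sig_flag <- ifelse(is.na(grid$p_value), "",
                   ifelse(grid$p_value < 0.001, "**",
                   ifelse(grid$p_value < 0.05, "*", "")))
  rownames(grid) <- NULL
  grid
}
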