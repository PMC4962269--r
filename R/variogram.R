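#' Spherical semivariogram model
#'
#' Container for the three parameters of the spherical semivariogram
#' \deqn{\gamma(h) = c_0 + c_1\left(1.5\,h/a - 0.5\,(h/a)^3\right), \quad 0 < h \le a,}
#' with \eqn{\gamma(0) = 0} and \eqn{\gamma(h) = c_0 + c_1} for \eqn{h > a}.
#' `nugget` (\eqn{c_0}, ppb^2) is the discontinuity at the origin
#' (measurement and microscale variance), `psill` (\eqn{c_1}, ppb^2) the
#' additional variance reached at the sill, and `range_km` (\eqn{a}) the
#' distance beyond which values are uncorrelated.
#'
#' @param nugget nugget variance c0 (ppb^2), >= 0.
#' @param psill partial sill c1 (ppb^2), >= 0.
#' @param range_km range a (km), > 0.
#' @return A `variogram_model` list with elements `nugget`, `psill`,
#'   `range_km`, `model` (always `"spherical"`).
#' @examples
#' vm <- variogram_model(nugget = 0, psill = 100, range_km = 10)
#' spherical_gamma(c(0, 5, 10, 20), vm)
#' @export
variogram_model <- function(nugget, psill, range_km) {
  if (!is.finite(nugget) || nugget < 0)
    stop_ozl("nugget must be finite and >= 0", "ozl_invalid_config")
  if (!is.finite(psill) || psill < 0)
    stop_ozl("partial sill must be finite and >= 0", "ozl_invalid_config")
  if (!is.finite(range_km) || range_km <= 0)
    stop_ozl("range must be finite and > 0", "ozl_invalid_config")
  structure(list(nugget = as.numeric(nugget), psill = as.numeric(psill),
                 range_km = as.numeric(range_km), model = "spherical"),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model> spherical: nugget %.4g ppb^2, partial sill %.4g ppb^2, range %.4g km\n",
              x$nugget, x$psill, x$range_km))
  invisible(x)
}

#' Evaluate a spherical semivariogram
#'
#' @param h distances (km), vector or matrix; nonnegative.
#' @param model a [variogram_model()].
#' @return gamma(h) in ppb^2, same shape as `h`; exactly 0 at h = 0.
#' @export
spherical_gamma <- function(h, model) {
  a <- model$range_km
  r <- pmin(h / a, 1)
  g <- model$nugget + model$psill * (1.5 * r - 0.5 * r^3)
  g[h == 0] <- 0
  g
}

# covariance implied by the variogram between *distinct* locations:
# C(h) = c1 * (1 - 1.5 h/a + 0.5 (h/a)^3) for h < a, 0 beyond; the nugget
# acts as independent site noise and contributes only on the diagonal.
spherical_cov <- function(h, model) {
  a <- model$range_km
  r <- pmin(h / a, 1)
  model$psill * (1 - 1.5 * r + 0.5 * r^3)
}

#' Empirical (Matheron) semivariogram of a daily panel
#'
#' Computes the classical Matheron estimator
#' \eqn{\hat\gamma(h) = \frac{1}{2N(h)} \sum_{(i,j)} (z_i - z_j)^2}
#' over all monitor pairs whose separation falls in each distance bin.
#' Given a matrix of daily values, pairs are pooled across days (each day
#' contributes its complete pairs), which stabilises the estimate when a
#' single day offers only n(n-1)/2 pairs.
#'
#' @param values named numeric vector (one day; names = monitor ids) or a
#'   monitors x days matrix with rownames = monitor ids. `NA`s are dropped
#'   pairwise.
#' @param network a [monitor_network()] covering the value names.
#' @param n_bins number of equal-width distance bins on (0, max_lag].
#' @param max_lag largest separation (km) considered; default half the
#'   network diameter, standard geostatistical practice.
#' @return data.frame with one row per non-empty bin: `lag_km` (mean pair
#'   separation in the bin), `gamma` (ppb^2), `n_pairs`.
#' @examples
#' net <- monitor_network(c("A", "B", "C"), c(0, 4, 9), c(0, 0, 0))
#' empirical_semivariogram(c(A = 10, B = 14, C = 9), net,
#'                         n_bins = 3, max_lag = 10)
#' @export
empirical_semivariogram <- function(values, network, n_bins = 6, max_lag = NULL) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1, dimnames = list(names(values), NULL))
  ids <- rownames(values)
  if (is.null(ids) || !all(ids %in% network$id))
    stop_ozl("values must be named/rownamed by monitor ids present in the network",
             "ozl_invalid_config")
  if (sum(rowSums(!is.na(values)) > 0) < 2L)
    stop_ozl("at least two monitors with data are required", "ozl_insufficient_data")
  net <- network[match(ids, network$id), , drop = FALSE]
  d <- cross_dist(net$x_km, net$y_km, net$x_km, net$y_km)
  if (is.null(max_lag)) max_lag <- max(d) / 2
  if (!is.finite(max_lag) || max_lag <= 0)
    stop_ozl("max_lag must be positive", "ozl_invalid_config")

  pair <- which(upper.tri(d), arr.ind = TRUE)
  pd <- d[pair]
  keep <- pd > 0 & pd <= max_lag
  pair <- pair[keep, , drop = FALSE]
  pd <- pd[keep]
  if (length(pd) == 0L)
    stop_ozl("no monitor pairs within max_lag", "ozl_insufficient_data")

  bin <- ceiling(pd / (max_lag / n_bins))
  bin[bin < 1L] <- 1L

  zi <- values[pair[, 1], , drop = FALSE]
  zj <- values[pair[, 2], , drop = FALSE]
  sq <- (zi - zj)^2            # pairs x days
  ok <- !is.na(sq)
  sq[!ok] <- 0

  n_pairs <- as.vector(rowsum(rowSums(ok), bin))
  ssq     <- as.vector(rowsum(rowSums(sq), bin))
  wdist   <- as.vector(rowsum(pd * rowSums(ok), bin))
  out <- data.frame(lag_km = wdist / n_pairs,
                    gamma  = ssq / (2 * n_pairs),
                    n_pairs = n_pairs)
  out <- out[out$n_pairs > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "max_lag") <- max_lag
  out
}

# profiled weighted least squares for fixed range a: gamma ~ c0 + c1 * f(h; a)
# with c0, c1 >= 0. Returns list(c0, c1, sse).
wls_profile <- function(bins, a) {
  h <- bins$lag_km; g <- bins$gamma; w <- bins$n_pairs
  r <- pmin(h / a, 1)
  f <- 1.5 * r - 0.5 * r^3
  sw <- sum(w); swf <- sum(w * f); swff <- sum(w * f * f)
  swg <- sum(w * g); swfg <- sum(w * f * g)
  det <- sw * swff - swf^2
  if (abs(det) > 1e-12 * max(sw * swff, 1e-300)) {
    c1 <- (sw * swfg - swf * swg) / det
    c0 <- (swg - c1 * swf) / sw
  } else {
    c1 <- 0; c0 <- swg / sw
  }
  if (c0 < 0) {                       # refit on the c0 = 0 boundary
    c0 <- 0
    c1 <- if (swff > 0) max(0, swfg / swff) else 0
  }
  if (c1 < 0) {                       # flat model: pure nugget
    c1 <- 0
    c0 <- max(0, swg / sw)
  }
  sse <- sum(w * (g - c0 - c1 * f)^2)
  list(c0 = c0, c1 = c1, sse = sse)
}

#' Fit a spherical model to an empirical semivariogram
#'
#' Weighted least squares with weights equal to the per-bin pair counts.
#' For a fixed range the model is linear in (nugget, partial sill), so those
#' two are profiled out in closed form subject to nonnegativity; the range is
#' found by a multistart grid over (0, 2 max_lag] followed by a bounded
#' 1-D refinement. With all-zero semivariances the degenerate flat model
#' (nugget 0, partial sill 0) is returned.
#'
#' @param bins data.frame from [empirical_semivariogram()] (`lag_km`,
#'   `gamma`, `n_pairs`), at least 3 rows.
#' @param max_lag upper end of the binned distances; defaults to the value
#'   recorded by [empirical_semivariogram()], else `max(lag_km)`. The fitted
#'   range is constrained to (0, 2 max_lag].
#' @return A [variogram_model()].
#' @examples
#' vm <- variogram_model(0, 100, 10)
#' h <- seq(1, 14, length.out = 8)
#' bins <- data.frame(lag_km = h, gamma = spherical_gamma(h, vm), n_pairs = 10)
#' fit_spherical_variogram(bins)
#' @export
fit_spherical_variogram <- function(bins, max_lag = NULL) {
  if (!is.data.frame(bins) || nrow(bins) < 3L)
    stop_ozl("need at least 3 semivariogram bins to fit a spherical model",
             "ozl_insufficient_data")
  if (is.null(max_lag)) max_lag <- attr(bins, "max_lag") %||% max(bins$lag_km)
  a_max <- 2 * max_lag

  if (all(bins$gamma == 0))
    return(structure(list(nugget = 0, psill = 0, range_km = max_lag,
                          model = "spherical"), class = "variogram_model"))

  a_grid <- seq(0.05, 1, length.out = 25) * a_max
  sse <- vapply(a_grid, function(a) wls_profile(bins, a)$sse, numeric(1))
  a0 <- a_grid[which.min(sse)]
  opt <- try(stats::nlminb(a0, function(a) wls_profile(bins, a)$sse,
                           lower = 1e-6, upper = a_max), silent = TRUE)
  a_hat <- if (!inherits(opt, "try-error") && is.finite(opt$par)) opt$par else a0
  best <- wls_profile(bins, a_hat)
  grid_best <- wls_profile(bins, a0)
  if (grid_best$sse < best$sse) { a_hat <- a0; best <- grid_best }

  structure(list(nugget = best$c0, psill = best$c1,
                 range_km = max(a_hat, 1e-6), model = "spherical"),
            class = "variogram_model")
}

# fallback chain used by prediction / cross-validation when a per-day fit is
# not possible: pooled all-days fit, then pure nugget at the sample variance.
pooled_or_nugget_fit <- function(values_matrix, network, n_bins = 6, max_lag = NULL) {
  vm <- try({
    bins <- empirical_semivariogram(values_matrix, network, n_bins = n_bins,
                                    max_lag = max_lag)
    fit_spherical_variogram(bins)
  }, silent = TRUE)
  if (!inherits(vm, "try-error")) return(vm)
  v <- stats::var(as.vector(values_matrix), na.rm = TRUE)
  if (!is.finite(v)) v <- 0
  structure(list(nugget = max(v, 1e-12), psill = 0,
                 range_km = max(max_lag %||% 1, 1), model = "spherical"),
            class = "variogram_model")
}
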