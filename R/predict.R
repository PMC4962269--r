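#' Variogram fitting policy for kriging prediction
#'
#' With ~10 monitors a single day offers only 45 pairs, so per-day variogram
#' fits can be fragile. The policy controls how kriging obtains its model
#' for each day: `"daily"` fits the spherical model to that day's available
#' monitors and falls back to a pooled (all-days) fit, then to a pure-nugget
#' model at the sample variance, whenever the daily fit is not possible;
#' `"pooled"` always uses the single all-days fit.
#'
#' @param mode `"daily"` or `"pooled"`.
#' @param n_bins number of semivariogram distance bins.
#' @param max_lag largest lag (km); default half the network diameter.
#' @return a `variogram_policy` list.
#' @export
variogram_policy <- function(mode = c("daily", "pooled"), n_bins = 6,
                             max_lag = NULL) {
  mode <- match.arg(mode)
  structure(list(mode = mode, n_bins = n_bins, max_lag = max_lag),
            class = "variogram_policy")
}

# fit the variogram for one day under a policy; `pooled` is the precomputed
# all-days fallback model. Returns list(model, source).
day_variogram <- function(day_values, network, policy, pooled) {
  if (policy$mode == "pooled") return(list(model = pooled, source = "pooled"))
  vm <- try({
    bins <- empirical_semivariogram(day_values, network,
                                    n_bins = policy$n_bins,
                                    max_lag = policy$max_lag)
    fit_spherical_variogram(bins)
  }, silent = TRUE)
  if (inherits(vm, "try-error")) list(model = pooled, source = "pooled")
  else list(model = vm, source = "daily")
}

#' Predict daily exposure at arbitrary locations for a whole panel
#'
#' Applies one of the four exposure-estimation methods to every
#' (location, day) combination of a daily metric panel. For kriging the
#' variogram is refit per day under the given [variogram_policy()]; days
#' where fewer than two monitors report fall back to the nearest available
#' monitor value, and days with no data at all propagate as `NA`.
#'
#' @param panel a [daily_panel()].
#' @param network the [monitor_network()] matching the panel rows.
#' @param locations data.frame/matrix of target points (columns x_km, y_km);
#'   row identifiers are taken from a `subject_id` column, rownames, or
#'   generated.
#' @param method one of `"simple_average"`, `"nearest"`, `"idw"`,
#'   `"kriging"`.
#' @param policy a [variogram_policy()] (kriging only).
#' @param power IDW exponent (default 1, i.e. 1/d weights).
#' @return an `exposure_predictions` object: list with `values`
#'   (locations x days ppb matrix), `variance` (same shape, kriging only),
#'   `method`, `dates`, and a `fallbacks` count of kriging days that used
#'   the pooled variogram. `as.data.frame()` yields the long form.
#' @examples
#' net <- monitor_network(c("A", "B"), c(0, 10), c(0, 0))
#' pan <- daily_panel(matrix(c(40, 50), 2, 1, dimnames = list(c("A", "B"), NULL)),
#'                    as.Date("2009-06-01"))
#' predict_all(pan, net, data.frame(x_km = 2, y_km = 0), method = "idw")
#' @export
predict_all <- function(panel, network,
                        locations,
                        method = c("simple_average", "nearest", "idw", "kriging"),
                        policy = variogram_policy(),
                        power = 1) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "daily_panel"))
  if (!all(rownames(panel$values) %in% network$id))
    stop_ozl("panel monitors not all present in network", "ozl_invalid_config")
  locations <- as.data.frame(locations)
  loc_ids <- if ("subject_id" %in% names(locations)) as.character(locations$subject_id)
             else rownames(locations) %||% sprintf("L%04d", seq_len(nrow(locations)))
  xy <- as.matrix(locations[, c("x_km", "y_km")])

  n_loc <- nrow(xy); n_day <- ncol(panel$values)
  values <- matrix(NA_real_, n_loc, n_day, dimnames = list(loc_ids, colnames(panel$values)))
  variance <- if (method == "kriging") values else NULL

  pooled <- NULL; fallbacks <- 0L
  if (method == "kriging" &&
      sum(rowSums(!is.na(panel$values)) > 0) >= 2L)
    pooled <- pooled_or_nugget_fit(panel$values, network,
                                   n_bins = policy$n_bins, max_lag = policy$max_lag)

  for (j in seq_len(n_day)) {
    v <- stats::setNames(panel$values[, j], rownames(panel$values))
    n_avail <- sum(!is.na(v))
    if (n_avail == 0L) next
    if (method == "simple_average") {
      values[, j] <- as.numeric(simple_average(v))
    } else if (method == "nearest" || n_avail == 1L) {
      values[, j] <- nearest_neighbor(v, network, xy)
    } else if (method == "idw") {
      values[, j] <- idw(v, network, xy, power = power)
    } else {
      dv <- day_variogram(v, network, policy, pooled)
      if (dv$source == "pooled" && policy$mode == "daily") fallbacks <- fallbacks + 1L
      pr <- ordinary_kriging(v, network, dv$model, xy)
      values[, j] <- pr$value
      variance[, j] <- pr$variance
    }
  }
  structure(list(values = values, variance = variance, method = method,
                 dates = panel$dates, fallbacks = fallbacks),
            class = "exposure_predictions")
}

#' @export
print.exposure_predictions <- function(x, ...) {
  cat(sprintf("<exposure_predictions> method %s: %d location(s) x %d day(s), %d missing cell(s)\n",
              x$method, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  if (x$fallbacks > 0)
    cat(sprintf("  kriging fell back to the pooled variogram on %d day(s)\n", x$fallbacks))
  invisible(x)
}

#' @export
as.data.frame.exposure_predictions <- function(x, ...) {
  v <- x$values
  out <- data.frame(subject_id = rep(rownames(v), times = ncol(v)),
                    date = rep(x$dates, each = nrow(v)),
                    method = x$method,
                    ppb = as.vector(v),
                    stringsAsFactors = FALSE)
  out$kriging_variance <- if (!is.null(x$variance)) as.vector(x$variance) else NA_real_
  out
}
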