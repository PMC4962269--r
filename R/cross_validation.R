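#' Leave-one-monitor-out prediction
#'
#' For each monitor in turn, its values are withheld and the remaining
#' monitors predict the ozone level at the withheld location, day by day.
#' For kriging the variogram is refit without the withheld monitor (daily
#' fit with pooled fallback, or pooled, per the policy), so the excluded
#' station never leaks into the model. With only one remaining monitor the
#' prediction falls back to that monitor's value for every method.
#' The network-average method is allowed (it predicts the mean of the other
#' monitors) but is location-insensitive, which is flagged on the result.
#'
#' @inheritParams predict_all
#' @return data.frame of paired values with columns `monitor_id`, `date`,
#'   `measured`, `predicted` (ppb); rows where either side is missing are
#'   dropped. Attributes: `method`, `location_insensitive`, `fallbacks`.
#' @examples
#' net <- monitor_network(c("A", "B"), c(0, 10), c(0, 0))
#' pan <- daily_panel(matrix(c(40, 50, 42, 48), 2, 2,
#'                           dimnames = list(c("A", "B"), NULL)),
#'                    as.Date("2009-06-01") + 0:1)
#' loo_predict(pan, net, method = "nearest")
#' @export
loo_predict <- function(panel, network,
                        method = c("simple_average", "nearest", "idw", "kriging"),
                        policy = variogram_policy(),
                        power = 1) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "daily_panel"))
  ids <- rownames(panel$values)
  if (length(ids) < 2L)
    stop_ozl("leave-one-out validation needs at least two monitors",
             "ozl_insufficient_data")
  out <- vector("list", length(ids))
  fallbacks <- 0L
  for (m in seq_along(ids)) {
    keep <- setdiff(ids, ids[m])
    sub_panel <- daily_panel(panel$values[keep, , drop = FALSE], panel$dates)
    sub_net <- network[network$id %in% keep, , drop = FALSE]
    loc <- network[network$id == ids[m], c("x_km", "y_km"), drop = FALSE]
    pr <- predict_all(sub_panel, sub_net, loc, method = method,
                      policy = policy, power = power)
    fallbacks <- fallbacks + pr$fallbacks
    out[[m]] <- data.frame(monitor_id = ids[m],
                           date = panel$dates,
                           measured = unname(panel$values[ids[m], ]),
                           predicted = as.vector(pr$values),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out <- out[!is.na(out$measured) & !is.na(out$predicted), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "method") <- method
  attr(out, "location_insensitive") <- method == "simple_average"
  attr(out, "fallbacks") <- fallbacks
  out
}

#' Root mean square error of paired series
#'
#' \deqn{RMSE = \sqrt{\frac{1}{p}\sum_{i=1}^{p} (x_{ij} - x_{ik})^2}}
#' where \eqn{x_{ij}} and \eqn{x_{ik}} are the measured and predicted
#' values for observation i and p the number of pairs.
#'
#' @param measured,predicted numeric vectors of equal length (ppb).
#' @return RMSE in ppb.
#' @examples
#' rmse(c(10, 10), c(13, 14))  # sqrt(12.5)
#' @export
rmse <- function(measured, predicted) {
  if (length(measured) != length(predicted))
    stop_ozl("measured and predicted must have equal length", "ozl_invalid_config")
  ok <- !is.na(measured) & !is.na(predicted)
  if (!any(ok))
    stop_ozl("no complete pairs to score", "ozl_insufficient_data")
  sqrt(mean((measured[ok] - predicted[ok])^2))
}

#' Coefficient of divergence of paired series
#'
#' \deqn{COD = \sqrt{\frac{1}{p}\sum_{i=1}^{p}
#'   \left(\frac{x_{ij} - x_{ik}}{x_{ij} + x_{ik}}\right)^2}}
#' A COD of 0 means the measured and predicted series are identical; values
#' approaching 1 indicate maximum divergence. For nonnegative inputs the
#' result lies in [0, 1]. Pairs whose sum is zero (impossible for strictly
#' positive ozone) are dropped; the count of dropped pairs is recorded in
#' the `n_dropped` attribute.
#'
#' @inheritParams rmse
#' @return unitless COD in [0, 1], with attribute `n_dropped`.
#' @examples
#' cod(3, 1)  # 0.5
#' @export
cod <- function(measured, predicted) {
  if (length(measured) != length(predicted))
    stop_ozl("measured and predicted must have equal length", "ozl_invalid_config")
  ok <- !is.na(measured) & !is.na(predicted)
  if (any(measured[ok] < 0 | predicted[ok] < 0))
    stop_ozl("COD is defined for nonnegative concentrations", "ozl_invalid_config")
  s <- measured + predicted
  zero_sum <- ok & s == 0
  use <- ok & s > 0
  if (!any(use))
    stop_ozl("no usable pairs (all missing or zero-sum)", "ozl_insufficient_data")
  val <- sqrt(mean(((measured[use] - predicted[use]) / s[use])^2))
  structure(val, n_dropped = sum(zero_sum))
}

#' Cross-validation summary table
#'
#' Runs [loo_predict()] for each requested method and scores the pooled
#' pairs (all monitor-days at once) as well as each monitor separately with
#' [rmse()] and [cod()].
#'
#' @inheritParams predict_all
#' @param methods character vector of method labels.
#' @return data.frame with columns `method`, `monitor_id` (`"ALL"` for the
#'   pooled row), `n_pairs`, `rmse_ppb`, `cod`.
#' @export
crossval_summary <- function(panel, network,
                             methods = c("nearest", "idw", "kriging"),
                             policy = variogram_policy(),
                             power = 1) {
  rows <- list()
  for (m in methods) {
    pairs <- loo_predict(panel, network, method = m, policy = policy, power = power)
    rows[[length(rows) + 1L]] <- data.frame(
      method = m, monitor_id = "ALL", n_pairs = nrow(pairs),
      rmse_ppb = rmse(pairs$measured, pairs$predicted),
      cod = as.numeric(cod(pairs$measured, pairs$predicted)),
      stringsAsFactors = FALSE)
    for (id in unique(pairs$monitor_id)) {
      p <- pairs[pairs$monitor_id == id, ]
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, monitor_id = id, n_pairs = nrow(p),
        rmse_ppb = rmse(p$measured, p$predicted),
        cod = as.numeric(cod(p$measured, p$predicted)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
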