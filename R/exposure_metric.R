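#' Daily maximum 8-hour moving average
#'
#' The regulatory-style daily ozone metric: the highest of the 17 within-day
#' 8-hour window means (windows starting at hours 0 through 16; windows never
#' cross midnight, which is what makes the count 17). Missing hours are
#' handled by completeness rules: a window is valid if at least 6 of its 8
#' hours are present (the mean is then taken over the present hours, without
#' imputation), and the day is valid if at least 13 of the 17 windows are
#' valid. An invalid day yields `NA`.
#'
#' @param day_values numeric vector of exactly 24 hourly ppb values (hours
#'   0-23), `NA` for missing hours.
#' @return the metric in ppb, or `NA` for an invalid day; attribute
#'   `n_valid_windows` gives the number of valid windows.
#' @examples
#' max_8h_moving_average(0:23)        # window hours 16-23 -> 19.5
#' max_8h_moving_average(rep(50, 24)) # 50
#' @export
max_8h_moving_average <- function(day_values) {
  if (length(day_values) != 24L)
    stop_ozl("day_values must have exactly 24 hourly slots", "ozl_invalid_config")
  x <- as.numeric(day_values)
  if (any(x < 0, na.rm = TRUE))
    stop_ozl("ozone concentrations must be nonnegative", "ozl_invalid_config")
  present <- !is.na(x)
  x0 <- ifelse(present, x, 0)
  cs <- c(0, cumsum(x0)); cn <- c(0, cumsum(present))
  starts <- 1:17
  n_h <- cn[starts + 8] - cn[starts]
  sums <- cs[starts + 8] - cs[starts]
  valid <- n_h >= 6
  n_valid <- sum(valid)
  out <- if (n_valid >= 13) max(sums[valid] / n_h[valid]) else NA_real_
  structure(out, n_valid_windows = n_valid)
}

#' Construct a daily metric panel directly from daily values
#'
#' Wraps an existing monitors x days matrix of daily metric values (ppb) as a
#' `daily_panel`, the container consumed by the interpolation and
#' cross-validation stages. Used when daily values are already available
#' (e.g. simulated at the daily level); [build_daily_panel()] derives the
#' matrix from hourly data.
#'
#' @param values monitors x days numeric matrix, rownames = monitor ids,
#'   `NA` allowed.
#' @param dates Date vector, one per column.
#' @param n_valid optional matrix of valid-window counts (same shape).
#' @return a `daily_panel` object.
#' @export
daily_panel <- function(values, dates, n_valid = NULL) {
  values <- as.matrix(values)
  dates <- as.Date(dates)
  if (is.null(rownames(values)))
    stop_ozl("panel values need monitor ids as rownames", "ozl_invalid_config")
  if (length(dates) != ncol(values))
    stop_ozl("one date per panel column is required", "ozl_invalid_config")
  if (any(values < 0, na.rm = TRUE))
    stop_ozl("panel values must be nonnegative", "ozl_invalid_config")
  colnames(values) <- as.character(dates)
  structure(list(values = values, dates = dates,
                 monitor_ids = rownames(values),
                 n_valid = n_valid),
            class = "daily_panel")
}

#' @export
print.daily_panel <- function(x, ...) {
  v <- x$values
  cat(sprintf("<daily_panel> %d monitor(s) x %d day(s), %d/%d cells valid\n",
              nrow(v), ncol(v), sum(!is.na(v)), length(v)))
  cat(sprintf("  dates %s .. %s; ppb range %.1f .. %.1f\n",
              min(x$dates), max(x$dates),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' @export
as.data.frame.daily_panel <- function(x, ...) {
  v <- x$values
  data.frame(monitor_id = rep(rownames(v), times = ncol(v)),
             date = rep(x$dates, each = nrow(v)),
             ppb = as.vector(v),
             stringsAsFactors = FALSE)
}

#' Build the daily metric panel from hourly ozone data
#'
#' Applies [max_8h_moving_average()] (or, for diagnostic use, a plain daily
#' mean requiring at least 18 present hours) to each monitor-day of a
#' long-format hourly table.
#'
#' @param hourly data.frame with columns `monitor_id`, `date` (Date or
#'   coercible), `hour` (0-23), `ppb` (`NA` allowed).
#' @param metric `"max8h"` (default) or `"daily_mean"`.
#' @return a [daily_panel()] spanning the full date range of the input;
#'   monitor-days failing the completeness rules are `NA`.
#' @examples
#' h <- expand.grid(hour = 0:23, date = as.Date("2009-06-01") + 0:1)
#' h$monitor_id <- "M01"; h$ppb <- 40 + h$hour / 2
#' build_daily_panel(h)
#' @export
build_daily_panel <- function(hourly, metric = c("max8h", "daily_mean")) {
  metric <- match.arg(metric)
  need <- c("monitor_id", "date", "hour", "ppb")
  if (!is.data.frame(hourly) || nrow(hourly) == 0L || !all(need %in% names(hourly)))
    stop_ozl("hourly data must be a non-empty data.frame with columns monitor_id, date, hour, ppb",
             "ozl_invalid_config")
  hour <- as.integer(hourly$hour)
  if (any(hour < 0L | hour > 23L, na.rm = TRUE))
    stop_ozl("hours must lie in 0..23", "ozl_invalid_config")
  if (any(hourly$ppb < 0, na.rm = TRUE))
    stop_ozl("ozone concentrations must be nonnegative", "ozl_invalid_config")
  date <- as.Date(hourly$date)
  key <- paste(hourly$monitor_id, date, hour)
  if (anyDuplicated(key))
    stop_ozl("duplicate (monitor, date, hour) rows in hourly data", "ozl_invalid_config")

  ids <- sort(unique(as.character(hourly$monitor_id)))
  dates <- seq(min(date), max(date), by = "day")
  vals <- matrix(NA_real_, nrow = length(ids) * length(dates), ncol = 24)
  ridx <- match(as.character(hourly$monitor_id), ids) +
    (match(date, dates) - 1L) * length(ids)
  vals[cbind(ridx, hour + 1L)] <- hourly$ppb

  if (metric == "max8h") {
    res <- apply(vals, 1, function(x) {
      m <- max_8h_moving_average(x)
      c(as.numeric(m), attr(m, "n_valid_windows"))
    })
    values <- matrix(res[1, ], nrow = length(ids), ncol = length(dates),
                     dimnames = list(ids, as.character(dates)))
    n_valid <- matrix(res[2, ], nrow = length(ids), ncol = length(dates),
                      dimnames = list(ids, as.character(dates)))
  } else {
    nh <- rowSums(!is.na(vals))
    mv <- rowMeans(vals, na.rm = TRUE)
    mv[nh < 18] <- NA_real_
    values <- matrix(mv, nrow = length(ids), ncol = length(dates),
                     dimnames = list(ids, as.character(dates)))
    n_valid <- NULL
  }
  daily_panel(values, dates, n_valid = n_valid)
}
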