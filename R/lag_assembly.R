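#' Lag definitions for exposure assignment
#'
#' The six lag structures used to relate ozone to a lung-function test
#' performed on day d: the test day itself (`0d`), one day before (`1d`),
#' two days before (`2d`), and the unweighted averages over the test day and
#' previous day (`0-1d`), the two previous days (`1-2d`), and the test day
#' plus two previous days (`0-2d`).
#'
#' @return named list mapping lag label to its day offsets.
#' @export
lag_specs <- function() {
  list("0d" = 0L, "1d" = 1L, "2d" = 2L,
       "0-1d" = c(0L, 1L), "1-2d" = c(1L, 2L), "0-2d" = c(0L, 1L, 2L))
}

#' Assign lag-structured exposures to subjects
#'
#' For each subject and lag, averages the subject's predicted daily ozone
#' values at test_date - offset over the lag's offsets. Completeness rules:
#' single-day lags require that day's prediction; two-day lags require both
#' days; the three-day lag `0-2d` tolerates one missing day (mean of the
#' two present days).
#'
#' @param predictions an `exposure_predictions` object from [predict_all()]
#'   (rows = subjects, columns = days), or a subjects x days matrix with
#'   column names coercible to dates.
#' @param cohort data.frame with `subject_id` and `test_date` (Date)
#'   matching the prediction rows.
#' @param lags character vector of lag labels (default all six).
#' @return long data.frame: `subject_id`, `method`, `lag`, `ppb` (`NA`
#'   where the completeness rule fails).
#' @examples
#' m <- matrix(c(40, 50, 60), 1, 3,
#'             dimnames = list("S1", as.character(as.Date("2009-06-01") + 0:2)))
#' coh <- data.frame(subject_id = "S1", test_date = as.Date("2009-06-03"))
#' assign_exposure(m, coh)
#' @export
assign_exposure <- function(predictions, cohort, lags = names(lag_specs())) {
  specs <- lag_specs()
  if (!all(lags %in% names(specs)))
    stop_ozl("unknown lag label(s)", "ozl_invalid_config")
  if (inherits(predictions, "exposure_predictions")) {
    values <- predictions$values
    dates <- predictions$dates
    method <- predictions$method
  } else {
    values <- as.matrix(predictions)
    dates <- as.Date(colnames(values))
    method <- attr(predictions, "method") %||% NA_character_
  }
  sid <- as.character(cohort$subject_id)
  ridx <- match(sid, rownames(values))
  if (anyNA(ridx))
    stop_ozl("some subjects are absent from the prediction table", "ozl_invalid_config")
  test_date <- as.Date(cohort$test_date)

  out <- vector("list", length(lags))
  for (k in seq_along(lags)) {
    offs <- specs[[lags[k]]]
    day_cols <- vapply(offs, function(o) match(test_date - o, dates),
                       integer(length(sid)))
    day_cols <- matrix(day_cols, nrow = length(sid))
    vals <- matrix(NA_real_, length(sid), length(offs))
    for (j in seq_along(offs)) {
      has <- !is.na(day_cols[, j])
      vals[has, j] <- values[cbind(ridx[has], day_cols[has, j])]
    }
    n_present <- rowSums(!is.na(vals))
    min_needed <- if (length(offs) <= 2L) length(offs) else length(offs) - 1L
    ppb <- rowMeans(vals, na.rm = TRUE)
    ppb[n_present < min_needed] <- NA_real_
    out[[k]] <- data.frame(subject_id = sid, method = method,
                           lag = lags[k], ppb = ppb,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Interquartile range of assigned exposures
#'
#' The 75th minus the 25th percentile under the linear-interpolation
#' quantile definition (R type 7), used to express regression effects per
#' IQR increase in ozone.
#'
#' @param x numeric exposures (ppb); `NA` dropped.
#' @return IQR in ppb.
#' @examples
#' exposure_iqr(1:100)  # 49.5
#' @export
exposure_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 4L)
    stop_ozl("need at least 4 non-missing exposures for an IQR", "ozl_insufficient_data")
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] - q[1]
}
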