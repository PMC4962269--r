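#' Exposure-estimation methods
#'
#' Four ways of assigning a day's ozone level, observed at a sparse monitor
#' network, to arbitrary residential locations: the network average
#' (identical for every location), the nearest monitor's value, inverse
#' distance weighting with weights proportional to 1/d, and ordinary kriging
#' driven by a spherical semivariogram. Monitors with a missing value that
#' day are dropped from the calculation rather than imputed.
#'
#' @name interpolation-methods
#' @keywords internal
NULL

as_points <- function(point) {
  if (is.null(dim(point))) {
    stopifnot(length(point) == 2L)
    point <- matrix(as.numeric(point), ncol = 2)
  } else {
    point <- as.matrix(as.data.frame(point)[, 1:2])
  }
  storage.mode(point) <- "double"
  point
}

check_day_values <- function(values, network) {
  if (is.null(names(values)) || !all(names(values) %in% network$id))
    stop_ozl("day values must be named by monitor ids present in the network",
             "ozl_invalid_config")
  keep <- !is.na(values)
  if (!any(keep))
    stop_ozl("no monitor has data for this day", "ozl_no_data")
  values[keep]
}

#' Network-average exposure (Method 1)
#'
#' The arithmetic mean of all monitors reporting that day; every subject is
#' assigned the same value regardless of location.
#'
#' @param values named numeric vector of that day's monitor values (ppb),
#'   `NA` for monitors without data.
#' @return single ppb value, with attribute `n_used`.
#' @examples
#' simple_average(c(M01 = 10, M02 = 20, M03 = 30))
#' @export
simple_average <- function(values) {
  z <- values[!is.na(values)]
  if (length(z) == 0L)
    stop_ozl("no monitor has data for this day", "ozl_no_data")
  structure(mean(z), n_used = length(z))
}

#' Nearest-monitor exposure (Method 2)
#'
#' Assigns each point the value of the closest monitor (Euclidean distance,
#' km) with data that day. Exact distance ties are broken by the lowest
#' monitor id so predictions are deterministic.
#'
#' @param values named numeric vector of the day's monitor values (ppb).
#' @param network a [monitor_network()].
#' @param point a length-2 `c(x_km, y_km)` vector or a matrix/data.frame of
#'   points (columns x, y).
#' @return numeric vector of ppb values, one per point; attribute `n_used`.
#' @examples
#' net <- monitor_network(c("M01", "M02"), c(0, 10), c(0, 0))
#' nearest_neighbor(c(M01 = 10, M02 = 20), net, c(2, 0))
#' @export
nearest_neighbor <- function(values, network, point) {
  z <- check_day_values(values, network)
  pts <- as_points(point)
  net <- network[match(names(z), network$id), , drop = FALSE]
  ord <- order(net$id)                       # id order for tie-breaking
  net <- net[ord, , drop = FALSE]; z <- z[ord]
  d <- cross_dist(pts[, 1], pts[, 2], net$x_km, net$y_km)
  idx <- apply(d, 1, which.min)              # first minimum = lowest id
  structure(unname(z[idx]), n_used = length(z))
}

#' Inverse-distance-weighted exposure (Method 3)
#'
#' Weighted mean of the day's monitor values with weights
#' \eqn{w_i \propto 1/d_i^{p}}. The default power p = 1 gives the plain
#' 1/d weighting; p = 2 is the more common geostatistical convention and is
#' available through `power`. A point closer than 1e-9 km to a monitor
#' receives that monitor's value exactly.
#'
#' @inheritParams nearest_neighbor
#' @param power inverse-distance exponent (default 1).
#' @return numeric vector of ppb values, one per point; attribute `n_used`.
#' @examples
#' net <- monitor_network(c("A", "B"), c(1, 3), c(0, 0))
#' idw(c(A = 10, B = 20), net, c(0, 0))   # weights 3/4, 1/4 -> 12.5
#' @export
idw <- function(values, network, point, power = 1) {
  z <- check_day_values(values, network)
  pts <- as_points(point)
  net <- network[match(names(z), network$id), , drop = FALSE]
  d <- cross_dist(pts[, 1], pts[, 2], net$x_km, net$y_km)
  w <- d^(-power)
  out <- numeric(nrow(pts))
  at_monitor <- d < 1e-9
  hit <- rowSums(at_monitor) > 0
  if (any(hit))
    out[hit] <- z[apply(at_monitor[hit, , drop = FALSE], 1, which.max)]
  if (any(!hit)) {
    wn <- w[!hit, , drop = FALSE]
    out[!hit] <- as.vector((wn %*% z) / rowSums(wn))
  }
  structure(out, n_used = length(z))
}

#' Ordinary kriging exposure (Method 4)
#'
#' Best linear unbiased prediction under an unknown constant mean: weights
#' solve the ordinary-kriging system built from the spherical semivariogram
#' (monitor-monitor semivariances augmented with the unbiasedness row and
#' column; right-hand side the monitor-to-point semivariances), and sum to 1.
#' Also returns the kriging variance. If the system is numerically singular,
#' a diagonal regularisation of 1e-10 (nugget + sill) is applied once before
#' giving up. A point coincident with a monitor under a zero-nugget model is
#' an exact interpolation (that monitor's value, variance 0).
#'
#' @inheritParams nearest_neighbor
#' @param variogram a [variogram_model()].
#' @return data.frame with one row per point: `value` (ppb), `variance`
#'   (ppb^2), `n_used`.
#' @examples
#' net <- monitor_network(c("A", "B", "C"), c(0, 6, 3), c(0, 0, 5))
#' vm <- variogram_model(0, 100, 10)
#' ordinary_kriging(c(A = 40, B = 50, C = 45), net, vm, c(3, 2))
#' @export
ordinary_kriging <- function(values, network, variogram, point) {
  z <- check_day_values(values, network)
  if (length(z) < 2L)
    stop_ozl("ordinary kriging needs at least two monitors with data",
             "ozl_insufficient_data")
  if (!inherits(variogram, "variogram_model"))
    stop_ozl("variogram must be a variogram_model", "ozl_invalid_config")
  pts <- as_points(point)
  net <- network[match(names(z), network$id), , drop = FALSE]
  n <- length(z)

  # flat (zero-variance) model: the kriging system is degenerate and every
  # weight vector summing to 1 is optimal; take the symmetric equal-weight
  # solution, i.e. the network mean, with zero prediction variance.
  if (variogram$nugget + variogram$psill == 0)
    return(data.frame(value = rep(mean(z), nrow(pts)),
                      variance = 0, n_used = n))

  G <- spherical_gamma(cross_dist(net$x_km, net$y_km, net$x_km, net$y_km), variogram)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  D0 <- cross_dist(pts[, 1], pts[, 2], net$x_km, net$y_km)   # points x monitors
  B <- rbind(t(spherical_gamma(D0, variogram)), 1)           # (n+1) x points

  sol <- try(solve(A, B), silent = TRUE)
  if (inherits(sol, "try-error")) {
    ridge <- 1e-10 * (variogram$nugget + variogram$psill)
    diag(A)[seq_len(n)] <- diag(A)[seq_len(n)] + ridge
    sol <- try(solve(A, B), silent = TRUE)
    if (inherits(sol, "try-error"))
      stop_ozl("kriging system singular even after regularization (degenerate geometry)",
               "ozl_degenerate_geometry")
  }
  lambda <- sol[seq_len(n), , drop = FALSE]
  mu <- sol[n + 1L, ]
  value <- as.vector(crossprod(lambda, z))
  variance <- pmax(colSums(lambda * B[seq_len(n), , drop = FALSE]) + mu, 0)

  # exact interpolation at a monitor when there is no nugget effect
  at_monitor <- D0 < 1e-9
  hit <- which(rowSums(at_monitor) > 0)
  if (length(hit) && variogram$nugget == 0) {
    j <- apply(at_monitor[hit, , drop = FALSE], 1, which.max)
    value[hit] <- z[j]
    variance[hit] <- 0
  }
  data.frame(value = value, variance = variance, n_used = n)
}
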