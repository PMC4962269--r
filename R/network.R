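#' Monitor network
#'
#' A set of fixed ambient air monitoring stations on planar kilometre
#' coordinates. Distances throughout the package are Euclidean in km; the
#' study domains targeted here (a coastal bay, tens of km across) are small
#' enough that no geographic projection handling is needed.
#'
#' @param id character vector of unique station identifiers.
#' @param x_km,y_km numeric planar coordinates in kilometres.
#' @return A `monitor_network` data.frame with columns `id`, `x_km`, `y_km`.
#' @examples
#' net <- monitor_network(c("M01", "M02"), x_km = c(0, 10), y_km = c(0, 0))
#' network_diameter(net)
#' @export
monitor_network <- function(id, x_km, y_km) {
  id <- as.character(id)
  x_km <- as.numeric(x_km)
  y_km <- as.numeric(y_km)
  if (length(id) < 1L)
    stop_ozl("a monitor network needs at least one station", "ozl_invalid_config")
  if (anyDuplicated(id))
    stop_ozl("monitor ids must be unique", "ozl_invalid_config")
  if (length(x_km) != length(id) || length(y_km) != length(id))
    stop_ozl("id, x_km and y_km must have equal length", "ozl_invalid_config")
  if (!all(is.finite(x_km)) || !all(is.finite(y_km)))
    stop_ozl("monitor coordinates must be finite", "ozl_invalid_config")
  out <- data.frame(id = id, x_km = x_km, y_km = y_km, stringsAsFactors = FALSE)
  class(out) <- c("monitor_network", "data.frame")
  out
}

#' @export
print.monitor_network <- function(x, ...) {
  cat(sprintf("<monitor_network> %d station(s), diameter %.2f km\n",
              nrow(x), network_diameter(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Pairwise distance matrix of a monitor network
#'
#' @param network a [monitor_network()].
#' @return symmetric matrix of Euclidean distances (km), dimnames = ids.
#' @export
network_distances <- function(network) {
  d <- cross_dist(network$x_km, network$y_km, network$x_km, network$y_km)
  dimnames(d) <- list(network$id, network$id)
  d
}

#' Largest pairwise distance in a network (km)
#' @param network a [monitor_network()].
#' @export
network_diameter <- function(network) {
  if (nrow(network) < 2L) return(0)
  max(network_distances(network))
}
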