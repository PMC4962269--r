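# internal helpers shared across modules

# Euclidean distance matrix between two coordinate sets (planar km)
cross_dist <- function(x1, y1, x2, y2) {
  dx <- outer(x1, x2, "-")
  dy <- outer(y1, y2, "-")
  sqrt(dx * dx + dy * dy)
}

# Deterministic per-component seed derived from the master seed, so that e.g.
# enlarging the cohort does not perturb the ozone field draws. Kept < 2^31.
substream_seed <- function(seed, component) {
  stopifnot(is.character(component), length(component) == 1L)
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ozl <- function(msg, class) {
  stop(structure(class = c(class, "ozonelung_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
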