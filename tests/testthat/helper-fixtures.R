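# shared fixtures and independent oracles (kept deliberately naive so they
# stay independent of the implementation they check)

toy_network <- function(n = 3) {
  coords <- list(x = c(0, 6, 3, 9, 1), y = c(0, 0, 5, 4, 8))
  monitor_network(sprintf("M%02d", seq_len(n)),
                  coords$x[seq_len(n)], coords$y[seq_len(n)])
}

constant_panel <- function(network, n_days = 5, value = 40) {
  v <- matrix(value, nrow(network), n_days,
              dimnames = list(network$id, NULL))
  daily_panel(v, as.Date("2009-06-01") + seq_len(n_days) - 1)
}

# spherical semivariogram written out longhand
gamma_sph <- function(h, c0, c1, a) {
  if (h == 0) return(0)
  if (h >= a) return(c0 + c1)
  c0 + c1 * (1.5 * h / a - 0.5 * (h / a)^3)
}

# direct solve of the augmented ordinary-kriging system, scalar loops only
ok_oracle <- function(z, xs, ys, c0, c1, a, px, py) {
  n <- length(z)
  A <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    h <- sqrt((xs[i] - xs[j])^2 + (ys[i] - ys[j])^2)
    A[i, j] <- gamma_sph(h, c0, c1, a)
  }
  A[n + 1, seq_len(n)] <- 1
  A[seq_len(n), n + 1] <- 1
  b <- numeric(n + 1)
  for (i in seq_len(n))
    b[i] <- gamma_sph(sqrt((xs[i] - px)^2 + (ys[i] - py)^2), c0, c1, a)
  b[n + 1] <- 1
  w <- solve(A, b)
  list(value = sum(w[seq_len(n)] * z),
       variance = sum(w[seq_len(n)] * b[seq_len(n)]) + w[n + 1],
       weights = w[seq_len(n)])
}

# brute-force max 8-h moving average: loop over the 17 windows
max8h_oracle <- function(x) {
  means <- rep(NA_real_, 17)
  for (s in 1:17) {
    win <- x[s:(s + 7)]
    if (sum(!is.na(win)) >= 6) means[s] <- mean(win, na.rm = TRUE)
  }
  if (sum(!is.na(means)) >= 13) max(means, na.rm = TRUE) else NA_real_
}
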