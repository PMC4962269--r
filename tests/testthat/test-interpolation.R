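test_that("simple average and degenerate single-monitor network", {
  expect_equal(as.numeric(simple_average(c(A = 10, B = 20, C = 30))), 20)
  expect_equal(as.numeric(simple_average(c(A = 42.2))), 42.2)
  expect_equal(as.numeric(simple_average(c(A = 10, B = NA))), 10)
  expect_error(simple_average(c(A = NA, B = NA)), class = "ozl_no_data")
})

test_that("nearest neighbor: zero distance, missing fallback, id tie-break", {
  net <- toy_network(3)  # M01 (0,0), M02 (6,0), M03 (3,5)
  v <- c(M01 = 10, M02 = 20, M03 = 30)
  expect_equal(nearest_neighbor(v, net, c(0, 0)), 10, ignore_attr = TRUE)
  # nearest (M01) missing -> next nearest (from (1,0): M02 at 5 km, M03 at 5.39 km)
  v2 <- c(M01 = NA, M02 = 20, M03 = 30)
  expect_equal(nearest_neighbor(v2, net, c(1, 0)), 20, ignore_attr = TRUE)
  # equidistant from M01 and M02 -> lowest id wins
  expect_equal(nearest_neighbor(v, net, c(3, 0)), 10, ignore_attr = TRUE)
})

test_that("IDW matches hand-computed 1/d weights and its limiting cases", {
  net <- monitor_network(c("A", "B"), c(1, 3), c(0, 0))
  # d = 1 and 3 from the origin: weights 3/4 and 1/4
  expect_equal(idw(c(A = 10, B = 20), net, c(0, 0)), 12.5, ignore_attr = TRUE)
  # power 2: weights 9/10, 1/10
  expect_equal(idw(c(A = 10, B = 20), net, c(0, 0), power = 2), 11,
               ignore_attr = TRUE)
  # equidistant monitors -> simple average
  net3 <- monitor_network(c("A", "B", "C"), c(1, -1, 0), c(0, 0, 1))
  expect_equal(idw(c(A = 10, B = 20, C = 60), net3, c(0, 0)), 30,
               ignore_attr = TRUE)
  # point at a monitor -> exactly its value
  expect_equal(idw(c(A = 10, B = 20), net, c(1, 0)), 10, ignore_attr = TRUE)
})

test_that("IDW weights sum to one (brute force on random instances)", {
  set.seed(3)
  for (i in 1:15) {
    n <- sample(2:8, 1)
    net <- monitor_network(sprintf("M%02d", 1:n), runif(n, 0, 20), runif(n, 0, 20))
    z <- runif(n, 10, 80); names(z) <- net$id
    p <- runif(2, 0, 20)
    d <- sqrt((net$x_km - p[1])^2 + (net$y_km - p[2])^2)
    w <- (1 / d) / sum(1 / d)
    expect_lt(abs(sum(w) - 1), 1e-12)
    expect_equal(idw(z, net, p), sum(w * z), ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("ordinary kriging matches a direct augmented-system solve", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(2:5, 1)
    xs <- runif(n, 0, 20); ys <- runif(n, 0, 20)
    z <- runif(n, 20, 70)
    c0 <- runif(1, 0, 10); c1 <- runif(1, 10, 120); a <- runif(1, 5, 25)
    p <- runif(2, 0, 20)
    net <- monitor_network(sprintf("M%02d", 1:n), xs, ys)
    names(z) <- net$id
    pred <- ordinary_kriging(z, net, variogram_model(c0, c1, a), p)
    orc <- ok_oracle(z, xs, ys, c0, c1, a, p[1], p[2])
    expect_equal(pred$value, orc$value, tolerance = 1e-8)
    expect_equal(pred$variance, max(orc$variance, 0), tolerance = 1e-6)
  }
})

test_that("kriging limit cases: pure nugget, exact interpolation, one monitor", {
  net <- toy_network(4)
  z <- c(M01 = 30, M02 = 50, M03 = 45, M04 = 60)
  # pure nugget -> equal weights -> network mean
  pn <- ordinary_kriging(z, net, variogram_model(8, 0, 10), c(2, 2))
  expect_equal(pn$value, mean(z), tolerance = 1e-10)
  # zero nugget -> exact interpolator at every monitor
  vm <- variogram_model(0, 100, 12)
  for (i in seq_len(nrow(net))) {
    pr <- ordinary_kriging(z, net, vm, c(net$x_km[i], net$y_km[i]))
    expect_equal(pr$value, unname(z[i]), tolerance = 1e-8)
    expect_equal(pr$variance, 0, tolerance = 1e-8)
  }
  expect_error(ordinary_kriging(c(M01 = 30), toy_network(1),
                                vm, c(1, 1)),
               class = "ozl_insufficient_data")
})

test_that("all methods agree on a single-monitor network and translate with the field", {
  net1 <- toy_network(1)
  pan1 <- constant_panel(net1, n_days = 2, value = 33)
  pts <- data.frame(x_km = c(1, 7), y_km = c(2, 2))
  for (m in c("simple_average", "nearest", "idw", "kriging")) {
    pr <- predict_all(pan1, net1, pts, method = m)
    expect_true(all(pr$values == 33), info = m)
  }

  # translation equivariance on a 4-monitor day
  net <- toy_network(4)
  z <- c(M01 = 30, M02 = 50, M03 = 45, M04 = 60)
  p <- c(4, 3); cshift <- 7.5
  vm <- variogram_model(3, 80, 10)
  expect_equal(as.numeric(simple_average(z + cshift)),
               as.numeric(simple_average(z)) + cshift)
  expect_equal(nearest_neighbor(z + cshift, net, p),
               nearest_neighbor(z, net, p) + cshift, ignore_attr = TRUE)
  expect_equal(idw(z + cshift, net, p), idw(z, net, p) + cshift,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(ordinary_kriging(z + cshift, net, vm, p)$value,
               ordinary_kriging(z, net, vm, p)$value + cshift,
               tolerance = 1e-10)

  # non-kriging predictions stay within the day's observed range
  set.seed(9)
  for (i in 1:10) {
    pt <- runif(2, -5, 15)
    expect_true(idw(z, net, pt) >= min(z) && idw(z, net, pt) <= max(z))
    expect_true(nearest_neighbor(z, net, pt) %in% z)
  }
})

test_that("predict_all on a constant panel returns the constant everywhere", {
  net <- toy_network(5)
  pan <- constant_panel(net, n_days = 4, value = 40)
  pts <- data.frame(x_km = runif(6, 0, 9), y_km = runif(6, 0, 9))
  for (m in c("simple_average", "nearest", "idw", "kriging")) {
    pr <- predict_all(pan, net, pts, method = m)
    expect_true(all(abs(pr$values - 40) < 1e-10), info = m)
  }
})

test_that("missing monitor-days are dropped, not imputed", {
  net <- toy_network(3)
  v <- matrix(c(10, 20, 30, NA, NA, NA), nrow = 3,
              dimnames = list(net$id, NULL))
  pan <- daily_panel(v, as.Date("2009-06-01") + 0:1)
  pr <- predict_all(pan, net, data.frame(x_km = 1, y_km = 1), method = "idw")
  expect_false(is.na(pr$values[1, 1]))
  expect_true(is.na(pr$values[1, 2]))
})
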