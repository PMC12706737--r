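test_that("distance regression recovers hand-computable fits", {
  # exactly linear in log10 distance: slope -4 per decade, perfect fit
  obs <- data.frame(distance_to_water = c(10, 100, 1000), value = c(10, 6, 2))
  fit <- distance_regression(obs)
  expect_equal(fit$slope, -4)
  expect_equal(fit$intercept, 14)
  expect_equal(fit$r2, 1)
  # constant response: zero slope, zero r2 by convention
  obs2 <- data.frame(distance_to_water = c(10, 100, 1000), value = c(5, 5, 5))
  fit2 <- distance_regression(obs2)
  expect_equal(fit2$slope, 0)
  expect_equal(fit2$r2, 0)
  # r2 invariant under affine rescaling of the response
  set.seed(31)
  obs3 <- data.frame(distance_to_water = 10^runif(20, 1, 3.5),
                     value = rnorm(20, 100, 20))
  obs4 <- obs3; obs4$value <- 3 * obs3$value + 7
  expect_equal(distance_regression(obs3)$r2, distance_regression(obs4)$r2,
               tolerance = 1e-12)
  # shuffled responses carry no signal on average
  set.seed(32)
  r2s <- replicate(30, {
    o <- obs3; o$value <- sample(o$value); distance_regression(o)$r2
  })
  expect_lt(mean(r2s), 0.15)
  expect_error(distance_regression(obs[1:2, ]), "at least 3")
  expect_error(distance_regression(
    data.frame(distance_to_water = c(10, 10, 10), value = 1:3)), "singular")
})

test_that("Moran's I matches brute-force evaluation and its null expectation", {
  # 5-point hand case with binary weights
  obs <- data.frame(x = c(0, 1, 2, 3, 4), y = 0, value = c(2, 4, 3, 8, 7))
  w <- (as.matrix(dist(cbind(obs$x, obs$y))) <= 1) * 1
  diag(w) <- 0
  out <- morans_i(obs, weights = w, n_perm = 199, seed = 2)
  # independent brute-force of I = (n/S0) sum w_ij z_i z_j / sum z_i^2
  wr <- w / rowSums(w)
  z <- obs$value - mean(obs$value)
  num <- 0
  for (i in 1:5) for (j in 1:5) num <- num + wr[i, j] * z[i] * z[j]
  i_hand <- (5 / sum(wr)) * num / sum(z^2)
  expect_equal(out$i, i_hand, tolerance = 1e-12)
  expect_equal(out$expected_i, -0.25)

  # cross-check against an independent implementation
  ape_i <- ape::Moran.I(obs$value, wr)
  expect_equal(out$i, ape_i$observed, tolerance = 1e-9)

  # spatially random values: I near -1/(n-1), permutation p not small
  set.seed(33)
  null_obs <- data.frame(x = runif(40), y = runif(40), value = rnorm(40))
  out0 <- morans_i(null_obs, n_perm = 499, seed = 3)
  expect_lt(abs(out0$i - out0$expected_i), 0.12)
  expect_gt(out0$p_perm, 0.05)
  # a strong gradient field is detected
  grad <- data.frame(x = runif(40), y = runif(40))
  grad$value <- grad$x * 10 + rnorm(40, 0, 0.5)
  outg <- morans_i(grad, n_perm = 499, seed = 4)
  expect_gt(outg$i, 0.2)
  expect_lt(outg$p_perm, 0.01)
  expect_error(morans_i(null_obs[1:3, ]), "at least 5")
  expect_error(morans_i(data.frame(x = c(1, 1, 2, 3, 4), y = 1,
                                   value = rnorm(5))), "coincident")
})

test_that("Moran permutation p-values are uniform under the null", {
  set.seed(34)
  ps <- replicate(120, {
    obs <- data.frame(x = runif(15), y = runif(15), value = rnorm(15))
    morans_i(obs, n_perm = 199, seed = sample.int(1e6, 1))$p_perm
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("kriging is exact at data points with weights that sum to one", {
  set.seed(35)
  obs <- data.frame(x = runif(12, 0, 1000), y = runif(12, 0, 1000))
  obs$value <- 50 + 0.02 * obs$x - 0.01 * obs$y + rnorm(12)
  vg <- structure(list(nugget = 0, psill = 4, range = 400,
                       model = "exponential"), class = "variogram_model")
  grid <- data.frame(x = c(obs$x, 123, 777), y = c(obs$y, 456, 222))
  ok <- ordinary_kriging(obs, grid = grid, variogram = vg,
                         return_weights = TRUE)
  # exact interpolation at the data locations (zero nugget)
  expect_equal(ok$predictions$pred[1:12], obs$value, tolerance = 1e-8)
  # unbiasedness constraint: weights sum to one everywhere
  expect_equal(rowSums(ok$weights), rep(1, nrow(grid)), tolerance = 1e-8)
  expect_true(all(is.finite(ok$loo$predicted)))
})

test_that("kriging a constant field returns the constant with zero error", {
  obs <- data.frame(x = 1:6, y = c(2, 5, 1, 7, 3, 9), value = 4.2)
  ok <- ordinary_kriging(obs, grid = data.frame(x = c(2.5, 8), y = c(3, 1)))
  expect_equal(ok$predictions$pred, c(4.2, 4.2))
  expect_equal(ok$loo_rmse, 0)
})

test_that("variogram recovery from a known random field is unbiased to ~30%", {
  # median of replicate estimates: a single-realization exponential range
  # estimate at n = 100 has large sampling spread, so recovery is judged on
  # the estimator's central tendency
  one <- function(seed, range_true = 500, dom = 6000, n = 100, sill = 2) {
    set.seed(seed)
    xy <- matrix(runif(2 * n, 0, dom), n)
    d <- as.matrix(dist(xy))
    z <- drop(chol(sill * exp(-d / range_true) + diag(1e-8, n)) %*% rnorm(n))
    vg <- fit_variogram(empirical_variogram(
      data.frame(x = xy[, 1], y = xy[, 2], value = z + 10), n_bins = 15))
    c(sill = vg$nugget + vg$psill, range = vg$range)
  }
  est <- t(vapply(1:24, one, c(sill = 0, range = 0)))
  expect_lt(abs(stats::median(est[, "sill"]) / 2 - 1), 0.3)
  expect_lt(abs(stats::median(est[, "range"]) / 500 - 1), 0.3)
})

test_that("rank-sum test gives exact and approximate p-values correctly", {
  # fully enumerated 3+3 case: most extreme split, two-sided p = 2/20
  out <- ranksum_test(c(1, 2, 3), c(10, 20, 30))
  expect_equal(out$p, 0.1)
  expect_identical(out$method, "exact")
  # identical groups: maximal p
  same <- ranksum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  # symmetric in the group order
  expect_equal(ranksum_test(c(10, 20, 30), c(1, 2, 3))$p, 0.1)
  # near-water vs far groups with a 4x median shift separate sharply
  set.seed(36)
  near <- 800 * exp(rnorm(12, 0, 0.4))
  far <- 200 * exp(rnorm(8, 0, 0.4))
  expect_lt(ranksum_test(near, far)$p, 0.005)
  expect_error(ranksum_test(1, c(1, 2)), "at least 2")
})
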