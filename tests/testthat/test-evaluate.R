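test_that("window_rmse matches hand computations", {
  expect_equal(window_rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(window_rmse(c(100, 100), c(103, 97)), 3)
  x <- rnorm(100)
  expect_equal(window_rmse(x, x + 2.5), 2.5)
  expect_error(window_rmse(1:3, 1:4), "length mismatch")
})

test_that("window_correlation handles affine, sign, and degenerate cases", {
  x <- rnorm(200)
  expect_equal(window_correlation(x, 2 * x + 5), 1)
  expect_equal(window_correlation(x, -x), -1)
  y <- rnorm(200)
  cov_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(window_correlation(x, y), cov_oracle, tolerance = 1e-12)
  z <- window_correlation(rep(1, 10), rnorm(10))
  expect_true(is.na(z))
  expect_true(isTRUE(attr(z, "zero_variance")))
})

test_that("align_fiducials matches spec-style hand cases", {
  p <- align_fiducials(c(100, 200, 300), c(105, 210))
  expect_equal(unname(p), matrix(c(100, 105, 200, 210), 2, byrow = TRUE))
  expect_equal(sum(abs(p[, 1] - p[, 2])), 15)
  eq <- align_fiducials(c(5, 10, 15), c(6, 11, 16))
  expect_equal(unname(eq[, "true"]), c(5, 10, 15))
  expect_equal(nrow(align_fiducials(c(1, 2), integer())), 0)
})

test_that("align_fiducials equals brute-force enumeration up to length 6", {
  set.seed(99)
  for (i in 1:150) {
    n <- sample(0:6, 1); m <- sample(0:6, 1)
    a <- sort(sample(1:200, n))
    b <- sort(sample(1:200, m))
    p <- align_fiducials(a, b)
    expect_equal(nrow(p), min(n, m))
    if (min(n, m) > 0)
      expect_equal(sum(abs(p[, 1] - p[, 2])), oracle_align_cost(a, b))
  }
})

test_that("bland_altman reports bias, precision, and the AAMI verdict", {
  ba0 <- bland_altman(c(120, 110), c(120, 110), n_boot = 50)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$sd, 0)
  expect_true(ba0$aami_pass)
  ba <- bland_altman(c(120, 110, 100), c(124, 112, 106), n_boot = 50)
  expect_equal(ba$bias, 4)
  expect_equal(ba$sd, 2)
  expect_true(ba$aami_pass)
  expect_equal(ba$points$diff, c(4, 2, 6))
  expect_equal(ba$points$mean, c(122, 111, 103))
  # constant difference of 6 mmHg: accurate SD but biased -> AAMI fail
  ba6 <- bland_altman(c(120, 110, 100), c(126, 116, 106), n_boot = 50)
  expect_equal(ba6$bias, 6)
  expect_false(ba6$aami_pass)
  expect_error(bland_altman(120, 124), "at least 2")
})

test_that("bland_altman bias is antisymmetric in its arguments", {
  set.seed(101)
  a <- rnorm(50, 120, 10); b <- a + rnorm(50, 2, 3)
  expect_equal(bland_altman(a, b, n_boot = 50)$bias,
               -bland_altman(b, a, n_boot = 50)$bias)
})

test_that("bootstrap_ci is deterministic, degenerate-safe, and CLT-sized", {
  v <- rnorm(200)
  ci1 <- bootstrap_ci(v, mean, seed = 4)
  ci2 <- bootstrap_ci(v, mean, seed = 4)
  expect_identical(ci1, ci2)
  same <- bootstrap_ci(rep(3.3, 10), mean, seed = 1)
  expect_equal(same, c(3.3, 3.3))
  set.seed(102)
  big <- rnorm(10000)
  ci <- bootstrap_ci(big, mean, n_boot = 500, seed = 5)
  expect_lt(ci[1], mean(big)); expect_gt(ci[2], mean(big))
  half <- (ci[2] - ci[1]) / 2
  expect_lt(abs(half - 1.96 / sqrt(10000)) / (1.96 / sqrt(10000)), 0.25)
  expect_error(bootstrap_ci(1), "at least 2")
})

test_that("error_vs_time_since_nibp bins at 10 s and flags empty bins", {
  single <- error_vs_time_since_nibp(rep(5, 4), c(1, 2, 3, 4))
  expect_equal(nrow(single), 1)
  expect_equal(single$rmse_mean, 2.5)
  t <- c(5, 15, 25, 35); r <- c(1, 2, 3, 4)
  tb <- error_vs_time_since_nibp(t, r)
  expect_equal(tb$rmse_mean, c(1, 2, 3, 4))
  expect_true(all(diff(tb$rmse_mean) > 0))
  gap <- error_vs_time_since_nibp(c(5, 25), c(1, 2))
  expect_true(is.na(gap$rmse_mean[2]))
  expect_equal(gap$n, c(1L, 0L, 1L))
  expect_equal(nrow(error_vs_time_since_nibp(numeric(0), numeric(0))), 0)
})

test_that("evaluate_predictions aggregates windows and beats coherently", {
  set.seed(103)
  truew <- t(replicate(6, 80 + 40 * pulse_train(32, 1.2) + rnorm(3200, 0.1)))
  pred <- truew + rnorm(length(truew), sd = 1)
  ev <- evaluate_predictions(truew, pred, t_since_s = rep(c(5, 15), 3),
                             n_boot = 50)
  expect_equal(ev$n_windows, 6)
  expect_gt(ev$n_beats, 100)
  expect_lt(ev$rmse_mean, 1.2)
  expect_gt(ev$corr_mean, 0.99)
  expect_true(ev$rmse_ci[1] <= ev$rmse_mean && ev$rmse_mean <= ev$rmse_ci[2])
  expect_true(ev$aami_pass)
  expect_equal(nrow(ev$error_vs_time), 2)
  # pooled RMSE invariant to window order
  ord <- c(4, 1, 6, 3, 2, 5)
  ev2 <- evaluate_predictions(truew[ord, ], pred[ord, ], n_boot = 50)
  expect_equal(sort(ev2$per_window$rmse), sort(ev$per_window$rmse))
})

test_that("bland_altman recovers an injected bias and spread at n = 10000", {
  set.seed(104)
  n <- 10000; b <- 3; sigma <- 4
  truev <- rnorm(n, 120, 10)
  predv <- truev + b + rnorm(n, 0, sigma)
  ba <- bland_altman(truev, predv, n_boot = 100)
  expect_lt(abs(ba$bias - b), 2 * sigma / sqrt(n))
  expect_lt(abs(ba$sd - sigma) / sigma, 0.10)
})
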