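# Conv-net engine kernels against plain-R double-precision references.
# The C++ kernels are single precision internally, so comparisons use
# float-level tolerances on O(1) inputs.

ref_conv_fw <- function(X, W, b, k, stride, pad) {
  C <- dim(X)[1]; L <- dim(X)[2]; N <- dim(X)[3]; Cout <- nrow(W)
  Lout <- (L + 2 * pad - k) %/% stride + 1
  Xp <- array(0, c(C, L + 2 * pad, N)); Xp[, pad + seq_len(L), ] <- X
  Y <- array(0, c(Cout, Lout, N))
  for (n in 1:N) for (j in 1:Lout) {
    colv <- numeric(C * k)
    for (tt in 1:k) for (c in 1:C)
      colv[(tt - 1) * C + c] <- Xp[c, (j - 1) * stride + tt, n]
    Y[, j, n] <- W %*% colv + b
  }
  Y
}

test_that("conv1d forward matches the double-precision reference", {
  set.seed(11)
  X <- array(rnorm(3 * 24 * 2), c(3, 24, 2))
  for (st in c(1L, 2L)) {
    k <- if (st == 1) 5L else 2L
    pad <- if (st == 1) 2L else 0L
    W <- matrix(rnorm(4 * 3 * k), 4)
    b <- rnorm(4)
    got <- abpwave:::cpp_conv1d_fw(X, W, b, k, st, pad, "")
    expect_equal(as.numeric(got), as.numeric(ref_conv_fw(X, W, b, k, st, pad)),
                 tolerance = 1e-5)
  }
})

test_that("conv1d backward gradients match central differences", {
  set.seed(12)
  X <- array(rnorm(2 * 16 * 2), c(2, 16, 2))
  W <- matrix(rnorm(3 * 2 * 5), 3); b <- rnorm(3)
  G <- array(rnorm(3 * 16 * 2), c(3, 16, 2))
  f <- function(X_, W_, b_) sum(abpwave:::cpp_conv1d_fw(X_, W_, b_, 5L, 1L, 2L, "") * G)
  bw <- abpwave:::cpp_conv1d_bw(X, W, G, 5L, 1L, 2L, "")
  h <- 1e-3
  for (kk in sample(length(W), 8)) {
    Wp <- W; Wp[kk] <- W[kk] + h; Wm <- W; Wm[kk] <- W[kk] - h
    expect_equal(bw$dw[kk], (f(X, Wp, b) - f(X, Wm, b)) / (2 * h),
                 tolerance = 5e-3)
  }
  for (kk in sample(length(X), 8)) {
    Xp <- X; Xp[kk] <- X[kk] + h; Xm <- X; Xm[kk] <- X[kk] - h
    expect_equal(bw$dx[kk], (f(Xp, W, b) - f(Xm, W, b)) / (2 * h),
                 tolerance = 5e-3)
  }
  expect_equal(as.numeric(bw$db), apply(G, 1, sum), tolerance = 1e-4)
})

test_that("transposed-convolution kernels match their references", {
  set.seed(13)
  Cin <- 3L; Cout <- 2L; L <- 6L; N <- 2L
  x <- array(rnorm(Cin * L * N), c(Cin, L, N))
  w <- matrix(rnorm(2 * Cout * Cin), 2 * Cout)   # row index t*Cout + c
  b <- rnorm(Cout)
  y <- abpwave:::cpp_upconv2_fw(x, w, b)
  yr <- array(0, c(Cout, 2 * L, N))
  for (n in 1:N) for (j in 1:L) for (t in 0:1) for (c in 1:Cout)
    yr[c, 2 * (j - 1) + t + 1, n] <- b[c] + sum(w[t * Cout + c, ] * x[, j, n])
  expect_equal(as.numeric(y), as.numeric(yr), tolerance = 1e-5)
  g <- array(rnorm(Cout * 2 * L * N), c(Cout, 2 * L, N))
  bw <- abpwave:::cpp_upconv2_bw(x, w, g)
  f <- function(w_, x_) sum(abpwave:::cpp_upconv2_fw(x_, w_, b) * g)
  h <- 1e-3
  for (kk in seq_along(w)) {
    wp <- w; wp[kk] <- w[kk] + h; wm <- w; wm[kk] <- w[kk] - h
    expect_equal(bw$dw[kk], (f(wp, x) - f(wm, x)) / (2 * h), tolerance = 5e-3)
  }
  for (kk in seq_along(x)) {
    xp <- x; xp[kk] <- x[kk] + h; xm <- x; xm[kk] <- x[kk] - h
    expect_equal(bw$dx[kk], (f(w, xp) - f(w, xm)) / (2 * h), tolerance = 5e-3)
  }
})

test_that("PReLU kernels equal the elementwise definition", {
  set.seed(14)
  a <- c(0.1, 0.5, 0.9)
  x <- array(rnorm(3 * 7 * 2), c(3, 7, 2))
  y <- abpwave:::cpp_prelu_fw(x, a)
  expect_equal(as.numeric(y),
               as.numeric(ifelse(x > 0, x, array(a, dim(x)) * x)))
  g <- array(rnorm(length(x)), dim(x))
  bw <- abpwave:::cpp_prelu_bw(x, a, g)
  expect_equal(as.numeric(bw$dx),
               as.numeric(g * ifelse(x > 0, 1, array(a, dim(x)))))
  da_ref <- rowSums(array(g * ifelse(x > 0, 0, x), dim(x)), dims = 1)
  expect_equal(as.numeric(bw$da), as.numeric(da_ref))
})

test_that("whole-network gradients drive a small V-Net to fit noise", {
  # end-to-end: if any layer's gradient were wrong, full-batch training
  # could not cut the loss by more than an order of magnitude
  set.seed(15)
  cfg <- abpwave:::vnet_config(in_channels = 3, input_len = 64, levels = 2,
                               base_filters = 4, convs_per_level = c(1, 2),
                               bottom_convs = 2, seed = 7)
  m <- build_vnet1d(cfg)
  X <- array(rnorm(3 * 64 * 8), c(3, 64, 8))
  R <- array(rnorm(64 * 8), c(1, 64, 8))
  opt <- abpwave:::nadam_new(m$params, lr = 3e-3)
  l0 <- NULL
  for (i in 1:300) {
    fw <- abpwave:::vnet_forward(m, X)
    l <- abpwave:::vnet_batch_loss(fw$out$val, R, integer(), cfg)
    if (i == 1) l0 <- l$loss
    abpwave:::nn_backward(fw$tape, fw$out, l$grad)
    abpwave:::nadam_step(opt, fw$tape$pgrads)
  }
  expect_lt(l$loss, l0 / 20)
})

test_that("a Nadam step reproduces the hand-computed update", {
  p <- abpwave:::nn_params()
  p[["w"]] <- 2
  opt <- abpwave:::nadam_new(p, lr = 0.1, beta1 = 0.9, beta2 = 0.999,
                             schedule_decay = 0.004, eps = 1e-7)
  g <- new.env(); g[["w"]] <- 0.5
  abpwave:::nadam_step(opt, g)
  mu1 <- 0.9 * (1 - 0.5 * 0.96^0.004)
  mu2 <- 0.9 * (1 - 0.5 * 0.96^0.008)
  m <- 0.1 * 0.5
  v <- 0.001 * 0.25
  g_hat <- 0.5 / (1 - mu1)
  m_hat <- m / (1 - mu1 * mu2)
  v_hat <- v / (1 - 0.999)
  m_bar <- (1 - mu1) * g_hat + mu2 * m_hat
  expect_equal(p[["w"]], 2 - 0.1 * m_bar / (sqrt(v_hat) + 1e-7),
               tolerance = 1e-12)
})
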