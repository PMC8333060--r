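# small configurations keep these structural tests fast
tiny_cfg <- function(...) {
  vnet_config(in_channels = 3, input_len = 128, levels = 2, base_filters = 4,
              convs_per_level = c(1, 2), bottom_convs = 2, batch = 4,
              seed = 7, ...)
}

tiny_windows <- function(n, cfg, patients = 2, resid_scale = 1, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    x <- matrix(rnorm(cfg$in_channels * cfg$input_len), cfg$in_channels)
    attr(x, "standardized") <- TRUE
    scaled <- 90 + 10 * sin(seq_len(cfg$input_len) / 10)
    r <- resid_scale * (2 * sin(seq_len(cfg$input_len) / 15 + i) +
                          0.5 * x[1, ])
    list(x = x, ppg_scaled = scaled, abp = scaled + r, r = r,
         fid = sort(sample(cfg$input_len, 5)),
         patient = paste0("p", (i %% patients) + 1))
  })
}

test_that("the network maps (C, L) input to a length-L single channel", {
  cfg <- tiny_cfg()
  m <- build_vnet1d(cfg)
  x <- array(rnorm(3 * 128 * 2), c(3, 128, 2))
  out <- abpwave:::vnet_forward(m, x)$out$val
  expect_equal(dim(out), c(1, 128, 2))
  # default config: (9, 3200) -> (1, 3200)
  m9 <- build_vnet1d(vnet_config(base_filters = 4, seed = 1))
  o9 <- abpwave:::vnet_forward(m9, array(0, c(9, 3200, 1)))$out$val
  expect_equal(dim(o9), c(1, 3200, 1))
  # 5 levels divide 3200; an indivisible length is refused
  expect_silent(vnet_config(levels = 5))
  expect_error(vnet_config(input_len = 3000, levels = 4), "divisible")
})

test_that("parameter initialization is deterministic for a fixed seed", {
  a <- build_vnet1d(tiny_cfg())
  b <- build_vnet1d(tiny_cfg())
  for (nm in ls(a$params)) expect_identical(a$params[[nm]], b$params[[nm]])
})

test_that("the two-part loss matches hand computations", {
  expect_equal(vnet_loss(c(1, 2, 3), c(1, 2, 3), 1L, 3L), 0)
  expect_equal(vnet_loss(c(0, 0, 0, 0), c(1, 1, 1, 1), c(1L), c(4L), 1), 2)
  expect_warning(l <- vnet_loss(c(0, 0), c(1, 3)), "no fiducial")
  expect_equal(l, 5)
  expect_error(vnet_loss(1:3, 1:4), "length mismatch")
  expect_error(vnet_loss(1:3, c(1, 2, 3), sys_idx = 9L), "out of range")
})

test_that("residual targets reconstruct the ABP exactly", {
  cfg <- tiny_cfg()
  w <- tiny_windows(4, cfg)
  for (wi in w) expect_identical(wi$abp, wi$ppg_scaled + wi$r)
})

test_that("a zero final layer predicts the PPG-scaling baseline exactly", {
  cfg <- tiny_cfg()
  m <- build_vnet1d(cfg)
  m$params[["final.w"]][] <- 0
  m$params[["final.b"]][] <- 0
  w <- tiny_windows(1, cfg)[[1]]
  pred <- predict_abp(m, w$x, w$ppg_scaled)
  expect_identical(pred, w$ppg_scaled)
})

test_that("prediction enforces the standardized-features contract", {
  cfg <- tiny_cfg()
  m <- build_vnet1d(cfg)
  w <- tiny_windows(1, cfg)[[1]]
  raw <- w$x
  attr(raw, "standardized") <- NULL
  expect_error(predict_abp(m, raw, w$ppg_scaled), "standardized")
  bad <- w$x
  bad[2, 5] <- NA
  expect_error(predict_abp(m, bad, w$ppg_scaled), "NaN|NA")
})

test_that("training decreases the loss and is deterministic by seed", {
  cfg <- tiny_cfg(max_epochs = 6, val_fraction = 0.25, lr = 3e-3)
  w <- tiny_windows(16, cfg, patients = 4)
  m1 <- train_vnet(build_vnet1d(cfg), w)
  m2 <- train_vnet(build_vnet1d(cfg), w)
  expect_equal(m1$history, m2$history, tolerance = 1e-12)
  expect_lt(m1$history$train_loss[6], m1$history$train_loss[1])
  # validation patients are never trained on
  expect_true(all(m1$val_patients %in% c("p1", "p2", "p3", "p4")))
})

test_that("early stopping fires after `patience` non-improving epochs", {
  # zero learning rate: the validation loss never improves after epoch 1
  cfg <- tiny_cfg(max_epochs = 50, patience = 8, lr = 0,
                  val_fraction = 0.25)
  w <- tiny_windows(8, cfg, patients = 4)
  m <- train_vnet(build_vnet1d(cfg), w)
  expect_equal(nrow(m$history), 9)  # best at 1, stops after 8 waiting epochs
})

test_that("fine_tune is a no-op at 0 epochs and guards split leakage", {
  cfg <- tiny_cfg(max_epochs = 2)
  w <- tiny_windows(8, cfg, patients = 2)
  m <- build_vnet1d(cfg)
  snap <- abpwave:::params_snapshot(m$params)
  m0 <- fine_tune(m, w, epochs = 0)
  for (nm in names(snap)) expect_identical(m0$params[[nm]], snap[[nm]])
  expect_error(fine_tune(m, w, epochs = 1, test_patients = "p1"),
               "split-integrity")
})
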