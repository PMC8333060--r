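test_that("derive_nibp samples the waveform every 5 minutes", {
  # 11-minute 120/80 pulse: ticks at 0, 300, 600 s
  abp <- 80 + 40 * pulse_train(660, 1.2)
  nibp <- derive_nibp(abp)
  expect_equal(length(nibp), 3)
  expect_equal(vapply(nibp, `[[`, numeric(1), "t"), c(0, 300, 600))
  for (s in nibp) {
    expect_true(s$derived)
    expect_lt(abs(s$sys - 120), 2)
    expect_lt(abs(s$dias - 80), 2)
  }
  # constant ABP: all ticks skipped
  expect_length(derive_nibp(rep(100, 66000)), 0)
})

test_that("fill_nibp returns the most recent sample and elapsed ms", {
  nibp <- list(nibp_sample(0, 120, 80, derived = TRUE),
               nibp_sample(300, 115, 75, derived = TRUE))
  f <- fill_nibp(160, nibp)
  expect_equal(f$nibp$sys, 120)
  expect_equal(f$t_since_ms, 160000)
  f2 <- fill_nibp(310, nibp)
  expect_equal(f2$nibp$sys, 115)
  expect_equal(f2$t_since_ms, 10000)
  expect_null(fill_nibp(10, list(nibp_sample(60, 120, 80))))
})

test_that("fill_nibp elapsed time is monotone between NIBP events", {
  nibp <- list(nibp_sample(0, 120, 80), nibp_sample(300, 115, 75))
  t_between <- seq(0, 290, by = 16)
  el <- vapply(t_between, function(t) fill_nibp(t, nibp)$t_since_ms,
               numeric(1))
  expect_true(all(diff(el) > 0))
})

test_that("compute_pat pairs R waves with subsequent PPG peaks", {
  fs <- 100
  t <- (0:3199) / fs
  ecg <- numeric(3200); ppg <- numeric(3200)
  r_times <- seq(1, 31, by = 1)
  for (r in r_times) {
    ecg <- ecg + exp(-((t - r) / 0.02)^2)
    ppg <- ppg + exp(-((t - r - 0.25) / 0.06)^2)
  }
  pat <- compute_pat(ecg, ppg)
  expect_equal(stats::median(pat$pat), 0.25, tolerance = 0.011)
  expect_equal(pat$median_log_pat, log(stats::median(pat$pat)))
})

test_that("PAT summary matches the small-sample oracle and bound rules", {
  # direct check of the summary arithmetic on {0.2, 0.25, 0.3}
  vals <- c(0.2, 0.25, 0.3)
  expect_equal(log(stats::median(vals)), log(0.25))
  expect_equal(stats::sd(vals), 0.05)
  # a single 0.05 s PAT is excluded -> summary missing
  fs <- 100
  t <- (0:3199) / fs
  ecg <- exp(-((t - 10) / 0.02)^2)
  ppg <- exp(-((t - 10.05) / 0.03)^2)
  pat <- compute_pat(ecg, ppg)
  expect_equal(pat$n_excluded, 1)
  expect_true(is.na(pat$median_log_pat))
  # bounds are retained when hit exactly
  ppg2 <- exp(-((t - 10.1) / 0.03)^2)
  pat2 <- compute_pat(ecg, ppg2)
  expect_equal(pat2$pat, 0.1)
})

test_that("compute_hr equals peak count scaled to bpm", {
  expect_equal(compute_hr(pulse_train(32, 1)), 60)
  expect_equal(compute_hr(pulse_train(32, 1.5)), 90)
  expect_equal(compute_hr(rep(0, 3200)), 0)
  # brute-force identity across generator rates
  for (f in c(0.6, 1, 1.7, 2.4)) {
    p <- pulse_train(32, f)
    expect_equal(compute_hr(p),
                 length(detect_peaks(p, "ppg_sys")) / 32 * 60)
  }
})

test_that("feature tensor has 9 channels with constant channels constant", {
  cfg <- make_clean_cohort_cfg(n_patients = 1, duration_s = 120)
  pr <- generate_record(cfg, "f1", 1)
  rec <- preprocess_record(pr$record)
  w <- slice_windows(rec)[2, ]
  x <- build_feature_tensor(window_samples(rec, w, "ecg"),
                            window_samples(rec, w, "ppg"),
                            nibp_sample(0, 120, 80), 16000)
  expect_equal(dim(x), c(9, 3200))
  expect_equal(rownames(x), feature_channels())
  for (ch in c("nibp_sys", "nibp_dias", "nibp_map", "pat_med_log", "hr"))
    expect_equal(length(unique(x[ch, ])), 1)
  # time-since channel is a ramp in ms
  expect_equal(unname(x["t_since_nibp", 1]), 16000)
  expect_equal(unname(diff(x["t_since_nibp", 1:2])), 10)
})

test_that("streaming standardization equals batch statistics", {
  set.seed(77)
  mk <- function() {
    x <- matrix(rnorm(9 * 3200), 9, 3200,
                dimnames = list(feature_channels(), NULL))
    x
  }
  tensors <- list(mk(), mk(), mk())
  tr <- fit_feature_transform(tensors)
  pooled <- do.call(cbind, tensors)
  expect_equal(unname(tr$mean), unname(rowMeans(pooled)), tolerance = 1e-10)
  expect_equal(unname(tr$sd), unname(apply(pooled, 1, sd)), tolerance = 1e-8)
  # frozen transform standardizes the training stream
  std <- lapply(tensors, function(x) apply_feature_transform(tr, x))
  spooled <- do.call(cbind, std)
  expect_lt(max(abs(rowMeans(spooled))), 1e-6)
  expect_lt(max(abs(apply(spooled, 1, sd) - 1)), 1e-6)
})

test_that("missing PAT/HR are imputed with the training median and
           constant channels are epsilon-guarded", {
  set.seed(78)
  mk <- function(pat) {
    x <- matrix(rnorm(9 * 100), 9, 100,
                dimnames = list(feature_channels(), NULL))
    x["pat_med_log", ] <- pat
    x["hr", ] <- 72          # constant channel -> zero SD guard
    x
  }
  tensors <- list(mk(-1.3), mk(NA), mk(-1.5))
  expect_warning(tr <- fit_feature_transform(tensors), "guarded")
  expect_equal(tr$impute[["pat_med_log"]], stats::median(c(-1.3, -1.5)))
  out <- apply_feature_transform(tr, mk(NA))
  expect_false(anyNA(out))
  expect_true(all(out["hr", ] == 0))  # constant channel scaled to zeros
  expect_true(isTRUE(attr(out, "standardized")))
})
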