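abp_wave <- function(rate_hz = 1.2, sys = 120, dias = 80, duration = 32) {
  dias + (sys - dias) * pulse_train(duration, rate_hz)
}

test_that("ECG/PPG rules: clean, flatline, spike-train windows", {
  clean <- pulse_train(32, 1.2) + rnorm(3200, sd = 0.01)
  expect_length(check_ecg_ppg_validity(clean, "ppg"), 0)
  flat <- rep(0.5, 3200)
  expect_setequal(check_ecg_ppg_validity(flat, "ppg"),
                  c("low_variance", "too_few_peaks"))
  # 5 Hz spike train: 160 peaks > 128 allowed
  t <- (0:3199) / 100
  spikes <- abs(sin(2 * pi * 5 * t))^30
  r <- check_ecg_ppg_validity(spikes, "ppg")
  expect_true("too_many_peaks" %in% r)
  expect_equal(length(detect_peaks(spikes, "ppg_sys")), 160)
})

test_that("ABP rules map each artifact class to its reason", {
  fs <- 100
  clean <- abp_wave() + rnorm(3200, sd = 0.1)
  expect_length(check_abp_validity(clean), 0)
  expect_true(mean(clean) > 90 && mean(clean) < 110)

  # mean out of bounds
  expect_true("mean_oob" %in% check_abp_validity(abp_wave(sys = 40, dias = 10)))
  # max out of bounds (too high) and min floor
  high <- abp_wave(sys = 320, dias = 100)
  expect_true("max_oob" %in% check_abp_validity(high))
  low <- abp_wave(sys = 80, dias = 15)
  expect_true("min_oob" %in% check_abp_validity(low))
  # low variance (noisy near-flat) and no beats (exactly flat)
  flatish <- rep(100, 3200) + rnorm(3200, sd = 0.5)
  expect_true("low_variance" %in% check_abp_validity(flatish))
  expect_true(all(c("low_variance", "no_beats", "flatline") %in%
                  check_abp_validity(rep(100, 3200))))
  # pulse pressure > 70: one beat at 160/85
  pp <- abp_wave(sys = 160, dias = 85)
  expect_true("high_pulse_pressure" %in% check_abp_validity(pp))
  # consecutive systolic jump > 50
  half <- abp_wave(rate_hz = 1, sys = 110, dias = 80, duration = 16)
  jump <- c(half, abp_wave(rate_hz = 1, sys = 165, dias = 80, duration = 16))
  expect_true("beat_jump" %in% check_abp_validity(jump))
  # flatline run of equal samples
  fl <- clean; fl[1000:1300] <- fl[1000]
  expect_true("flatline" %in% check_abp_validity(fl))
  # NIBP mismatch: window systolic 120 vs NIBP systolic 165
  expect_true("nibp_mismatch" %in%
              check_abp_validity(clean, nibp_sample(0, 165, 100)))
  expect_false("nibp_mismatch" %in%
               check_abp_validity(clean, nibp_sample(0, 125, 80)))
  # diastolic-to-systolic delay > 0.5 s (very slow upstroke)
  slow <- abp_wave(rate_hz = 0.6)  # trough-to-peak = 0.3/0.6Hz = 0.5 s
  slow2 <- 80 + 40 * pulse_train(32, 0.55, peak_frac = 0.4)
  expect_true("dias_sys_delay" %in% check_abp_validity(slow2))
})

test_that("cross-signal rules: identical trains, missing beat, offset", {
  ppg <- pulse_train(32, 1.25)
  abp <- 80 + 40 * pulse_train(32, 1.25)
  expect_length(check_cross_signal(ppg, abp), 0)
  # remove one interior beat from the PPG -> count mismatch
  ppg2 <- ppg
  pk <- detect_peaks(ppg, "ppg_sys")
  mid <- pk[20]
  ppg2[(mid - 40):(mid + 40)] <- 0
  expect_true("peak_count_mismatch" %in% check_cross_signal(ppg2, abp))
  # equal counts, uniform 0.2 s offset -> misalignment
  ppg3 <- shift_signal(ppg, 20)
  r <- check_cross_signal(ppg3, abp)
  expect_true("peak_time_misalignment" %in% r)
  expect_false("peak_count_mismatch" %in% r)
})

test_that("quantile outlier rule matches a sorted-quantile oracle", {
  set.seed(55)
  n <- 2000
  means <- cbind(ecg = rnorm(n), ppg = rnorm(n), abp = rnorm(n, 95, 2))
  means[17, "abp"] <- 950  # one gross outlier
  flagged <- quantile_outlier_filter(means)
  expect_true(flagged[17])
  # oracle: strict exceedance of type-7 quantiles per channel
  oracle <- rep(FALSE, n)
  for (j in 1:3) {
    v <- means[, j]
    oracle <- oracle | v > quantile(v, 0.999) | v < quantile(v, 0.0001)
  }
  expect_equal(flagged, oracle)
  # all means identical: nothing flagged
  same <- matrix(1, 1500, 3, dimnames = list(NULL, c("ecg", "ppg", "abp")))
  expect_false(any(quantile_outlier_filter(same)))
  # small cohort: rule skipped with a warning
  expect_warning(f <- quantile_outlier_filter(means[1:500, ]), "skipped")
  expect_false(any(f))
})

test_that("tightening thresholds never turns an invalid window valid", {
  cfg <- make_clean_cohort_cfg(n_patients = 2, duration_s = 180,
                               artifact_rates = c(flatline = 1, spike = 1,
                                                  dropout = 1,
                                                  clock_drift = 0))
  pr <- generate_record(cfg, "m1", 1)
  rec <- preprocess_record(pr$record, drift_segment_s = 120)
  nibp <- derive_nibp(rec$channels$abp, period_s = 120)
  loose <- filter_config()
  tight <- filter_config(pulse_pressure_max = 50, abp_var_min = 120,
                         consec_beat_jump_max = 25,
                         sbp_vs_nibp_diff_max = 20,
                         peaks_per_s_max = 3, peaks_per_s_min = 0.8,
                         peak_time_diff_max = 0.05)
  w_loose <- filter_record(rec, nibp, loose)
  w_tight <- filter_record(rec, nibp, tight)
  expect_false(any(!w_loose$valid & w_tight$valid))
})

test_that("filter_record records every fired rule and is deterministic", {
  cfg <- make_clean_cohort_cfg(n_patients = 1, duration_s = 180,
                               artifact_rates = c(flatline = 2, spike = 0,
                                                  dropout = 0,
                                                  clock_drift = 0))
  pr <- generate_record(cfg, "d1", 1)
  rec <- preprocess_record(pr$record, drift_segment_s = 120)
  nibp <- derive_nibp(rec$channels$abp, period_s = 120)
  w1 <- filter_record(rec, nibp)
  w2 <- filter_record(rec, nibp)
  expect_identical(w1$reasons, w2$reasons)
  rep <- rejection_report(w1)
  expect_equal(rep$n_windows, nrow(w1))
  expect_equal(rep$n_valid, sum(w1$valid))
})

test_that("records without ABP are filtered on the remaining rules", {
  cfg <- make_clean_cohort_cfg(n_patients = 1, duration_s = 120)
  pr <- generate_record(cfg, "i1", 1)
  rec <- pr$record
  rec$channels$abp <- NULL
  rec2 <- preprocess_record(rec)
  wins <- filter_record(rec2)
  expect_true(all(wins$valid))
  expect_true(all(is.na(wins$mean_abp)))
})

test_that("windows before the first NIBP are rejected with no_nibp", {
  cfg <- make_clean_cohort_cfg(n_patients = 1, duration_s = 120)
  pr <- generate_record(cfg, "n1", 1)
  rec <- preprocess_record(pr$record)
  nibp <- list(nibp_sample(60, 120, 80))
  wins <- filter_record(rec, nibp)
  early <- wins$start_t < 60
  expect_true(all(vapply(wins$reasons[early],
                         function(r) "no_nibp" %in% r, logical(1))))
})
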