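test_that("waveform_record enforces its invariants", {
  ok <- waveform_record("r1", 100, list(ecg = rnorm(100), ppg = rnorm(100)))
  expect_s3_class(ok, "waveform_record")
  expect_error(
    waveform_record("r1", 100, list(ecg = rnorm(100), ppg = rnorm(99))),
    "length mismatch")
  expect_error(
    waveform_record("r1", 100, list(ecg = rnorm(10), foo = rnorm(10))),
    "unknown channel")
  expect_error(
    waveform_record("r1", 100, list(ecg = rnorm(10), ppg = rnorm(10)),
                    nibp_events = list(nibp_sample(10, 120, 80),
                                       nibp_sample(5, 120, 80))),
    "non-decreasing")
})

test_that("nibp_sample validates pressure ordering", {
  s <- nibp_sample(0, 120, 80)
  expect_equal(s$map, (120 + 2 * 80) / 3)
  expect_error(nibp_sample(0, 80, 120), "sys >= map >= dias")
  expect_error(nibp_sample(0, 120, -5), "dias > 0")
})

test_that("tabular write-then-read round trip is bit-exact", {
  set.seed(5)
  rec <- waveform_record("rt-1", 100,
                         list(ecg = rnorm(600), ppg = rnorm(600),
                              abp = 90 + 10 * rnorm(600)))
  path <- tempfile(fileext = ".csv")
  write_record_tabular(rec, path)
  back <- load_record(path, "tabular")
  expect_identical(back$record_id, "rt-1")
  expect_identical(back$fs, 100)
  for (ch in names(rec$channels))
    expect_identical(back$channels[[ch]], rec$channels[[ch]])
})

test_that("two-channel tabular record loads with abp absent", {
  rec <- waveform_record("noabp", 100,
                         list(ecg = sin(1:6000 / 50), ppg = cos(1:6000 / 50)))
  path <- tempfile(fileext = ".csv")
  write_record_tabular(rec, path)
  back <- load_record(path, "tabular")
  expect_equal(length(back$channels$ecg), 6000)
  expect_null(back$channels$abp)
})

test_that("WFDB round trip maps II/PLETH/ABP and preserves samples to
           quantization precision", {
  set.seed(6)
  rec <- waveform_record("wf-1", 125,
                         list(ecg = rnorm(500), ppg = runif(500),
                              abp = 90 + 15 * sin(1:500 / 10)))
  stem <- tempfile()
  write_record_wfdb(rec, stem)
  back <- load_record(stem, "wfdb")
  expect_setequal(names(back$channels), c("ecg", "ppg", "abp"))
  expect_equal(back$fs, 125)
  for (ch in names(rec$channels)) {
    span <- diff(range(rec$channels[[ch]]))
    expect_lt(max(abs(back$channels[[ch]] - rec$channels[[ch]])),
              span / 30000)
  }
})

test_that("unmapped WFDB channels warn; missing ecg/ppg is an error", {
  rec <- waveform_record("wf-2", 100,
                         list(ecg = rnorm(100), ppg = rnorm(100)))
  stem <- tempfile()
  write_record_wfdb(rec, stem, names = c(ecg = "II", ppg = "RESP"))
  expect_warning(expect_error(load_record(stem, "wfdb"), "channel-mapping"),
                 "unmapped")
})

test_that("NIBP CSV round trip preserves events", {
  nibp <- list(nibp_sample(0, 121, 79), nibp_sample(300, 118, 76))
  path <- tempfile(fileext = ".csv")
  write_nibp_csv(nibp, path)
  back <- read_nibp_csv(path)
  expect_equal(length(back), 2)
  expect_equal(back[[2]]$sys, 118)
  expect_equal(back[[2]]$t, 300)
})

test_that("slice_windows matches the closed-form count and enumeration", {
  mk <- function(T) waveform_record("s", 100, list(ecg = numeric(T * 100),
                                                   ppg = numeric(T * 100)))
  w64 <- slice_windows(mk(64))
  expect_equal(nrow(w64), 3)
  expect_equal(w64$start_t, c(0, 16, 32))
  expect_equal(nrow(slice_windows(mk(32))), 1)
  expect_equal(nrow(slice_windows(mk(31))), 0)
  # closed-form count vs explicit enumeration for a range of durations
  for (T in c(32, 33, 47, 48, 100, 600)) {
    wins <- slice_windows(mk(T))
    starts <- seq(0, T - 32, by = 16)
    expect_equal(nrow(wins), length(starts))
    expect_equal(wins$start_t, starts)
    expect_true(all(wins$i1 - wins$i0 + 1 == 3200))
  }
  expect_error(slice_windows(waveform_record("s", 125,
                                             list(ecg = numeric(125 * 40),
                                                  ppg = numeric(125 * 40)))),
               "100 Hz")
})
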