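# Waveform normalization and temporal alignment.

#' Resample a signal to 100 Hz
#'
#' Rational-ratio polyphase FIR resampling with an anti-aliasing low-pass.
#' Only downsampling is supported: records sampled below 100 Hz cannot be
#' brought to the target rate without inventing information.
#'
#' @param x numeric signal.
#' @param fs_in input sampling rate (Hz), `>= 100`.
#' @return signal at 100 Hz with length `round(length(x) * 100 / fs_in)`.
#' @export
resample_to_100hz <- function(x, fs_in) {
  if (fs_in < 100)
    stop("unsupported rate: fs_in = ", fs_in, " Hz; only downsampling to ",
         "100 Hz is supported")
  if (fs_in == 100) return(x)
  if (abs(fs_in - round(fs_in)) > 1e-9)
    stop("unsupported rate: fs_in must be an integer number of Hz")
  fs_in <- round(fs_in)
  g <- gcd_int(100L, fs_in)
  p <- 100L %/% g
  q <- fs_in %/% g
  n <- length(x)
  # zero-stuff by p, apply a delay-compensated Kaiser-windowed sinc
  # low-pass (cutoff at the narrower of the two Nyquist limits), take
  # every q-th sample
  xu <- numeric(n * p)
  xu[seq(1, n * p, by = p)] <- x
  m <- max(p, q)
  K <- 10L
  L <- 2L * K * m + 1L
  k <- seq_len(L) - 1L - (L - 1L) / 2
  fc <- 0.5 / m
  h <- 2 * fc * ifelse(k == 0, 1, sin(2 * pi * fc * k) / (2 * pi * fc * k))
  h <- p * h * as.numeric(signal::kaiser(L, 8))
  pad <- (L - 1L) / 2
  yf <- stats::convolve(c(xu, numeric(pad)), rev(h), type = "open")
  yu <- yf[(pad + 1L):(pad + n * p)]             # group delay removed
  n_out <- round(n * 100 / fs_in)
  idx <- seq(1L, by = q, length.out = n_out)
  yu[pmin(idx, n * p)]
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Zero-phase 16 Hz low-pass filter
#'
#' 4th-order Butterworth applied forward-backward (`filtfilt`), so fiducial
#' timing is unchanged. The two-pass response attenuates 25 Hz by more than
#' 20 dB while keeping passband ripple below 1 dB under 12 Hz.
#'
#' @param x signal at 100 Hz.
#' @param fs sampling rate (Hz).
#' @param cutoff_hz cutoff frequency (Hz).
#' @return filtered signal, same length.
#' @export
lowpass_16hz <- function(x, fs = 100, cutoff_hz = 16) {
  if (anyNA(x))
    stop("NaN/NA in input at index ", which(is.na(x))[1])
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  n <- length(x)
  # odd-reflection padding removes the start/end transients of the
  # forward-backward pass (and keeps constants exactly constant)
  p <- min(n - 1, 3 * fs)
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(p + 1):(p + n)]
}

#' Median/IQR scaling of a window
#'
#' Subtracts the window median and divides by the inter-quartile range, so
#' scaled windows have median 0 and IQR 1 regardless of per-patient signal
#' range. Positive affine transforms of the input map to the same output.
#'
#' @param x window samples (at least two distinct values).
#' @return scaled samples.
#' @export
scale_window_median_iqr <- function(x) {
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- qs[3] - qs[1]
  if (iqr <= 0)
    stop("degenerate window: inter-quartile range is zero")
  (x - qs[2]) / iqr
}

#' Estimate and correct PPG clock drift against the ABP waveform
#'
#' Clock-synchronization drift between acquisition devices offsets the PPG
#' from the ABP. The lag applied to the PPG that maximizes the Pearson
#' cross-correlation with ABP is searched over +/- `max_lag_s`; correlation
#' is computed on mean-removed signals over an alignment segment (clock drift
#' is slow, so one lag per record segment suffices; a per-window lag would
#' absorb physiological pulse-arrival-time variation). Ties are broken toward
#' the smallest absolute lag.
#'
#' @param ppg,abp signals at `fs` Hz with overlapping span of at least 30 s.
#' @param fs sampling rate (Hz).
#' @param max_lag_s search bound (s).
#' @param segment_s alignment segment length (s); the first `segment_s`
#'   seconds are used.
#' @return list with `lag_s` (signed shift applied to the PPG), `peak_xcorr`,
#'   `search_bound_s`, and `ppg_shifted` (the PPG advanced/delayed by
#'   `lag_s`, edges padded with the boundary value).
#' @export
correct_signal_drift <- function(ppg, abp, fs = 100, max_lag_s = 4,
                                 segment_s = 300) {
  n <- min(length(ppg), length(abp))
  if (n < 30 * fs) stop("overlapping span must be at least 30 s")
  seg <- seq_len(min(n, round(segment_s * fs)))
  p <- ppg[seg] - mean(ppg[seg])
  a <- abp[seg] - mean(abp[seg])
  if (stats::sd(p) == 0 || stats::sd(a) == 0)
    stop("undefined correlation: constant input signal")
  max_lag <- round(max_lag_s * fs)
  lags <- -max_lag:max_lag
  cors <- vapply(lags, function(l) {
    # shifted ppg: ppg_shifted[i] = ppg[i - l]
    if (l >= 0) {
      i <- (1 + l):length(seg)
      suppressWarnings(stats::cor(p[i - l], a[i]))
    } else {
      i <- 1:(length(seg) + l)
      suppressWarnings(stats::cor(p[i - l], a[i]))
    }
  }, numeric(1))
  cors[is.na(cors)] <- -Inf
  best <- max(cors)
  cand <- which(cors >= best - 1e-12)
  lag <- lags[cand[which.min(abs(lags[cand]))]]
  list(lag_s = lag / fs, peak_xcorr = best, search_bound_s = max_lag_s,
       ppg_shifted = shift_signal(ppg, lag))
}

#' Shift a signal by an integer number of samples
#'
#' `y[i] = x[i - shift]`; positive shifts delay the signal. Shifted-out edges
#' are padded with the boundary value.
#' @param x signal.
#' @param shift integer sample shift.
#' @return shifted signal, same length.
#' @export
shift_signal <- function(x, shift) {
  n <- length(x)
  shift <- as.integer(round(shift))
  if (shift == 0) return(x)
  if (shift > 0) c(rep(x[1], shift), x[seq_len(n - shift)])
  else c(x[(1 - shift):n], rep(x[n], -shift))
}

#' Preprocess a record: resample, low-pass, drift-correct
#'
#' Applies the normalization chain to every channel (resampling to 100 Hz and
#' the 16 Hz zero-phase low-pass; the ABP target is filtered like the inputs,
#' which can smooth extreme systolic peaks slightly), then estimates and
#' removes PPG clock drift against the ABP when an ABP channel is present.
#' Per-window median/IQR scaling of ECG/PPG happens later, at feature-tensor
#' construction.
#'
#' @param record a [waveform_record()].
#' @param fs_target target rate (Hz).
#' @param drift_max_s,drift_segment_s drift-search parameters.
#' @param correct_drift apply the estimated lag to the PPG channel.
#' @return the preprocessed record, with a `drift` element
#'   (the [correct_signal_drift()] estimate, or `NULL` without ABP).
#' @export
preprocess_record <- function(record, fs_target = 100, drift_max_s = 4,
                              drift_segment_s = 300, correct_drift = TRUE) {
  ch <- lapply(record$channels, function(x) {
    y <- resample_to_100hz(x, record$fs)
    lowpass_16hz(y, fs = fs_target)
  })
  drift <- NULL
  if (!is.null(ch$abp) && correct_drift) {
    drift <- correct_signal_drift(ch$ppg, ch$abp, fs = fs_target,
                                  max_lag_s = drift_max_s,
                                  segment_s = drift_segment_s)
    ch$ppg <- drift$ppg_shifted
    drift$ppg_shifted <- NULL
  }
  out <- waveform_record(record$record_id, fs_target, ch,
                         start_time = record$start_time,
                         nibp_events = record$nibp_events)
  out$drift <- drift
  out
}
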