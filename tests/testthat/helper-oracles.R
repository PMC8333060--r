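# Independent brute-force oracles used across tests.

# synthetic 1 Hz-style pulse train with raised-cosine beats
pulse_train <- function(duration_s, rate_hz, fs = 100, peak_frac = 0.3) {
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  period <- 1 / rate_hz
  phase <- (t %% period) / period
  ifelse(phase < peak_frac,
         0.5 * (1 - cos(pi * phase / peak_frac)),
         cos(pi / 2 * (phase - peak_frac) / (1 - peak_frac))^2)
}

# sort-based median/IQR oracle (type-7 quantiles, like the implementation's
# contract, but assembled from first principles)
oracle_scale_median_iqr <- function(x) {
  s <- sort(x)
  n <- length(s)
  q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  (x - q(0.5)) / (q(0.75) - q(0.25))
}

# exhaustive threshold sweep: minimum observed score with PPV >= target
oracle_select_threshold <- function(scores, y, target) {
  best <- NA_real_
  for (t in sort(unique(scores))) {
    pos <- scores >= t
    if (sum(pos) > 0 && sum(y[pos]) / sum(pos) >= target) {
      best <- t
      break
    }
  }
  best
}

# brute-force order-preserving matchings of size min(n, m): minimal cost
oracle_align_cost <- function(a, b) {
  n <- length(a); m <- length(b)
  k <- min(n, m)
  if (k == 0) return(0)
  best <- Inf
  ai <- utils::combn(n, k, simplify = FALSE)
  bi <- utils::combn(m, k, simplify = FALSE)
  for (ia in ai) for (ib in bi) {
    cost <- sum(abs(a[ia] - b[ib]))
    if (cost < best) best <- cost
  }
  best
}

# brute-force local maxima + greedy tallest-first distance pruning
oracle_peaks <- function(x, min_dist) {
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  cand <- cand[order(-x[cand], cand)]
  taken <- integer()
  for (p in cand)
    if (!length(taken) || all(abs(taken - p) >= min_dist)) taken <- c(taken, p)
  sort(taken)
}

# FFT amplitude of the closest bin to a target frequency
fft_amplitude <- function(x, f, fs) {
  n <- length(x)
  sp <- abs(stats::fft(x)) / n * 2
  k <- round(f * n / fs) + 1
  sp[k]
}

make_clean_cohort_cfg <- function(n_patients = 3, duration_s = 240,
                                  seed = 101, ...) {
  sim_config(n_patients = n_patients, duration_s = duration_s,
             seed = seed, ...)
}
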