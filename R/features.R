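# Constant-per-window model input channels: derived NIBP, time-since-NIBP,
# pulse arrival time, heart rate; feature-tensor assembly and the frozen
# running standardization transform.

#' Channel order of the model input tensor
#' @return character vector of the 9 channel names.
#' @export
feature_channels <- function() {
  c("ecg", "ppg", "nibp_sys", "nibp_dias", "nibp_map",
    "t_since_nibp", "pat_med_log", "pat_sd", "hr")
}

#' Derive NIBP samples from the ABP waveform
#'
#' Emulates intermittent cuff readings by sampling the invasive waveform:
#' at each tick (every `period_s` seconds) the median per-beat systolic and
#' diastolic pressures and the mean ABP over a `subwin_s`-second segment
#' anchored at the tick are emitted. Ticks whose segment fails beat
#' detection (or runs past the record end) are skipped.
#'
#' @param abp ABP signal (mmHg) at `fs` Hz.
#' @param fs sampling rate (Hz).
#' @param period_s tick spacing (s); 300 s emulates 5-minute cuff cycling.
#' @param subwin_s segment length per tick (s).
#' @return list of [nibp_sample()] with `derived = TRUE` (possibly empty).
#' @export
derive_nibp <- function(abp, fs = 100, period_s = 300, subwin_s = 4) {
  stopifnot(length(abp) >= subwin_s * fs)
  out <- list()
  ticks <- seq(0, length(abp) / fs, by = period_s)
  for (t in ticks) {
    i0 <- round(t * fs) + 1L
    i1 <- i0 + subwin_s * fs - 1L
    if (i1 > length(abp)) next
    seg <- abp[i0:i1]
    beats <- annotate_beats(seg, fs = fs)
    if (!length(beats$sys_idx) || !length(beats$dias_idx)) next
    sys <- stats::median(beats$sys_val)
    dias <- stats::median(beats$dias_val)
    m <- mean(seg)
    if (!(sys >= m && m >= dias)) m <- (sys + 2 * dias) / 3
    out[[length(out) + 1L]] <- nibp_sample(t, sys, dias, m, derived = TRUE)
  }
  out
}

#' Most recent NIBP sample for a window
#'
#' @param start_t window start time (s).
#' @param nibp list of [nibp_sample()] in non-decreasing time order.
#' @return `NULL` when no sample exists at or before `start_t` (the caller
#'   rejects such windows with reason `no_nibp`); otherwise a list with
#'   `nibp` (the latest sample with `t <= start_t`) and `t_since_ms`.
#' @export
fill_nibp <- function(start_t, nibp) {
  if (!length(nibp)) return(NULL)
  tt <- vapply(nibp, `[[`, numeric(1), "t")
  k <- findInterval(start_t, tt)
  if (k < 1) return(NULL)
  list(nibp = nibp[[k]], t_since_ms = (start_t - tt[k]) * 1000)
}

#' Pulse arrival time summary for a window
#'
#' Each ECG R peak is paired with the first PPG systolic peak strictly after
#' it (and before the next R peak); the delay in seconds is the PAT. Values
#' outside the plausible band are excluded (bounds retained: exactly 0.1 or
#' 1.0 s survive). The summary is the log of the median PAT and the sample
#' SD of the raw PATs; with no valid PATs both are `NA` and are imputed
#' later with the training-stream median.
#'
#' @param ecg,ppg window samples.
#' @param fs sampling rate (Hz).
#' @param bounds_s retained PAT interval (s).
#' @return list with `pat` (retained values, s), `median_log_pat`, `pat_sd`,
#'   `n_excluded`.
#' @export
compute_pat <- function(ecg, ppg, fs = 100, bounds_s = c(0.1, 1.0)) {
  r_idx <- detect_peaks(ecg, "ecg_r", fs = fs)
  p_idx <- detect_peaks(ppg, "ppg_sys", fs = fs)
  pats <- numeric(0)
  if (length(r_idx) && length(p_idx)) {
    nxt_r <- c(r_idx[-1], Inf)
    for (i in seq_along(r_idx)) {
      p <- p_idx[p_idx > r_idx[i] & p_idx < nxt_r[i]]
      if (length(p)) pats <- c(pats, (p[1] - r_idx[i]) / fs)
    }
  }
  keep <- pats >= bounds_s[1] & pats <= bounds_s[2]
  kept <- pats[keep]
  list(pat = kept,
       median_log_pat = if (length(kept)) log(stats::median(kept)) else NA_real_,
       pat_sd = if (length(kept) > 1) stats::sd(kept) else NA_real_,
       n_excluded = sum(!keep))
}

#' Heart rate of a window from the PPG
#'
#' Peak count divided by the window duration in seconds, times 60.
#' @param ppg window samples.
#' @param fs sampling rate (Hz).
#' @param window_s window duration (s).
#' @return heart rate in bpm (0 when no peaks are found; flagged `NA`-like
#'   missing downstream when 0).
#' @export
compute_hr <- function(ppg, fs = 100, window_s = length(ppg) / fs) {
  length(detect_peaks(ppg, "ppg_sys", fs = fs)) / window_s * 60
}

#' Assemble the 9-channel feature tensor for one window
#'
#' Per-timestep channels (median/IQR-scaled ECG and PPG) plus constant
#' channels repeated along time: NIBP systolic/diastolic/mean, time since
#' the NIBP reading (a per-sample ramp in ms, since the elapsed time differs
#' across the 32 s of the window), the log-median PAT, the PAT SD, and the
#' heart rate. PAT/HR may be `NA` here; imputation happens inside the frozen
#' standardization transform.
#'
#' @param ecg,ppg preprocessed window samples (unscaled; scaling applied
#'   internally).
#' @param nibp the most recent [nibp_sample()].
#' @param t_since_ms elapsed ms from the NIBP reading to the window start.
#' @param fs sampling rate (Hz).
#' @return matrix `9 x length(ecg)` with rownames [feature_channels()].
#' @export
build_feature_tensor <- function(ecg, ppg, nibp, t_since_ms, fs = 100) {
  n <- length(ecg)
  stopifnot(length(ppg) == n)
  pat <- compute_pat(ecg, ppg, fs = fs)
  hr <- compute_hr(ppg, fs = fs)
  x <- matrix(0, 9, n, dimnames = list(feature_channels(), NULL))
  x["ecg", ] <- scale_window_median_iqr(ecg)
  x["ppg", ] <- scale_window_median_iqr(ppg)
  x["nibp_sys", ] <- nibp$sys
  x["nibp_dias", ] <- nibp$dias
  x["nibp_map", ] <- nibp$map
  x["t_since_nibp", ] <- t_since_ms + (seq_len(n) - 1) / fs * 1000
  x["pat_med_log", ] <- pat$median_log_pat
  x["pat_sd", ] <- pat$pat_sd
  x["hr", ] <- if (hr > 0) hr else NA_real_
  x
}

#' Fit the frozen feature standardization transform
#'
#' Accumulates running per-channel mean and SD over the training stream in
#' record order (one streaming pass; the frozen result equals the full-pass
#' statistics) and running medians of the observed PAT/HR summaries for
#' imputing windows where they are missing. The frozen transform is then
#' applied unchanged to validation and test windows, so no test statistics
#' leak into training.
#'
#' @param tensors list of feature tensors from [build_feature_tensor()], in
#'   training-stream order.
#' @param eps variance guard for near-constant channels.
#' @return a `feature_transform` with `mean`, `sd`, `impute` (per-channel
#'   medians for `pat_med_log`, `pat_sd`, `hr`).
#' @export
fit_feature_transform <- function(tensors, eps = 1e-8) {
  stopifnot(length(tensors) >= 2)
  ch <- feature_channels()
  imp_ch <- c("pat_med_log", "pat_sd", "hr")
  obs <- stats::setNames(vector("list", length(imp_ch)), imp_ch)
  for (x in tensors)
    for (nm in imp_ch) if (!is.na(x[nm, 1])) obs[[nm]] <- c(obs[[nm]], x[nm, 1])
  impute <- vapply(obs, function(v) if (length(v)) stats::median(v) else 0,
                   numeric(1))
  # streaming accumulation (Welford) per channel over all samples
  n <- numeric(length(ch)); mu <- numeric(length(ch)); m2 <- numeric(length(ch))
  names(n) <- names(mu) <- names(m2) <- ch
  for (x in tensors) {
    x <- impute_tensor(x, impute)
    for (j in seq_along(ch)) {
      v <- x[j, ]
      k <- length(v); d <- mean(v) - mu[j]
      tot <- n[j] + k
      mu[j] <- mu[j] + d * k / tot
      m2[j] <- m2[j] + sum((v - mean(v))^2) + d^2 * n[j] * k / tot
      n[j] <- tot
    }
  }
  sdv <- sqrt(m2 / pmax(n - 1, 1))
  low <- sdv < eps
  if (any(low))
    warning("near-constant feature channel(s) guarded: ",
            paste(ch[low], collapse = ", "), call. = FALSE)
  structure(list(mean = mu, sd = pmax(sdv, eps), impute = impute),
            class = "feature_transform")
}

impute_tensor <- function(x, impute) {
  for (nm in names(impute)) if (is.na(x[nm, 1])) x[nm, ] <- impute[[nm]]
  x
}

#' Apply a frozen feature transform
#'
#' @param transform a [fit_feature_transform()] result.
#' @param x one feature tensor (9 x n).
#' @return standardized tensor (attribute `standardized = TRUE`).
#' @export
apply_feature_transform <- function(transform, x) {
  x <- impute_tensor(x, transform$impute)
  out <- (x - transform$mean) / transform$sd
  attr(out, "standardized") <- TRUE
  out
}
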