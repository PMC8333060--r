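# Window-validity rules with per-rule rejection audit.
#
# Every rule is evaluated (not just the first to fire), so rejection reports
# can attribute counts to each rule. Validity is the absence of any reason.

#' Window-filtering configuration
#'
#' Thresholds of the artifact rejection rules. The ECG/PPG variance floor and
#' peak-rate bounds apply to the normalized inputs; the ABP bounds are in
#' mmHg on the unnormalized target. The peak-rate bounds 4/s and 0.5/s
#' correspond to heart-rate limits of 240 and 30 bpm. The quantile bounds are
#' asymmetric (99.9% upper, 0.01% lower) by design.
#'
#' @param ecg_ppg_var_min variance floor for ECG and PPG.
#' @param peaks_per_s_max,peaks_per_s_min allowed peak rates (peaks/s).
#' @param abp_mean_range,abp_max_range allowed window mean / maximum (mmHg).
#' @param abp_min_floor minimum allowed ABP sample (mmHg).
#' @param abp_var_min ABP variance floor (mmHg^2).
#' @param consec_beat_jump_max largest allowed jump between consecutive
#'   systolic (or diastolic) values (mmHg).
#' @param flat_run_len a run of this many equal consecutive ABP samples
#'   counts as a flatline.
#' @param pulse_pressure_max largest allowed per-beat pulse pressure (mmHg).
#' @param sbp_vs_nibp_diff_max largest allowed gap between the window's
#'   median systolic pressure and the most recent NIBP systolic (mmHg).
#' @param dias_to_sys_delay_max longest allowed diastolic-trough to
#'   systolic-peak delay (s).
#' @param peak_time_diff_max largest allowed mean PPG-vs-ABP peak time
#'   difference (s), after drift correction.
#' @param quantile_hi,quantile_lo cohort outlier quantiles on window means.
#' @param quantile_min_windows smallest cohort for which the quantile rule
#'   is applied.
#' @return a `filter_config` list.
#' @export
filter_config <- function(ecg_ppg_var_min = 1e-4,
                          peaks_per_s_max = 4,
                          peaks_per_s_min = 0.5,
                          abp_mean_range = c(30, 200),
                          abp_max_range = c(60, 300),
                          abp_min_floor = 20,
                          abp_var_min = 80,
                          consec_beat_jump_max = 50,
                          flat_run_len = 2,
                          pulse_pressure_max = 70,
                          sbp_vs_nibp_diff_max = 40,
                          dias_to_sys_delay_max = 0.5,
                          peak_time_diff_max = 0.15,
                          quantile_hi = 0.999,
                          quantile_lo = 0.0001,
                          quantile_min_windows = 1000) {
  cfg <- as.list(environment())
  stopifnot(ecg_ppg_var_min > 0, peaks_per_s_max > peaks_per_s_min,
            abp_mean_range[1] < abp_mean_range[2],
            abp_max_range[1] < abp_max_range[2],
            quantile_lo < quantile_hi)
  class(cfg) <- "filter_config"
  cfg
}

#' ECG/PPG validity rules for one window
#'
#' @param x window samples (ECG or PPG).
#' @param kind `"ecg"` or `"ppg"` (selects the fiducial detector).
#' @param cfg a [filter_config()].
#' @param fs sampling rate (Hz).
#' @param window_s window duration (s).
#' @return character vector of fired reasons, subset of
#'   `low_variance`, `too_many_peaks`, `too_few_peaks`.
#' @export
check_ecg_ppg_validity <- function(x, kind = c("ecg", "ppg"), cfg = filter_config(),
                                   fs = 100, window_s = length(x) / fs) {
  kind <- match.arg(kind)
  reasons <- character()
  if (stats::var(x) < cfg$ecg_ppg_var_min) reasons <- c(reasons, "low_variance")
  pk <- detect_peaks(x, if (kind == "ecg") "ecg_r" else "ppg_sys", fs = fs)
  if (length(pk) > cfg$peaks_per_s_max * window_s)
    reasons <- c(reasons, "too_many_peaks")
  if (length(pk) < cfg$peaks_per_s_min * window_s)
    reasons <- c(reasons, "too_few_peaks")
  reasons
}

has_flat_run <- function(x, run_len) {
  if (run_len < 2) return(TRUE)
  r <- rle(x)
  any(r$lengths >= run_len)
}

#' ABP validity rules for one window
#'
#' Each clause of the artifact rule list maps to exactly one reason code.
#'
#' @param abp ABP window samples (mmHg), unnormalized.
#' @param last_nibp most recent [nibp_sample()] at or before the window start,
#'   or `NULL` (the NIBP-mismatch rule is then skipped).
#' @param cfg a [filter_config()].
#' @param fs sampling rate (Hz).
#' @return character vector of fired reasons, subset of `mean_oob`,
#'   `max_oob`, `min_oob`, `low_variance`, `no_beats`, `beat_jump`,
#'   `flatline`, `high_pulse_pressure`, `nibp_mismatch`, `dias_sys_delay`.
#' @export
check_abp_validity <- function(abp, last_nibp = NULL, cfg = filter_config(),
                               fs = 100) {
  reasons <- character()
  m <- mean(abp)
  if (m < cfg$abp_mean_range[1] || m > cfg$abp_mean_range[2])
    reasons <- c(reasons, "mean_oob")
  mx <- max(abp)
  if (mx > cfg$abp_max_range[2] || mx < cfg$abp_max_range[1])
    reasons <- c(reasons, "max_oob")
  if (min(abp) < cfg$abp_min_floor) reasons <- c(reasons, "min_oob")
  if (stats::var(abp) < cfg$abp_var_min) reasons <- c(reasons, "low_variance")
  beats <- annotate_beats(abp, fs = fs)
  if (!length(beats$sys_idx) || !length(beats$dias_idx)) {
    reasons <- c(reasons, "no_beats")
  } else {
    if ((length(beats$sys_val) > 1 &&
         any(abs(diff(beats$sys_val)) > cfg$consec_beat_jump_max)) ||
        (length(beats$dias_val) > 1 &&
         any(abs(diff(beats$dias_val)) > cfg$consec_beat_jump_max)))
      reasons <- c(reasons, "beat_jump")
    if (length(beats$pulse_pressure) &&
        any(beats$pulse_pressure > cfg$pulse_pressure_max))
      reasons <- c(reasons, "high_pulse_pressure")
    if (!is.null(last_nibp) &&
        abs(stats::median(beats$sys_val) - last_nibp$sys) >
          cfg$sbp_vs_nibp_diff_max)
      reasons <- c(reasons, "nibp_mismatch")
    # delay from each diastolic trough to the next systolic peak; troughs
    # within 0.25 s of the window edge belong to beats the window truncates
    # and carry no upstroke-timing information
    guard <- round(0.25 * fs)
    whole <- beats$pp_dias_idx > guard
    if (any(whole) &&
        any((beats$pp_sys_idx[whole] - beats$pp_dias_idx[whole]) / fs >
              cfg$dias_to_sys_delay_max))
      reasons <- c(reasons, "dias_sys_delay")
  }
  if (has_flat_run(abp, cfg$flat_run_len)) reasons <- c(reasons, "flatline")
  reasons
}

#' Cross-signal agreement rules for one window
#'
#' Assumes drift correction has already been applied to the PPG. Systolic
#' peaks of the two channels are paired order-preservingly by proximity
#' (beats whose peaks lie within 0.25 s of each other — residual offsets
#' after drift correction are far smaller than a beat period).
#' `peak_count_mismatch` fires when either channel has an unpaired peak in
#' the window interior; unpaired peaks within 0.25 s of a window edge
#' belong to beats the window truncates — an artifact of windowing, not of
#' the signals — and are tolerated. `peak_time_misalignment` fires when the
#' mean absolute time difference over the paired peaks exceeds the
#' threshold.
#'
#' @param ppg,abp window samples.
#' @param cfg a [filter_config()].
#' @param fs sampling rate (Hz).
#' @return character vector of fired reasons, subset of
#'   `peak_count_mismatch`, `peak_time_misalignment`.
#' @export
check_cross_signal <- function(ppg, abp, cfg = filter_config(), fs = 100) {
  ppg_pk <- detect_peaks(ppg, "ppg_sys", fs = fs)
  abp_pk <- detect_peaks(abp, "abp_sys", fs = fs)
  if (!length(ppg_pk) && !length(abp_pk)) return(character())
  guard <- round(0.25 * fs)
  cap <- round(0.25 * fs)
  n <- length(ppg)
  # order-preserving two-pointer proximity pairing
  i <- 1L; j <- 1L
  dts <- numeric(0)
  un_a <- integer(0); un_p <- integer(0)
  while (i <= length(abp_pk) && j <= length(ppg_pk)) {
    d <- abp_pk[i] - ppg_pk[j]
    if (abs(d) <= cap) {
      dts <- c(dts, abs(d)); i <- i + 1L; j <- j + 1L
    } else if (d < 0) {
      un_a <- c(un_a, abp_pk[i]); i <- i + 1L
    } else {
      un_p <- c(un_p, ppg_pk[j]); j <- j + 1L
    }
  }
  if (i <= length(abp_pk)) un_a <- c(un_a, abp_pk[i:length(abp_pk)])
  if (j <= length(ppg_pk)) un_p <- c(un_p, ppg_pk[j:length(ppg_pk)])
  unpaired <- c(un_a, un_p)
  reasons <- character()
  if (any(unpaired > guard & unpaired <= n - guard))
    reasons <- c(reasons, "peak_count_mismatch")
  if (length(dts) && mean(dts) / fs > cfg$peak_time_diff_max)
    reasons <- c(reasons, "peak_time_misalignment")
  reasons
}

#' Cohort-level quantile outlier rule
#'
#' Windows whose per-channel mean exceeds the cohort's upper quantile or
#' falls below its lower quantile (of that channel's window means) are
#' flagged. Applied per cohort over candidate windows that passed all prior
#' rules; skipped with a warning for small cohorts, where extreme quantiles
#' are unstable.
#'
#' @param window_means matrix or data.frame of window means, one column per
#'   channel (`ecg`, `ppg`, `abp`), one row per window.
#' @param cfg a [filter_config()].
#' @return logical vector: `TRUE` where the window is a quantile outlier.
#' @export
quantile_outlier_filter <- function(window_means, cfg = filter_config()) {
  window_means <- as.matrix(window_means)
  n <- nrow(window_means)
  if (n < cfg$quantile_min_windows) {
    warning("quantile outlier rule skipped: ", n, " windows < ",
            cfg$quantile_min_windows, call. = FALSE)
    return(rep(FALSE, n))
  }
  flagged <- rep(FALSE, n)
  for (j in seq_len(ncol(window_means))) {
    v <- window_means[, j]
    qhi <- stats::quantile(v, cfg$quantile_hi, names = FALSE)
    qlo <- stats::quantile(v, cfg$quantile_lo, names = FALSE)
    flagged <- flagged | v > qhi | v < qlo
  }
  flagged
}

#' Apply all window-validity rules to a record
#'
#' Slices the record into 32-s windows and evaluates the rules in order:
#' ECG/PPG rules, ABP rules (skipped without an ABP channel), cross-signal
#' rules, NIBP availability, then the PPG quality index when a model is
#' supplied. All fired reasons are recorded; the cohort-level quantile rule
#' is applied separately (see [quantile_outlier_filter()]) because it pools
#' windows across records.
#'
#' @param record preprocessed, drift-corrected [waveform_record()] at 100 Hz.
#' @param nibp list of [nibp_sample()] (may be empty; the NIBP-dependent
#'   rules are then skipped).
#' @param cfg a [filter_config()].
#' @param qi_model optional fitted [train_qi_model()] model.
#' @param qi_threshold QI threshold; defaults to the model's selected one.
#' @param window_s,step_s windowing parameters.
#' @return data.frame of windows (as [slice_windows()]) with added columns:
#'   `valid`, `reasons` (list column), `qi_min`, `mean_ecg`, `mean_ppg`,
#'   `mean_abp`.
#' @export
filter_record <- function(record, nibp = list(), cfg = filter_config(),
                          qi_model = NULL, qi_threshold = NULL,
                          window_s = 32, step_s = 16) {
  wins <- slice_windows(record, window_s = window_s, step_s = step_s)
  n <- nrow(wins)
  reasons <- vector("list", n)
  qi_min <- rep(NA_real_, n)
  mean_ecg <- mean_ppg <- mean_abp <- rep(NA_real_, n)
  has_abp <- !is.null(record$channels$abp)
  if (is.null(qi_threshold) && !is.null(qi_model))
    qi_threshold <- qi_model$threshold
  for (i in seq_len(n)) {
    w <- wins[i, ]
    ecg <- window_samples(record, w, "ecg")
    ppg <- window_samples(record, w, "ppg")
    re <- check_ecg_ppg_validity(ecg, "ecg", cfg, record$fs)
    rp <- check_ecg_ppg_validity(ppg, "ppg", cfg, record$fs)
    r <- c(if (length(re)) paste0("ecg_", re),
           if (length(rp)) paste0("ppg_", rp))
    mean_ecg[i] <- mean(ecg); mean_ppg[i] <- mean(ppg)
    if (has_abp) {
      abp <- window_samples(record, w, "abp")
      mean_abp[i] <- mean(abp)
      fill <- fill_nibp(w$start_t, nibp)
      last_nibp <- if (is.null(fill)) NULL else fill$nibp
      r <- c(r, check_abp_validity(abp, last_nibp, cfg, record$fs))
      r <- c(r, check_cross_signal(ppg, abp, cfg, record$fs))
    }
    if (length(nibp) && is.null(fill_nibp(w$start_t, nibp)))
      r <- c(r, "no_nibp")
    if (!is.null(qi_model)) {
      qi <- window_min_qi(ppg, qi_model)
      qi_min[i] <- qi$min
      if (qi$min < qi_threshold) r <- c(r, "low_qi")
    }
    reasons[[i]] <- r
  }
  wins$valid <- lengths(reasons) == 0
  wins$reasons <- reasons
  wins$qi_min <- qi_min
  wins$mean_ecg <- mean_ecg
  wins$mean_ppg <- mean_ppg
  wins$mean_abp <- mean_abp
  wins
}

#' Apply the cohort quantile rule to filtered windows
#'
#' Appends the `mean_quantile_outlier` reason to windows flagged by
#' [quantile_outlier_filter()], computed over the windows that passed all
#' prior rules, and updates their validity.
#'
#' @param windows row-bound output of [filter_record()] across a cohort.
#' @param cfg a [filter_config()].
#' @return `windows` with updated `valid` and `reasons`.
#' @export
apply_quantile_filter <- function(windows, cfg = filter_config()) {
  cand <- which(windows$valid)
  if (!length(cand)) return(windows)
  cols <- intersect(c("mean_ecg", "mean_ppg", "mean_abp"), names(windows))
  m <- as.matrix(windows[cand, cols])
  m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
  flagged <- quantile_outlier_filter(m, cfg)
  for (i in cand[flagged]) {
    windows$reasons[[i]] <- c(windows$reasons[[i]], "mean_quantile_outlier")
    windows$valid[i] <- FALSE
  }
  windows
}

#' Per-rule rejection report
#'
#' @param windows output of [filter_record()] (optionally row-bound).
#' @return list with `n_windows`, `n_valid`, and a named vector of per-rule
#'   firing counts.
#' @export
rejection_report <- function(windows) {
  all_reasons <- unlist(windows$reasons)
  list(n_windows = nrow(windows),
       n_valid = sum(windows$valid),
       rule_counts = if (length(all_reasons)) sort(table(all_reasons),
                                                   decreasing = TRUE)
                     else table(character()))
}
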