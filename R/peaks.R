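# Deterministic fiducial-point detection.

#' Detect peaks (or troughs) in a waveform window
#'
#' Local maxima are kept if their topographic prominence exceeds
#' `prominence_frac` of the window's amplitude range, then pruned so that no
#' two retained peaks are closer than `min_dist_s` (0.2 s by default — the
#' detector must resolve rates above the 4 peaks/s (240 bpm) rejection
#' bound, otherwise the too-many-peaks rule could never observe a count
#' over its own threshold); pruning keeps the taller peak, with
#' ties broken toward the earlier index. The result is deterministic for a
#' fixed input. `kind = "abp_dias"` detects troughs (peaks of the negated
#' signal).
#'
#' @param x window samples.
#' @param kind fiducial type: `ecg_r`, `ppg_sys`, `abp_sys`, or `abp_dias`.
#' @param fs sampling rate (Hz).
#' @param min_dist_s minimum inter-peak distance (s).
#' @param prominence_frac prominence floor as a fraction of the window range.
#' @return increasing integer vector of 1-based sample indices (may be empty).
#' @export
detect_peaks <- function(x, kind = c("ecg_r", "ppg_sys", "abp_sys",
                                     "abp_dias"),
                         fs = 100, min_dist_s = 0.2,
                         prominence_frac = 0.25) {
  kind <- match.arg(kind)
  if (kind == "abp_dias") x <- -x
  n <- length(x)
  if (n < 3) return(integer())
  rng <- max(x) - min(x)
  if (rng == 0) return(integer())

  # strict local maxima; on plateaus keep the first sample
  dx <- diff(x)
  up <- c(dx > 0, FALSE)
  dn <- c(FALSE, dx < 0)
  flat <- c(FALSE, dx == 0)
  # a peak: rises into i and the next non-flat move after i is down
  cand <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(cand)) return(integer())

  prom <- vapply(cand, function(p) peak_prominence(x, p), numeric(1))
  keep <- cand[prom >= prominence_frac * rng]
  if (!length(keep)) return(integer())

  # distance pruning, tallest first (ties: earlier index first)
  min_dist <- round(min_dist_s * fs)
  ord <- keep[order(-x[keep], keep)]
  taken <- integer()
  for (p in ord) {
    if (!length(taken) || all(abs(taken - p) >= min_dist))
      taken <- c(taken, p)
  }
  sort(taken)
}

# topographic prominence: height above the higher of the two key saddles
# (minimum between the peak and the nearest higher ground on each side).
# A side whose walk runs into the window edge without meeting higher ground
# belongs to a truncated beat; that side is ignored so that edge beats keep
# their full prominence regardless of how fast each channel decays.
peak_prominence <- function(x, p) {
  n <- length(x)
  left_min <- x[p]
  left_closed <- FALSE
  i <- p
  while (i > 1L) {
    i <- i - 1L
    if (x[i] < left_min) left_min <- x[i]
    if (x[i] > x[p]) { left_closed <- TRUE; break }
  }
  right_min <- x[p]
  right_closed <- FALSE
  i <- p
  while (i < n) {
    i <- i + 1L
    if (x[i] < right_min) right_min <- x[i]
    if (x[i] > x[p]) { right_closed <- TRUE; break }
  }
  if (left_closed && right_closed) x[p] - max(left_min, right_min)
  else if (left_closed) x[p] - left_min
  else if (right_closed) x[p] - right_min
  else x[p] - max(left_min, right_min)
}

#' Annotate beats on an ABP window
#'
#' Detects systolic peaks and diastolic troughs, pairs each systolic peak
#' with the preceding diastolic trough, and reports per-beat pressures and
#' pulse pressures.
#'
#' @param abp ABP window samples (mmHg).
#' @param fs sampling rate (Hz).
#' @return list with `sys_idx`, `dias_idx`, `sys_val`, `dias_val`, and
#'   per-beat `pulse_pressure` (systolic minus preceding diastolic value;
#'   systolic peaks without a preceding trough are skipped).
#' @export
annotate_beats <- function(abp, fs = 100) {
  sys_idx <- detect_peaks(abp, "abp_sys", fs = fs)
  dias_idx <- detect_peaks(abp, "abp_dias", fs = fs)
  pp <- numeric(0)
  pp_sys_idx <- integer(0)
  pp_dias_idx <- integer(0)
  for (s in sys_idx) {
    prev <- dias_idx[dias_idx < s]
    if (length(prev)) {
      d <- max(prev)
      pp <- c(pp, abp[s] - abp[d])
      pp_sys_idx <- c(pp_sys_idx, s)
      pp_dias_idx <- c(pp_dias_idx, d)
    }
  }
  list(sys_idx = sys_idx, dias_idx = dias_idx,
       sys_val = abp[sys_idx], dias_val = abp[dias_idx],
       pulse_pressure = pp, pp_sys_idx = pp_sys_idx,
       pp_dias_idx = pp_dias_idx)
}
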