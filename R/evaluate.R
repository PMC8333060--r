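# Device-agreement and waveform-quality metrics.

#' Window RMSE between true and predicted waveforms
#' @param y_true,y_pred waveforms (equal length), mmHg.
#' @return root mean square error (mmHg).
#' @export
window_rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("length mismatch: ", length(y_true), " vs ", length(y_pred))
  sqrt(mean((y_true - y_pred)^2))
}

#' Window Pearson correlation between true and predicted waveforms
#' @param y_true,y_pred waveforms with nonzero variance.
#' @return correlation in `[-1, 1]`, or `NA` with attribute
#'   `zero_variance = TRUE` when undefined (the window is then skipped in
#'   aggregation).
#' @export
window_correlation <- function(y_true, y_pred) {
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0)
    return(structure(NA_real_, zero_variance = TRUE))
  stats::cor(y_true, y_pred)
}

#' Order-preserving alignment of fiducial index lists
#'
#' When the true and predicted waveforms yield different numbers of
#' systolic (or diastolic) points, beats are paired by the order-preserving
#' matching of size `min(length(true), length(pred))` that minimizes the sum
#' of absolute index differences, computed exactly by dynamic programming;
#' ties are broken toward earlier pairs.
#'
#' @param true_idx,pred_idx strictly increasing index vectors.
#' @return integer matrix with columns `true`, `pred`, one row per pair
#'   (possibly zero rows).
#' @export
align_fiducials <- function(true_idx, pred_idx) {
  n <- length(true_idx); m <- length(pred_idx)
  if (n == 0 || m == 0)
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("true", "pred"))))
  swapped <- n > m
  a <- if (swapped) pred_idx else true_idx   # shorter list: all matched
  b <- if (swapped) true_idx else pred_idx
  n <- length(a); m <- length(b)
  INF <- .Machine$double.xmax / 4
  D <- matrix(INF, n + 1, m + 1)
  D[1, ] <- 0
  for (i in seq_len(n)) {
    for (j in i:m) {
      D[i + 1, j + 1] <- min(D[i, j] + abs(a[i] - b[j]), D[i + 1, j])
    }
  }
  # traceback; on ties prefer skipping the later b (earlier pairs matched)
  pairs <- matrix(0L, n, 2)
  i <- n; j <- m
  while (i > 0) {
    if (j > i && D[i + 1, j + 1] == D[i + 1, j]) {
      j <- j - 1
    } else {
      pairs[i, ] <- c(a[i], b[j])
      i <- i - 1; j <- j - 1
    }
  }
  if (swapped) pairs <- pairs[, 2:1, drop = FALSE]
  dimnames(pairs) <- list(NULL, c("true", "pred"))
  pairs
}

#' Bootstrap percentile confidence interval
#'
#' @param values numeric vector (`length >= 2`).
#' @param stat statistic to bootstrap (function).
#' @param n_boot number of resamples.
#' @param seed RNG seed (deterministic result for a fixed seed).
#' @param level confidence level.
#' @return numeric `c(lo, hi)` percentile interval.
#' @export
bootstrap_ci <- function(values, stat = mean, n_boot = 1000, seed = 1L,
                         level = 0.95) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values for a bootstrap CI")
  with_seed(derive_seed(seed, 4L), {
    reps <- vapply(seq_len(n_boot), function(i)
      stat(values[sample.int(n, n, replace = TRUE)]), numeric(1))
    a <- (1 - level) / 2
    stats::quantile(reps, c(a, 1 - a), names = FALSE)
  })
}

#' Bland-Altman agreement analysis of paired pressures
#'
#' Differences are `pred - true` (so a positive systolic bias means
#' overestimation). Reports accuracy (mean difference), precision (sample
#' SD of the differences), bootstrap percentile CIs of both, the
#' difference-versus-mean point table, and the AAMI verdict
#' (`|mean| < 5` mmHg and `SD < 8` mmHg).
#'
#' @param true,pred paired per-beat pressures (mmHg), `length >= 2`.
#' @param n_boot,seed bootstrap settings.
#' @return list with `bias`, `sd`, `bias_ci`, `sd_ci`, `aami_pass`,
#'   `points` (data.frame `mean`, `diff`), `n`.
#' @export
bland_altman <- function(true, pred, n_boot = 1000, seed = 1L) {
  stopifnot(length(true) == length(pred))
  if (length(true) < 2) stop("need at least 2 pairs")
  d <- pred - true
  bias <- mean(d)
  sdd <- stats::sd(d)
  list(bias = bias, sd = sdd,
       bias_ci = bootstrap_ci(d, mean, n_boot = n_boot, seed = seed),
       sd_ci = bootstrap_ci(d, stats::sd, n_boot = n_boot,
                            seed = seed + 1L),
       aami_pass = abs(bias) < 5 && sdd < 8,
       points = data.frame(mean = (true + pred) / 2, diff = d),
       n = length(d))
}

#' Error binned by time since the last NIBP reading
#'
#' @param t_since_s per-window elapsed time since the most recent NIBP (s).
#' @param rmse per-window RMSE values (mmHg).
#' @param bin_s bin width (s).
#' @return data.frame with `bin_lo`, `bin_hi`, `n`, `rmse_mean`, `rmse_sd`
#'   (`NA` for empty bins).
#' @export
error_vs_time_since_nibp <- function(t_since_s, rmse, bin_s = 10) {
  stopifnot(length(t_since_s) == length(rmse))
  if (!length(t_since_s))
    return(data.frame(bin_lo = numeric(), bin_hi = numeric(), n = integer(),
                      rmse_mean = numeric(), rmse_sd = numeric()))
  k <- floor(t_since_s / bin_s)
  kk <- 0:max(k)
  data.frame(
    bin_lo = kk * bin_s,
    bin_hi = (kk + 1) * bin_s,
    n = vapply(kk, function(b) sum(k == b), integer(1)),
    rmse_mean = vapply(kk, function(b)
      if (any(k == b)) mean(rmse[k == b]) else NA_real_, numeric(1)),
    rmse_sd = vapply(kk, function(b)
      if (sum(k == b) > 1) stats::sd(rmse[k == b]) else NA_real_, numeric(1))
  )
}

#' Evaluate predicted ABP waveforms against the arterial-line truth
#'
#' Computes per-window RMSE and correlation with bootstrap CIs of their
#' means, extracts per-beat systolic and diastolic pressures from both
#' waveforms with [detect_peaks()], aligns them with [align_fiducials()],
#' and runs the pooled Bland-Altman analysis on each. Beats that fail
#' alignment are excluded and counted.
#'
#' @param y_true matrix of true ABP windows (one row per window, mmHg).
#' @param y_pred matrix of predicted windows (same shape).
#' @param t_since_s optional per-window time since NIBP (s) for the
#'   time-binned error table.
#' @param fs sampling rate (Hz).
#' @param n_boot,seed bootstrap settings.
#' @return an `agreement_summary` list: `rmse_mean`, `rmse_ci`, `corr_mean`,
#'   `corr_ci`, `sys` and `dias` Bland-Altman results, `aami_pass`,
#'   `n_windows`, `n_beats`, `n_beats_excluded`, `per_window` data.frame,
#'   and `error_vs_time` (when `t_since_s` given).
#' @export
evaluate_predictions <- function(y_true, y_pred, t_since_s = NULL, fs = 100,
                                 n_boot = 1000, seed = 1L) {
  stopifnot(is.matrix(y_true), all(dim(y_true) == dim(y_pred)))
  n <- nrow(y_true)
  rmse <- numeric(n); corr <- rep(NA_real_, n)
  sys_t <- sys_p <- dias_t <- dias_p <- numeric(0)
  n_excluded <- 0L
  for (i in seq_len(n)) {
    yt <- y_true[i, ]; yp <- y_pred[i, ]
    rmse[i] <- window_rmse(yt, yp)
    corr[i] <- window_correlation(yt, yp)
    for (kind in c("abp_sys", "abp_dias")) {
      ti <- detect_peaks(yt, kind, fs = fs)
      pi <- detect_peaks(yp, kind, fs = fs)
      pairs <- align_fiducials(ti, pi)
      n_excluded <- n_excluded + (max(length(ti), length(pi)) - nrow(pairs))
      if (!nrow(pairs)) next
      if (kind == "abp_sys") {
        sys_t <- c(sys_t, yt[pairs[, "true"]])
        sys_p <- c(sys_p, yp[pairs[, "pred"]])
      } else {
        dias_t <- c(dias_t, yt[pairs[, "true"]])
        dias_p <- c(dias_p, yp[pairs[, "pred"]])
      }
    }
  }
  corr_ok <- !is.na(corr)
  sys_ba <- if (length(sys_t) >= 2)
    bland_altman(sys_t, sys_p, n_boot = n_boot, seed = seed) else NULL
  dias_ba <- if (length(dias_t) >= 2)
    bland_altman(dias_t, dias_p, n_boot = n_boot, seed = seed + 2L) else NULL
  out <- list(
    rmse_mean = mean(rmse),
    rmse_ci = bootstrap_ci(rmse, mean, n_boot = n_boot, seed = seed + 3L),
    corr_mean = mean(corr[corr_ok]),
    corr_ci = if (sum(corr_ok) >= 2)
      bootstrap_ci(corr[corr_ok], mean, n_boot = n_boot, seed = seed + 4L)
      else c(NA_real_, NA_real_),
    sys = sys_ba, dias = dias_ba,
    aami_pass = !is.null(sys_ba) && !is.null(dias_ba) &&
      sys_ba$aami_pass && dias_ba$aami_pass,
    n_windows = n,
    n_beats = length(sys_t),
    n_beats_excluded = n_excluded,
    per_window = data.frame(rmse = rmse, corr = corr)
  )
  if (!is.null(t_since_s))
    out$error_vs_time <- error_vs_time_since_nibp(t_since_s, rmse)
  class(out) <- "agreement_summary"
  out
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("<agreement_summary: %d windows, %d beats>\n", x$n_windows,
              x$n_beats))
  cat(sprintf("  RMSE %.3f (%.3f-%.3f) mmHg, correlation %.3f\n",
              x$rmse_mean, x$rmse_ci[1], x$rmse_ci[2], x$corr_mean))
  if (!is.null(x$sys))
    cat(sprintf("  systolic  %+.3f +/- %.3f mmHg\n", x$sys$bias, x$sys$sd))
  if (!is.null(x$dias))
    cat(sprintf("  diastolic %+.3f +/- %.3f mmHg\n", x$dias$bias, x$dias$sd))
  cat(sprintf("  AAMI (<5 +/- 8 mmHg): %s\n",
              if (x$aami_pass) "pass" else "fail"))
  invisible(x)
}
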