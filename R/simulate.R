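# Physiologically structured ECG/PPG/ABP simulator with ground truth.
#
# The simulator's job is statistical structure, not hemodynamic realism: it
# produces pulsatile ABP with per-beat systolic/diastolic levels following a
# slow random walk, a PPG whose beat morphology is a smooth monotone transform
# of the ABP beat shape whose systolic peak trails each ECG R wave by the true
# pulse arrival time, and an ECG R-wave spike train. Artifacts (flatline,
# spike bursts, pressure dropouts, clock drift) are injected at configurable
# rates and logged with their intervals, so filtering tests have exact ground
# truth.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so simulation helpers do not
#' perturb surrounding stochastic code.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

#' Simulation configuration
#'
#' Defaults are chosen so that artifact-free records pass every window filter:
#' diastolic levels and pulse pressures keep the ABP mean, extrema, variance
#' and per-beat pulse pressure inside the validity bands, heart rates sit well
#' inside the 30--240 bpm peak-count bounds, and the pulse arrival time lies
#' in the retained 0.1--1.0 s interval.
#'
#' @param n_patients number of simulated patients.
#' @param duration_s record length in seconds.
#' @param fs sampling rate in Hz (the pipeline's target rate).
#' @param hr_range heart-rate range in bpm, drawn per patient.
#' @param dbp_range diastolic pressure base range (mmHg).
#' @param pp_range pulse-pressure base range (mmHg); kept below the 70 mmHg
#'   rejection bound and high enough that ABP window variance exceeds
#'   80 mmHg^2.
#' @param bp_drift_sd random-walk standard deviation of the per-beat
#'   diastolic level, in mmHg per sqrt-minute.
#' @param pat_range pulse arrival time range (s), drawn per patient.
#' @param ppg_morph list of PPG morphology parameters: `peak_frac` (systolic
#'   peak position as a fraction of the beat), `decay_pow` (decay shape
#'   exponent), `gain_sd` (slow multiplicative gain drift), `identity`
#'   (if `TRUE` the PPG is an exact affine copy of the ABP: the zero-residual
#'   regime in which PPG scaling reconstructs the ABP).
#' @param artifact_rates expected number of artifacts per record, by type
#'   (`flatline`, `spike`, `dropout`, `clock_drift`).
#' @param artifact_duration_s min/max artifact duration (s).
#' @param noise_sd list of additive noise SDs per channel (ECG/PPG unitless,
#'   ABP in mmHg).
#' @param label_flip_rate label noise rate for the QI training-set generator,
#'   emulating imperfect manual labels (clinician agreement about 94%).
#' @param seed base seed; per-patient streams are derived from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_patients = 20,
                       duration_s = 600,
                       fs = 100,
                       hr_range = c(60, 100),
                       dbp_range = c(62, 78),
                       pp_range = c(38, 58),
                       bp_drift_sd = 1.5,
                       pat_range = c(0.12, 0.38),
                       ppg_morph = list(peak_frac = c(0.25, 0.33),
                                        decay_pow = c(1.0, 1.5),
                                        gain_sd = 0.03,
                                        identity = FALSE),
                       artifact_rates = c(flatline = 0, spike = 0,
                                          dropout = 0, clock_drift = 0),
                       artifact_duration_s = c(20, 40),
                       noise_sd = list(ecg = 0.02, ppg = 0.01, abp = 0.2),
                       label_flip_rate = 0.06,
                       seed = 1L) {
  stopifnot(n_patients >= 1, duration_s > 0, fs > 0,
            hr_range[1] <= hr_range[2], dbp_range[1] <= dbp_range[2],
            pp_range[1] <= pp_range[2], pat_range[1] >= 0.1,
            pat_range[2] <= 1.0)
  cfg <- list(n_patients = n_patients, duration_s = duration_s, fs = fs,
              hr_range = hr_range, dbp_range = dbp_range, pp_range = pp_range,
              bp_drift_sd = bp_drift_sd, pat_range = pat_range,
              ppg_morph = ppg_morph, artifact_rates = artifact_rates,
              artifact_duration_s = artifact_duration_s, noise_sd = noise_sd,
              label_flip_rate = label_flip_rate, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# beat shape on phase u in [0,1): raised-cosine systolic upstroke peaking at
# `up`, cosine-squared decay with a dicrotic-notch shoulder.
abp_beat_shape <- function(u, up = 0.25, notch_amp = 0.08) {
  s <- numeric(length(u))
  r <- u < up
  s[r] <- 0.5 * (1 - cos(pi * u[r] / up))
  v <- (u[!r] - up) / (1 - up)
  s[!r] <- cos(pi * v / 2)^2 + notch_amp * exp(-((v - 0.35) / 0.08)^2)
  s
}

ppg_beat_shape <- function(u, up, decay_pow) {
  s <- numeric(length(u))
  r <- u < up
  s[r] <- 0.5 * (1 - cos(pi * u[r] / up))
  v <- (u[!r] - up) / (1 - up)
  s[!r] <- cos(pi * v / 2)^2 * exp(-decay_pow * v)
  s
}

# piecewise-beat evaluation: onset[i] is the start of beat i; samples before
# the first onset reuse beat 1, after the last reuse the final beat.
eval_beats <- function(t, onsets, fun_per_beat) {
  nb <- length(onsets) - 1L
  j <- findInterval(t, onsets)
  j[j < 1L] <- 1L
  j[j > nb] <- nb
  u <- (t - onsets[j]) / (onsets[j + 1L] - onsets[j])
  u <- pmin(pmax(u, 0), 1 - 1e-9)
  fun_per_beat(j, u)
}

#' Generate one synthetic patient record with ground truth
#'
#' @param cfg a [sim_config()].
#' @param patient_id identifier string; also indexes the per-patient seed
#'   stream via its numeric suffix (or pass `patient_index`).
#' @param patient_index integer used to derive the patient's seed.
#' @return list with elements `record` (a [waveform_record()]) and `truth`
#'   (beat table with R-wave times, systolic/diastolic pressures, true PAT;
#'   artifact log; true PPG clock-drift delay).
#' @export
generate_record <- function(cfg, patient_id = "sim-1", patient_index = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, patient_index), {
    fs <- cfg$fs
    n <- round(cfg$duration_s * fs)
    t <- (seq_len(n) - 1L) / fs

    hr <- stats::runif(1, cfg$hr_range[1], cfg$hr_range[2])
    rr0 <- 60 / hr
    nb <- ceiling(cfg$duration_s / rr0) + 4L
    rr <- rr0 * (1 + stats::rnorm(nb, sd = 0.015))
    r_t <- cumsum(c(0.3 * rr0, rr[-nb]))
    keep <- r_t < cfg$duration_s + 2 * rr0
    r_t <- r_t[keep]; rr <- rr[keep]
    nb <- length(r_t)

    pat0 <- stats::runif(1, cfg$pat_range[1], cfg$pat_range[2])
    pat <- pmin(pmax(pat0 + stats::rnorm(nb, sd = 0.004), 0.1), 1.0)

    dbp0 <- stats::runif(1, cfg$dbp_range[1], cfg$dbp_range[2])
    pp0 <- stats::runif(1, cfg$pp_range[1], cfg$pp_range[2])
    step_sd <- cfg$bp_drift_sd * sqrt(rr / 60)
    dbp <- dbp0 + cumsum(stats::rnorm(nb, sd = step_sd))
    dbp <- pmin(pmax(dbp, cfg$dbp_range[1] - 8), cfg$dbp_range[2] + 8)
    pp <- pp0 + cumsum(stats::rnorm(nb, sd = 0.5 * step_sd))
    pp <- pmin(pmax(pp, 34), 64)
    sys <- dbp + pp

    up_abp <- 0.25
    # ABP systolic peak coincides with the PPG systolic peak at R + PAT
    abp_on <- r_t + pat - up_abp * rr
    abp_onsets <- c(abp_on, abp_on[nb] + rr[nb])
    abp <- eval_beats(t, abp_onsets, function(j, u)
      dbp[j] + pp[j] * abp_beat_shape(u, up = up_abp))
    abp_peak_t <- abp_on + up_abp * rr

    morph <- cfg$ppg_morph
    identity_mode <- isTRUE(morph$identity)
    if (identity_mode) {
      ppg <- (abp - mean(dbp)) / mean(pp)
    } else {
      up_ppg <- stats::runif(1, morph$peak_frac[1], morph$peak_frac[2])
      decay_pow <- stats::runif(1, morph$decay_pow[1], morph$decay_pow[2])
      ppg_on <- r_t + pat - up_ppg * rr
      ppg_onsets <- c(ppg_on, ppg_on[nb] + rr[nb])
      # slow multiplicative gain drift per beat
      gain <- exp(cumsum(stats::rnorm(nb, sd = morph$gain_sd * sqrt(rr / 60))))
      ppg <- eval_beats(t, ppg_onsets, function(j, u)
        gain[j] * ppg_beat_shape(u, up = up_ppg, decay_pow = decay_pow))
    }

    ecg <- numeric(n)
    for (i in seq_len(nb)) {
      idx <- which(abs(t - r_t[i]) < 0.08)
      ecg[idx] <- ecg[idx] + exp(-((t[idx] - r_t[i]) / 0.022)^2)
      tw <- which(abs(t - (r_t[i] + 0.24)) < 0.2)
      ecg[tw] <- ecg[tw] + 0.10 * exp(-((t[tw] - r_t[i] - 0.24) / 0.06)^2)
    }

    ecg <- ecg + stats::rnorm(n, sd = cfg$noise_sd$ecg)
    if (!identity_mode) ppg <- ppg + stats::rnorm(n, sd = cfg$noise_sd$ppg)
    abp <- abp + stats::rnorm(n, sd = cfg$noise_sd$abp)

    # ---- artifacts ----
    art <- list()
    add_art <- function(type, channel, t0, t1)
      art[[length(art) + 1L]] <<- data.frame(type = type, channel = channel,
                                             t0 = t0, t1 = t1)
    n_art <- function(rate) stats::rpois(1, rate)
    dur <- function() stats::runif(1, cfg$artifact_duration_s[1],
                                   cfg$artifact_duration_s[2])
    idx_of <- function(t0, t1) {
      i0 <- max(1L, floor(t0 * fs) + 1L); i1 <- min(n, ceiling(t1 * fs))
      seq(i0, i1)
    }
    for (k in seq_len(n_art(cfg$artifact_rates[["flatline"]]))) {
      d <- dur(); t0 <- stats::runif(1, 0, cfg$duration_s - d)
      ch <- sample(c("ppg", "abp"), 1)
      ix <- idx_of(t0, t0 + d)
      if (ch == "ppg") ppg[ix] <- ppg[ix[1]] else abp[ix] <- round(abp[ix[1]])
      add_art("flatline", ch, t0, t0 + d)
    }
    for (k in seq_len(n_art(cfg$artifact_rates[["spike"]]))) {
      d <- dur(); t0 <- stats::runif(1, 0, cfg$duration_s - d)
      ix <- idx_of(t0, t0 + d)
      spk <- 3 * abs(sin(2 * pi * 5.5 * t[ix]))^24
      ppg[ix] <- ppg[ix] + spk
      add_art("spike", "ppg", t0, t0 + d)
    }
    for (k in seq_len(n_art(cfg$artifact_rates[["dropout"]]))) {
      d <- dur(); t0 <- stats::runif(1, 0, cfg$duration_s - d)
      ix <- idx_of(t0, t0 + d)
      abp[ix] <- 5 + stats::rnorm(length(ix), sd = 0.3)
      add_art("dropout", "abp", t0, t0 + d)
    }
    ppg_delay_s <- 0
    if (n_art(cfg$artifact_rates[["clock_drift"]]) > 0) {
      ppg_delay_s <- stats::runif(1, 0.5, 3) * sample(c(-1, 1), 1)
      sh <- round(ppg_delay_s * fs)
      ppg <- if (sh > 0) c(rep(ppg[1], sh), ppg[seq_len(n - sh)])
             else c(ppg[(1 - sh):n], rep(ppg[n], -sh))
      add_art("clock_drift", "ppg", 0, cfg$duration_s)
    }
    artifacts <- if (length(art)) do.call(rbind, art) else
      data.frame(type = character(), channel = character(),
                 t0 = numeric(), t1 = numeric())

    rec <- waveform_record(record_id = patient_id, fs = fs,
                           channels = list(ecg = ecg, ppg = ppg, abp = abp))
    truth <- list(
      beats = data.frame(r_t = r_t, abp_peak_t = abp_peak_t,
                         sys = sys, dias = dbp, pat = pat),
      hr_bpm = hr,
      artifacts = artifacts,
      ppg_delay_s = ppg_delay_s,
      identity_mode = identity_mode
    )
    list(record = rec, truth = truth)
  })
}

#' Generate a cohort of synthetic patients
#'
#' @param cfg a [sim_config()].
#' @param prefix record-id prefix.
#' @return list of `list(record, truth)` of length `cfg$n_patients`.
#' @export
generate_cohort <- function(cfg, prefix = "sim") {
  lapply(seq_len(cfg$n_patients), function(i)
    generate_record(cfg, sprintf("%s-%03d", prefix, i), patient_index = i))
}

#' Generate a labeled PPG quality-index training set
#'
#' Emulates a hand-labeling campaign over 4-s PPG windows: about 67% of
#' windows are artifact-free beats ("valid"), the rest carry flatline, spike,
#' or noise artifacts ("invalid"). Labels are flipped at `cfg$label_flip_rate`
#' to emulate rater disagreement.
#'
#' @param cfg a [sim_config()].
#' @param n_windows number of labeled windows.
#' @param valid_frac fraction of truly valid windows (default 0.671).
#' @return list with `x` (matrix `n_windows` x 400), `label` (factor
#'   valid/invalid as labeled), `truth` (true class), `patient` (integer id).
#' @export
generate_qi_training_set <- function(cfg, n_windows = 400,
                                     valid_frac = 0.671) {
  stopifnot(n_windows >= 10)
  with_seed(derive_seed(cfg$seed, 900001L), {
    len <- 4 * cfg$fs
    tt <- (seq_len(len) - 1L) / cfg$fs
    n_pat <- max(2L, cfg$n_patients)
    pat_morph <- lapply(seq_len(n_pat), function(i)
      list(hr = stats::runif(1, cfg$hr_range[1], cfg$hr_range[2]),
           up = stats::runif(1, cfg$ppg_morph$peak_frac[1],
                             cfg$ppg_morph$peak_frac[2]),
           dp = stats::runif(1, cfg$ppg_morph$decay_pow[1],
                             cfg$ppg_morph$decay_pow[2])))
    x <- matrix(0, n_windows, len)
    truth <- character(n_windows)
    patient <- sample(rep_len(seq_len(n_pat), n_windows))
    for (i in seq_len(n_windows)) {
      m <- pat_morph[[patient[i]]]
      rr <- 60 / m$hr
      onsets <- seq(-stats::runif(1, 0, rr), 4 + 2 * rr, by = rr)
      sig <- eval_beats(tt, onsets, function(j, u)
        ppg_beat_shape(u, up = m$up, decay_pow = m$dp))
      if (stats::runif(1) < valid_frac) {
        truth[i] <- "valid"
        x[i, ] <- sig + stats::rnorm(len, sd = cfg$noise_sd$ppg)
      } else {
        truth[i] <- "invalid"
        kind <- sample(c("flatline", "spike", "noise"), 1)
        x[i, ] <- switch(kind,
          flatline = rep(sig[1], len) + stats::rnorm(len, sd = 0.001),
          spike = sig + 3 * abs(sin(2 * pi * 5.5 * tt))^24 +
            stats::rnorm(len, sd = cfg$noise_sd$ppg),
          noise = stats::rnorm(len, sd = 0.5))
      }
    }
    label <- truth
    flip <- stats::runif(n_windows) < cfg$label_flip_rate
    label[flip] <- ifelse(truth[flip] == "valid", "invalid", "valid")
    list(x = x, label = factor(label, levels = c("invalid", "valid")),
         truth = factor(truth, levels = c("invalid", "valid")),
         patient = patient)
  })
}

#' Ground-truth artifact overlap set for a window table
#'
#' Marks the windows that materially overlap an injected artifact. PPG
#' artifact intervals are shifted by the drift-correction lag that the
#' pipeline applied to the PPG channel, so intervals are compared in the
#' corrected time base. Overlaps shorter than `min_overlap_s` are boundary
#' slivers (an artifact clipping the first or last second of a 32-s window)
#' and are not counted: the filter rules may legitimately go either way on
#' them, mirroring the boundary tolerance of the rejection audit.
#'
#' @param windows window table from [slice_windows()] / [filter_record()].
#' @param truth the `truth` element of [generate_record()].
#' @param lag_s drift-correction lag applied to the PPG (s).
#' @param min_overlap_s minimum intersection (s) counted as overlap.
#' @param window_s window duration (s).
#' @return logical vector over the rows of `windows`.
#' @export
artifact_overlap_windows <- function(windows, truth, lag_s = 0,
                                     min_overlap_s = 1, window_s = 32) {
  overlap <- rep(FALSE, nrow(windows))
  art <- truth$artifacts
  for (k in seq_len(nrow(art))) {
    if (art$type[k] == "clock_drift") next
    t0 <- art$t0[k]; t1 <- art$t1[k]
    if (art$channel[k] == "ppg") { t0 <- t0 + lag_s; t1 <- t1 + lag_s }
    ov <- pmin(windows$start_t + window_s, t1) - pmax(windows$start_t, t0)
    overlap <- overlap | (ov >= min_overlap_s)
  }
  overlap
}

#' Derive a domain-shifted "second site" configuration
#'
#' Perturbs PPG morphology and blood-pressure distributions to emulate a
#' calibration cohort recorded at a different hospital with different
#' instrumentation, for fine-tuning experiments.
#'
#' @param cfg base [sim_config()].
#' @param gain_shift multiplicative PPG gain perturbation (0 = none).
#' @param morph_shift shift of the PPG systolic peak position fraction.
#' @param bp_shift additive shift of the diastolic base range (mmHg).
#' @param seed seed for the new site (defaults to `cfg$seed + 1`).
#' @return a new `sim_config`.
#' @export
make_second_site <- function(cfg, gain_shift = 0.2, morph_shift = 0.05,
                             bp_shift = -5, seed = cfg$seed + 1L) {
  cfg2 <- cfg
  cfg2$ppg_morph$peak_frac <- pmin(cfg$ppg_morph$peak_frac + morph_shift, 0.45)
  cfg2$ppg_morph$decay_pow <- cfg$ppg_morph$decay_pow * (1 + gain_shift)
  cfg2$dbp_range <- cfg$dbp_range + bp_shift
  cfg2$seed <- as.integer(seed)
  cfg2
}
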