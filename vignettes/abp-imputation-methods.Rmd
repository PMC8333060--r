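---
title: "Continuous ABP waveform imputation: models, filters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous ABP waveform imputation: models, filters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abpwave)
```

## The problem

Arterial blood pressure (ABP) is monitored continuously only in patients
with an arterial catheter; everyone else gets an intermittent cuff reading
(NIBP) every few minutes to hours. Two signals that *are* monitored
continuously in acute care — the ECG and the pulse oximeter's
photo-plethysmogram (PPG) — carry substantial information about the pressure
waveform: the PPG is a peripheral pulse-volume signal whose shape tracks the
arterial pulse, and the ECG R-wave anchors the timing of each beat.
`abpwave` imputes the continuous ABP waveform from ECG, PPG, and sparse NIBP
values, and quantifies how well the imputed waveform agrees with an
arterial-line reference.

The estimator is deliberately two-staged:

1. **PPG scaling (closed form).** Within a 32-s window the PPG is used as a
   template shape and stretched affinely so that its maximum equals the most
   recent systolic NIBP and its minimum the diastolic NIBP:
   `scaled = (ppg - min) * (sys - dias)/(max - min) + dias`. This already
   captures most of the waveform (it is monotone and shape-preserving), but
   it inherits the PPG's morphology and goes stale as the NIBP reading ages.

2. **Residual 1-D V-Net.** A convolutional encoder–decoder is trained to
   predict the *residual* `r = abp - scaled`, which is added back to the
   baseline. Residual learning anchors the network at a sensible prediction
   (zero output = the baseline) and concentrates its capacity on morphology
   and drift corrections where the baseline is wrong.

## Signal preprocessing

All channels are brought to 100 Hz (rational-ratio polyphase FIR
downsampling only; upsampling is refused) and low-pass filtered at 16 Hz
with a 4th-order Butterworth applied forward–backward. Zero phase matters:
a causal filter would delay the PPG systolic peak relative to the ECG
R-wave and bias the pulse-arrival-time (PAT) feature. The two-pass
magnitude response attenuates 25 Hz by more than 20 dB while staying within
1 dB below 12 Hz. ECG and PPG amplitudes are patient- and sensor-specific,
so each 32-s window is scaled by its median and inter-quartile range; the
ABP target is never normalized (the model predicts mmHg). The median/IQR
statistics are computed per window rather than over a trailing buffer — the
windows are the unit of all later processing, and per-window scaling makes
the transform exactly invariant to positive affine re-calibrations of the
sensor.

Clock drift between the PPG and ABP acquisition devices is estimated as
the lag (up to ±4 s) maximizing the lag-wise Pearson correlation of the
mean-removed signals over the first five minutes of the record, one lag per
record; ties go to the smallest absolute lag. A per-window lag would absorb
real physiological timing (PAT) into the correction, so the alignment
segment is deliberately long.

## Window validity rules

Records are sliced into 32-s windows at a 16-s step (a window count of
`floor((T - 32)/16) + 1`). Every rule is evaluated on every window, and all
fired rules are recorded, so rejection can be audited per rule:

* ECG/PPG: variance below `1e-4`; more than 4 peaks/s (240 bpm) or fewer
  than 0.5 peaks/s (30 bpm).
* ABP (mmHg, unnormalized): mean outside [30, 200]; maximum outside
  [60, 300]; minimum below 20; variance below 80; no detectable beats;
  consecutive systolic or diastolic jump above 50; a flat run of 2 or more
  equal samples; any per-beat pulse pressure above 70; window median
  systolic more than 40 from the most recent NIBP systolic; any
  diastolic-trough-to-systolic-peak delay above 0.5 s.
* Cross-signal (after drift correction): systolic peaks of PPG and ABP are
  paired order-preservingly by proximity (0.25 s cap). An unpaired peak in
  the window *interior* is a peak-count mismatch; unpaired peaks within
  0.25 s of a window edge belong to beats the window truncates, where the
  two channels can legitimately disagree by a sample, and are tolerated.
  Misalignment fires when the mean absolute paired-peak time difference
  exceeds 0.15 s. The edge tolerance is a deliberate design choice: without
  it, a boundary-truncated beat whose peak falls one sample inside one
  channel and one sample outside the other rejects a perfectly clean
  window, and artifact-free synthetic cohorts could never reach 100%
  validity.
* Cohort level: windows whose per-channel mean exceeds the cohort's 99.9%
  quantile or falls below its 0.01% quantile (the asymmetry is intentional
  and kept as stated) are outliers. Extreme quantiles are meaningless in
  small cohorts, so the rule requires at least 1000 candidate windows and
  is computed per cohort (training and test populations separately) over
  windows that passed all prior rules.

Peak detection is deterministic: strict local maxima (plateaus take their
first sample), a topographic-prominence floor at 25% of the window's
amplitude range, and tallest-first pruning at a 0.25-s minimum spacing
(consistent with the 240 bpm ceiling). Prominence is one-sided for peaks
whose saddle search runs into a window edge, so truncated edge beats are
kept with their full prominence regardless of how fast each channel decays.

## PPG quality index

Artifact filtering by fixed rules misses many PPG corruptions, so a small
learned classifier scores 4-s PPG subwindows: three 1-D convolution blocks
(16/32/64 filters, kernel 7, stride 2, ReLU), global average pooling, and a
sigmoid output — a minimal standard design for a three-layer CNN. Training
data are labeled subwindows split *by patient* 70/30; the filtering
threshold is the smallest observed score whose positive predictive value on
the validation patients reaches 0.95, which keeps accepted windows clean
while remaining as permissive as the precision target allows. A 32-s window
holds eight non-overlapping 4-s subwindows; its quality index is the
minimum of the eight probabilities, and the window passes only if that
minimum reaches the threshold. Each subwindow is median/IQR-scaled exactly
as the training windows were, with a median-centering fallback for
flatlined (zero-IQR) subwindows. The published threshold for this kind of
filter is data- and model-specific; the package re-derives its threshold
from its own validation split, and the label generator supports a 6% label
flip rate so robustness to imperfect manual labels can be tested.

## Features

The model input is a 9 × 3200 tensor per window: scaled ECG and PPG,
constant channels carrying the most recent derived NIBP systolic /
diastolic / mean pressures, the time since that NIBP reading, the
log-median PAT, the PAT standard deviation, and the PPG-derived heart rate.
The time-since-NIBP channel is a per-sample ramp in milliseconds rather
than a constant, because the elapsed time genuinely differs by 32 s across
the window; a constant-channel variant is a one-line change in
`build_feature_tensor()`. PAT pairs each R-peak with the first subsequent
PPG systolic peak and discards values outside [0.1, 1.0] s (bounds
retained). "Median (log-transformed)" is read as the log of the median PAT;
since the logarithm is monotone this equals the median of the logs, so both
readings coincide. Derived NIBP emulates cuff cycling by sampling the ABP
waveform every 5 min: median per-beat systolic and diastolic values and the
mean pressure over a 4-s segment anchored at the tick.

All nine channels are standardized by per-channel running mean/SD
statistics accumulated over the training stream in record order and then
frozen; missing PAT/HR summaries are imputed with the training-stream
median before scaling. Freezing prevents any evaluation-patient statistics
from leaking into the transform; a near-constant channel is guarded with an
epsilon (`1e-8`) and scales to zeros.

## The residual 1-D V-Net

The network follows the V-Net design transposed to 1-D: each level applies
1–3 convolutions (kernel 5, PReLU) with an additive within-level residual
connection, down-sampling is a stride-2 convolution that doubles the
filters, up-sampling a stride-2 transposed convolution that halves them,
and encoder features are concatenated into the decoder at matching
resolution. Four down/up levels on 3200-sample inputs leave a 200-sample
bottleneck. The final layer is a linear 1 × 1 convolution onto one channel
— the residual in mmHg. Residual targets are deliberately *not*
standardized: keeping them in mmHg makes the zero-residual identity
(`prediction == baseline` when the final layer is zero) exactly testable.
The final layer's weights are initialized at a tenth of the usual He scale,
so an untrained network starts close to the baseline (a small random
residual) without the blocked gradients of an exactly-zero initialization;
this shortens the early phase of training considerably.

The loss has two parts: the mean squared error over the whole window, plus
an equally weighted (weight 1.0, configurable) mean squared error at the
systolic and diastolic fiducial samples of the true ABP, which pushes
accuracy exactly where derived pressures are read off. An L2 penalty with
weight 0.0005 on the network output shrinks the prediction toward the
baseline. The penalty is applied to the per-element *mean* of the squared
output rather than the per-sample sum: with a 3200-sample sum the penalty
would dwarf the data term and put a floor of tens of mmHg² under the loss,
contradicting the training contract that a single batch can be driven below
1 mmHg²; the mean form keeps it a mild shrinkage.

Optimization is Nadam (learning rate 0.001, momentum-schedule decay 0.004,
β₁ = 0.9, β₂ = 0.999), mini-batches of 32, at most 100 epochs, with 10% of
the training windows (patient-disjoint) held out for validation and early
stopping after 8 epochs without improvement; the best-validation weights
are restored. Everything stochastic (initialization, shuffling, splits) is
seeded, so runs are bit-reproducible. Fine-tuning for a second site
continues training of all parameters with the same optimizer settings on a
calibration cohort that must be disjoint from that site's test patients.

The package ships its own compact conv-net engine (single-precision
im2col + GEMM convolutions in C++, explicit reverse-mode tape in R) sized
for exactly these two architectures; its gradients are verified against
finite differences in the test suite's double-precision checks.

## Evaluation

Per-window RMSE and Pearson correlation are averaged with bootstrap
percentile 95% CIs (windows resampled). For derived pressures, systolic
peaks and diastolic troughs are detected on both waveforms; when counts
differ the lists are paired by the order-preserving matching minimizing the
sum of absolute index differences, computed exactly by dynamic programming
(ties toward earlier pairs; verified against exhaustive enumeration).
Bland–Altman differences are `predicted - true`, summarized as mean ± SD
(sample SD) with bootstrap CIs, and judged against the AAMI acceptability
bound of mean < 5 mmHg with SD < 8 mmHg. Both pooled (beats as units) and
per-patient aggregations are meaningful; the package reports pooled values
and exposes the per-beat table. Window errors are also binned into 10-s
intervals of time since the last NIBP reading, since the scaling baseline
degrades as the reading ages.

## The synthetic cohort generator

Every stage is testable without access to clinical waveform databases
because the generator produces physiologically *structured* (not
physiologically validated) records with exact ground truth: beat times,
per-beat systolic/diastolic pressures following a slow random walk, true
PAT per beat, artifact intervals, and the injected PPG clock lag. Defaults
are chosen so artifact-free records pass every filter: heart rate 60–100
bpm, diastolic base 62–78 mmHg, pulse pressure 38–58 mmHg (below the
70 mmHg rejection bound, above the variance floor), PAT 0.12–0.38 s.
Cohorts in the shipped tests and acceptance script range from 2 to 20
patients with 3–10-minute records; the held-out method-ordering experiment
uses 12 patients at 6 minutes each. PPG morphology is patient-specific, so
the ordering claim (V-Net beats the scaling baseline on *unseen* patients)
needs enough training morphologies to generalize from — with only two or
three training patients the experiment measures morphology sampling luck,
not the method. Twelve patients is the smallest cohort we found that tests
the claim while still training from scratch in a few minutes.

The PPG is built from its own beat template (patient-specific systolic peak
position and decay exponent, slow multiplicative gain drift), so its
morphology genuinely differs from the ABP's and the residual network has
something real to learn. In *identity mode* the PPG is an exact affine copy
of the ABP with drift and noise disabled — the zero-residual regime in
which PPG scaling reconstructs the ABP exactly and a correct training stack
must drive predictions to the baseline within 1 mmHg. Artifact types map
onto filter-rule classes: flatlines trigger the variance/flat-run rules,
spike bursts the peak-count rules, pressure dropouts the ABP range rules,
and clock drift the cross-signal misalignment. The ground-truth overlap set
counts windows with at least 1 s of artifact intersection (PPG intervals
compared in the drift-corrected time base); sub-second boundary slivers are
left to either side of the filter, mirroring the audit's boundary
tolerance.

What passing on synthetic data does *not* show: robustness to real sensor
noise spectra, damped catheter lines, arrhythmias, vasoactive drug boluses,
or morphology classes outside the template family. The generator's job is
to verify the machinery — rule logic, leakage-free splits, training
contracts, agreement statistics — not to certify clinical performance.

## Numerical and degenerate-input conventions

* Quantiles are type-7 (R's default) everywhere, including the asymmetric
  cohort outlier rule.
* Zero-IQR windows are degenerate: the scaler raises an error and the
  filter routes the window to rejection; the QI subwindow scaler falls back
  to median-centering so flatlines can still be scored (and rejected by the
  model).
* Zero-variance windows yield an undefined correlation and are skipped in
  aggregation, never silently zeroed.
* Drift estimation refuses constant inputs (undefined correlation) and
  spans shorter than 30 s.
* Sample indices are 1-based in R code; window intervals are half-open
  `[start, start + 32)`; seconds are counted from record start.

## Known limitations

* The engine is CPU-bound and single-precision; it is sized for the shipped
  reduced-width experiments, not for multi-hundred-patient training runs.
* WFDB support covers single-segment format-16 records — enough for
  round-tripping and for typical matched-subset waveform files, not the
  full format zoo.
* Multi-segment records with gaps are treated as independent records per
  contiguous segment.
* The second-site fine-tuning path is exercised on a simulated domain
  shift; transfer on real inter-hospital shifts is untested by construction.
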