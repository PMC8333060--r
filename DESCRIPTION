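Package: abpwave
Title: Continuous Arterial Blood Pressure Waveform Imputation from ECG and PPG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputes the continuous arterial blood pressure (ABP) waveform from
    non-invasive signals: the ECG (lead II), the photo-plethysmogram (PPG), and
    sparse non-invasive blood pressure (NIBP) readings. Provides the full
    preprocessing chain (resampling to 100 Hz, 16 Hz zero-phase low-pass,
    per-window median/IQR scaling, cross-correlation clock-drift correction),
    an exhaustive artifact window-filtering rule set with per-rule rejection
    audit, a learned convolutional PPG quality index with precision-targeted
    threshold selection, pulse-arrival-time and heart-rate feature extraction,
    a closed-form PPG-scaling baseline, and a residual 1-D V-Net that predicts
    the correction between the baseline and the true ABP waveform. Includes a
    physiologically structured waveform simulator with ground-truth beats and
    labeled artifacts, and a device-agreement evaluation suite (windowed RMSE
    and correlation, fiducial alignment, Bland-Altman analysis against the
    AAMI criterion, bootstrap confidence intervals, error versus time since
    the last NIBP reading).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
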