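# End-to-end orchestration: simulate/ingest -> preprocess -> filter -> QI ->
# features -> baseline -> train -> predict -> evaluate, with patient-level
# split management and provenance.

#' Split patients into disjoint groups
#'
#' Deterministic seeded shuffle followed by a cumulative-floor partition, so
#' e.g. 309 patients at fractions 2/3 / 1/3 give groups of 206 and 103.
#' Splits are always by patient, never by window.
#'
#' @param patients character vector of unique patient ids.
#' @param fractions named fractions summing to 1.
#' @param seed RNG seed.
#' @return named list of id vectors, one per fraction; attribute `seed`.
#' @export
make_splits <- function(patients, fractions = c(train = 2 / 3, test = 1 / 3),
                        seed = 1L) {
  if (anyDuplicated(patients))
    stop("duplicate patient ids: ",
         paste(unique(patients[duplicated(patients)]), collapse = ", "))
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n <- length(patients)
  shuffled <- with_seed(derive_seed(seed, 5L), sample(patients))
  cuts <- c(0, floor(cumsum(fractions) * n))
  cuts[length(cuts)] <- n
  out <- lapply(seq_along(fractions), function(i)
    shuffled[(cuts[i] + 1):cuts[i + 1]])
  names(out) <- names(fractions)
  attr(out, "seed") <- seed
  out
}

#' Build model-ready windows from a filtered record
#'
#' For each valid window: assembles the (unstandardized) 9-channel feature
#' tensor, the PPG-scaling baseline, the residual target
#' `r = abp - ppg_scaled`, and the systolic/diastolic fiducial indices of
#' the true ABP used by the two-part loss. Windows without ABP get `r` and
#' `fid` set to `NULL` (inference mode).
#'
#' @param record preprocessed [waveform_record()].
#' @param windows output of [filter_record()]; only rows with
#'   `valid == TRUE` are used.
#' @param nibp NIBP stream for the record.
#' @return list of window structures (`x`, `ppg_scaled`, `abp`, `r`, `fid`,
#'   `patient`, `start_t`, `t_since_s`).
#' @export
build_model_windows <- function(record, windows, nibp) {
  fs <- record$fs
  out <- list()
  for (i in which(windows$valid)) {
    w <- windows[i, ]
    ecg <- window_samples(record, w, "ecg")
    ppg <- window_samples(record, w, "ppg")
    fill <- fill_nibp(w$start_t, nibp)
    if (is.null(fill)) next
    x <- build_feature_tensor(ecg, ppg, fill$nibp, fill$t_since_ms, fs = fs)
    scaled <- as.numeric(ppg_scale(ppg, fill$nibp))
    win <- list(x = x, ppg_scaled = scaled, patient = record$record_id,
                start_t = w$start_t, t_since_s = fill$t_since_ms / 1000)
    if (!is.null(record$channels$abp)) {
      abp <- window_samples(record, w, "abp")
      beats <- annotate_beats(abp, fs = fs)
      win$abp <- abp
      win$r <- abp - scaled
      win$fid <- union(beats$sys_idx, beats$dias_idx)
    }
    out[[length(out) + 1L]] <- win
  }
  out
}

standardize_windows <- function(transform, windows) {
  lapply(windows, function(w) {
    w$x <- apply_feature_transform(transform, w$x)
    w
  })
}

#' Run the full imputation pipeline on a synthetic cohort
#'
#' Simulates a cohort, preprocesses and filters every record, trains the PPG
#' quality index on its own labeled set, splits patients into training and
#' test groups, fits the frozen feature transform and the cohort quantile
#' rule on training-cohort windows only, trains the residual V-Net, and
#' evaluates both the V-Net and the PPG-scaling baseline on the held-out
#' patients. Every fitted component records which patients produced it.
#'
#' @param sim a [sim_config()].
#' @param filter_cfg a [filter_config()].
#' @param qi_cfg a [qi_config()], or `NULL` to skip the QI stage.
#' @param model_cfg a [vnet_config()].
#' @param fractions patient split fractions.
#' @param qi_n_windows size of the QI labeled set.
#' @param nibp_period_s derived-NIBP tick spacing (s).
#' @param n_boot bootstrap resamples for evaluation CIs.
#' @param seed master seed (propagated to every stochastic stage).
#' @param quiet suppress progress messages.
#' @return list with `qi_model`, `transform`, `model`, `eval_vnet`,
#'   `eval_baseline`, `windows` (per-split model windows), `filtering`
#'   (per-record window tables), `report`, `provenance`.
#' @export
run_pipeline <- function(sim = sim_config(),
                         filter_cfg = filter_config(),
                         qi_cfg = qi_config(),
                         model_cfg = vnet_config(),
                         fractions = c(train = 2 / 3, test = 1 / 3),
                         qi_n_windows = 300,
                         nibp_period_s = 300,
                         n_boot = 200,
                         seed = 1L,
                         quiet = TRUE) {
  say <- function(...) if (!quiet) message(...)
  sim$seed <- derive_seed(seed, 10L)
  qi_cfg_used <- qi_cfg
  say("simulating ", sim$n_patients, " patients")
  cohort <- generate_cohort(sim)
  ids <- vapply(cohort, function(p) p$record$record_id, character(1))
  splits <- make_splits(ids, fractions, seed = derive_seed(seed, 11L))

  qi_model <- NULL
  if (!is.null(qi_cfg)) {
    say("training QI model")
    qi_cfg$seed <- derive_seed(seed, 12L)
    qi_set <- generate_qi_training_set(sim, qi_n_windows)
    qi_model <- train_qi_model(qi_set$x, qi_set$label, qi_set$patient, qi_cfg)
  }

  say("preprocessing and filtering")
  filtering <- list()
  per_rec_windows <- list()
  for (p in cohort) {
    rec <- preprocess_record(p$record)
    nibp <- derive_nibp(rec$channels$abp, fs = rec$fs,
                        period_s = nibp_period_s)
    wins <- filter_record(rec, nibp, filter_cfg, qi_model = qi_model)
    filtering[[rec$record_id]] <- wins
    per_rec_windows[[rec$record_id]] <- list(rec = rec, nibp = nibp)
  }
  # cohort quantile rule, per split (train and test populations separately)
  for (grp in names(splits)) {
    grp_ids <- splits[[grp]]
    if (!length(grp_ids)) next
    pooled <- do.call(rbind, filtering[grp_ids])
    pooled <- apply_quantile_filter(pooled, filter_cfg)
    off <- 0
    for (id in grp_ids) {
      n_i <- nrow(filtering[[id]])
      filtering[[id]] <- pooled[(off + 1):(off + n_i), ]
      off <- off + n_i
    }
  }

  say("building model windows")
  windows <- lapply(splits, function(grp_ids) {
    out <- list()
    for (id in grp_ids) {
      pr <- per_rec_windows[[id]]
      out <- c(out, build_model_windows(pr$rec, filtering[[id]], pr$nibp))
    }
    out
  })

  if (!length(windows$train)) stop("no valid training windows")
  if (is.null(windows$train[[1]]$r))
    stop("training requires an ABP channel (residual targets)")
  say("fitting feature transform on ", length(windows$train),
      " training windows")
  transform <- fit_feature_transform(lapply(windows$train, `[[`, "x"))
  windows <- lapply(windows, function(w) standardize_windows(transform, w))

  say("training V-Net")
  model_cfg$seed <- derive_seed(seed, 13L)
  model <- build_vnet1d(model_cfg)
  model <- train_vnet(model, windows$train, quiet = quiet)

  eval_grp <- if (length(windows$test)) "test" else "train"
  test_w <- windows[[eval_grp]]
  say("evaluating on ", length(test_w), " ", eval_grp, " windows")
  y_true <- do.call(rbind, lapply(test_w, `[[`, "abp"))
  y_base <- do.call(rbind, lapply(test_w, `[[`, "ppg_scaled"))
  y_pred <- predict_abp_batch(model, test_w, batch = model_cfg$batch)
  t_since <- vapply(test_w, `[[`, numeric(1), "t_since_s")
  ev_seed <- derive_seed(seed, 14L)
  eval_vnet <- evaluate_predictions(y_true, y_pred, t_since, n_boot = n_boot,
                                    seed = ev_seed)
  eval_base <- evaluate_predictions(y_true, y_base, t_since, n_boot = n_boot,
                                    seed = ev_seed)

  provenance <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("abpwave")),
    splits = splits,
    fitted_on = list(
      feature_transform = splits$train,
      quantile_filter = splits$train,
      qi_threshold = "independent labeled QI set",
      model_weights = setdiff(splits$train, model$val_patients),
      model_early_stopping = model$val_patients
    ),
    evaluated_on = splits[[eval_grp]]
  )
  report <- list(
    n_patients = sim$n_patients,
    n_windows_total = sum(vapply(filtering, nrow, integer(1))),
    n_windows_valid = sum(vapply(filtering, function(w) sum(w$valid),
                                 integer(1))),
    rejection = rejection_report(do.call(rbind, filtering)),
    vnet_rmse = eval_vnet$rmse_mean,
    baseline_rmse = eval_base$rmse_mean,
    vnet_corr = eval_vnet$corr_mean,
    baseline_corr = eval_base$corr_mean,
    aami_pass = eval_vnet$aami_pass
  )
  list(qi_model = qi_model, transform = transform, model = model,
       splits = splits, windows = windows, filtering = filtering,
       eval_vnet = eval_vnet, eval_baseline = eval_base,
       report = report, provenance = provenance)
}

#' Verify split integrity of pipeline artifacts
#'
#' Checks that no evaluation patient contributed to any fitted component:
#' the feature transform, the quantile-rule population, the model weights,
#' or the early-stopping monitor.
#'
#' @param artifacts a [run_pipeline()] result.
#' @return `TRUE` invisibly; stops with a description on violation.
#' @export
check_split_integrity <- function(artifacts) {
  pv <- artifacts$provenance
  test <- pv$evaluated_on
  for (comp in c("feature_transform", "quantile_filter", "model_weights",
                 "model_early_stopping")) {
    used <- pv$fitted_on[[comp]]
    if (is.character(used)) {
      bad <- intersect(used, test)
      if (length(bad))
        stop("split-integrity violation: ", comp,
             " was fitted on evaluation patient(s) ",
             paste(bad, collapse = ", "))
    }
  }
  invisible(TRUE)
}
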