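# Residual 1-D V-Net: predicts the residual between the PPG-scaling baseline
# and the true ABP waveform; the prediction is baseline + residual.

#' V-Net model configuration
#'
#' An encoder-decoder over 1-D multichannel signals following the V-Net
#' design: within-level residual (additive) connections, down-sampling by
#' stride-2 convolutions that double the filters, up-sampling by stride-2
#' transposed convolutions that halve them, encoder-to-decoder skip
#' concatenations, PReLU nonlinearities, kernel width 5, and 1-3
#' convolutions per level. The final layer is a linear 1x1 convolution onto
#' one output channel (the residual, in mmHg).
#'
#' @param in_channels input channels (the 9-channel feature tensor).
#' @param input_len window length in samples; must be divisible by
#'   `2^levels`.
#' @param levels number of down-sampling (and up-sampling) levels.
#' @param kernel convolution kernel width.
#' @param base_filters filters at the top level (doubled per level).
#' @param convs_per_level convolutions per encoder/decoder level.
#' @param bottom_convs convolutions at the bottleneck.
#' @param l2_activity_weight L2 penalty weight on the final layer's output
#'   (the residual), applied as a per-element mean; shrinks the prediction
#'   toward the PPG-scaling baseline.
#' @param loss_point_weight weight of the fiducial (systolic/diastolic)
#'   mean-squared-error term relative to the full-waveform term.
#' @param lr,schedule_decay,beta1,beta2 Nadam optimizer settings.
#' @param lr_decay multiplicative factor the learning rate reaches by the
#'   final epoch (exponential schedule; 1 keeps it constant).
#' @param batch mini-batch size.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param val_fraction fraction of training windows held out for validation
#'   (split by patient).
#' @param restore_best restore the best-validation weights at the end.
#' @param seed RNG seed covering weight init and shuffling.
#' @return a `vnet_config` list.
#' @export
vnet_config <- function(in_channels = 9, input_len = 3200, levels = 4,
                        kernel = 5, base_filters = 16,
                        convs_per_level = pmin(seq_len(levels), 3),
                        bottom_convs = 3,
                        l2_activity_weight = 5e-4, loss_point_weight = 1,
                        lr = 1e-3, schedule_decay = 0.004,
                        beta1 = 0.9, beta2 = 0.999, lr_decay = 1,
                        batch = 32, max_epochs = 100, patience = 8,
                        val_fraction = 0.10, restore_best = TRUE, seed = 1L) {
  if (input_len %% 2^levels != 0)
    stop("input_len ", input_len, " is not divisible by 2^levels = ",
         2^levels)
  stopifnot(length(convs_per_level) == levels, base_filters >= 1)
  cfg <- as.list(environment())
  class(cfg) <- "vnet_config"
  cfg
}

#' Build a residual 1-D V-Net
#'
#' Initializes all parameters (deterministically from `cfg$seed`) and
#' returns an untrained model.
#' @param cfg a [vnet_config()].
#' @return a `vnet1d` model (parameter store + config).
#' @export
build_vnet1d <- function(cfg = vnet_config()) {
  with_seed(derive_seed(cfg$seed, 1L), {
    p <- nn_params()
    ch <- cfg$base_filters * 2^(seq_len(cfg$levels + 1) - 1)
    for (l in seq_len(cfg$levels)) {
      c_l <- ch[l]
      c_in <- if (l == 1) cfg$in_channels else c_l
      for (j in seq_len(cfg$convs_per_level[l])) {
        init_conv(p, sprintf("enc%d.conv%d", l, j),
                  if (j == 1) c_in else c_l, c_l, cfg$kernel)
        init_prelu(p, sprintf("enc%d.act%d", l, j), c_l)
      }
      if (l == 1) init_conv(p, "enc1.proj", cfg$in_channels, c_l, 1L)
      init_prelu(p, sprintf("enc%d.resact", l), c_l)
      init_conv(p, sprintf("down%d", l), c_l, ch[l + 1], 2L)
      init_prelu(p, sprintf("down%d.act", l), ch[l + 1])
    }
    c_b <- ch[cfg$levels + 1]
    for (j in seq_len(cfg$bottom_convs)) {
      init_conv(p, sprintf("bot.conv%d", j), c_b, c_b, cfg$kernel)
      init_prelu(p, sprintf("bot.act%d", j), c_b)
    }
    init_prelu(p, "bot.resact", c_b)
    for (l in seq(cfg$levels, 1)) {
      c_l <- ch[l]
      init_upconv2(p, sprintf("up%d", l), ch[l + 1], c_l)
      init_prelu(p, sprintf("up%d.act", l), c_l)
      for (j in seq_len(cfg$convs_per_level[l])) {
        init_conv(p, sprintf("dec%d.conv%d", l, j),
                  if (j == 1) 2 * c_l else c_l, c_l, cfg$kernel)
        init_prelu(p, sprintf("dec%d.act%d", l, j), c_l)
      }
      init_prelu(p, sprintf("dec%d.resact", l), c_l)
    }
    # final layer initialized at a tenth of the usual scale: the untrained
    # network then starts close to the PPG-scaling baseline (small residual)
    # without blocking gradient flow
    init_conv(p, "final", ch[1], 1L, 1L)
    p[["final.w"]] <- p[["final.w"]] * 0.1
    structure(list(params = p, cfg = cfg, history = NULL),
              class = "vnet1d")
  })
}

#' @export
print.vnet1d <- function(x, ...) {
  np <- sum(vapply(ls(x$params), function(n) length(x$params[[n]]),
                   numeric(1)))
  cat(sprintf("<vnet1d: %d levels, base %d filters, %s parameters%s>\n",
              x$cfg$levels, x$cfg$base_filters, format(np, big.mark = ","),
              if (is.null(x$history)) " (untrained)" else ""))
  invisible(x)
}

# forward pass; x is (in_channels, input_len, N)
vnet_forward <- function(model, x) {
  cfg <- model$cfg
  tape <- nn_tape(model$params)
  h <- tp_input(tape, x)
  skips <- vector("list", cfg$levels)
  for (l in seq_len(cfg$levels)) {
    h0 <- h
    for (j in seq_len(cfg$convs_per_level[l])) {
      h <- op_conv(tape, h, sprintf("enc%d.conv%d", l, j), cfg$kernel)
      h <- op_prelu(tape, h, sprintf("enc%d.act%d", l, j))
    }
    res_in <- if (l == 1) op_conv(tape, h0, "enc1.proj", 1L) else h0
    h <- op_prelu(tape, op_add(tape, h, res_in), sprintf("enc%d.resact", l))
    skips[[l]] <- h
    h <- op_conv(tape, h, sprintf("down%d", l), 2L, stride = 2L, pad = 0L)
    h <- op_prelu(tape, h, sprintf("down%d.act", l))
  }
  h0 <- h
  for (j in seq_len(cfg$bottom_convs)) {
    h <- op_conv(tape, h, sprintf("bot.conv%d", j), cfg$kernel)
    h <- op_prelu(tape, h, sprintf("bot.act%d", j))
  }
  h <- op_prelu(tape, op_add(tape, h, h0), "bot.resact")
  for (l in seq(cfg$levels, 1)) {
    u <- op_prelu(tape, op_upconv2(tape, h, sprintf("up%d", l)),
                  sprintf("up%d.act", l))
    h <- op_concat(tape, u, skips[[l]])
    for (j in seq_len(cfg$convs_per_level[l])) {
      h <- op_conv(tape, h, sprintf("dec%d.conv%d", l, j), cfg$kernel)
      h <- op_prelu(tape, h, sprintf("dec%d.act%d", l, j))
    }
    h <- op_prelu(tape, op_add(tape, h, u), sprintf("dec%d.resact", l))
  }
  out <- op_conv(tape, h, "final", 1L)
  list(tape = tape, out = out)
}

#' Two-part waveform training loss
#'
#' Mean squared error over the whole window plus `point_weight` times the
#' mean squared error restricted to the systolic and diastolic fiducial
#' locations, which pushes the model to be accurate exactly where derived
#' blood-pressure values are read off.
#'
#' @param y_true,y_pred waveforms (equal length).
#' @param sys_idx,dias_idx fiducial sample indices from the true waveform's
#'   beat annotation (may be empty: the point term is then 0, with a
#'   warning).
#' @param point_weight weight of the fiducial term.
#' @return scalar loss (mmHg^2).
#' @export
vnet_loss <- function(y_true, y_pred, sys_idx = integer(),
                      dias_idx = integer(), point_weight = 1) {
  if (length(y_true) != length(y_pred))
    stop("length mismatch: ", length(y_true), " vs ", length(y_pred))
  fid <- union(sys_idx, dias_idx)
  if (length(fid) && (min(fid) < 1 || max(fid) > length(y_true)))
    stop("fiducial index out of range")
  d <- y_true - y_pred
  full <- mean(d^2)
  if (!length(fid)) {
    warning("no fiducial indices; point term is 0", call. = FALSE)
    return(full)
  }
  full + point_weight * mean(d[fid]^2)
}

# stack a list of windows into batch arrays
vnet_stack <- function(windows, idx) {
  cfg_len <- ncol(windows[[idx[1]]]$x)
  nch <- nrow(windows[[idx[1]]]$x)
  B <- length(idx)
  X <- array(0, c(nch, cfg_len, B))
  R <- array(0, c(1, cfg_len, B))
  pts <- integer(0)
  for (b in seq_len(B)) {
    w <- windows[[idx[b]]]
    X[, , b] <- w$x
    R[1, , b] <- w$r
    if (length(w$fid)) pts <- c(pts, (b - 1L) * cfg_len + w$fid)
  }
  list(X = X, R = R, pts = pts)
}

# loss + gradient for one batch; pred and R are (1, L, B)
vnet_batch_loss <- function(pred, R, pts, cfg, with_grad = TRUE) {
  diff <- pred - R
  nel <- length(diff)
  mse <- sum(diff^2) / nel
  act <- cfg$l2_activity_weight * sum(pred^2) / nel
  pt <- if (length(pts)) sum(diff[pts]^2) / length(pts) else 0
  loss <- mse + cfg$loss_point_weight * pt + act
  g <- NULL
  if (with_grad) {
    g <- 2 * diff / nel + 2 * cfg$l2_activity_weight * pred / nel
    if (length(pts))
      g[pts] <- g[pts] + cfg$loss_point_weight * 2 * diff[pts] / length(pts)
  }
  list(loss = loss, mse = mse, grad = g)
}

vnet_eval_loss <- function(model, windows, idx, cfg) {
  tot <- 0; tot_mse <- 0; n <- 0
  for (b0 in seq(1, length(idx), by = cfg$batch)) {
    bi <- idx[b0:min(b0 + cfg$batch - 1, length(idx))]
    st <- vnet_stack(windows, bi)
    fw <- vnet_forward(model, st$X)
    l <- vnet_batch_loss(fw$out$val, st$R, st$pts, cfg, with_grad = FALSE)
    tot <- tot + l$loss * length(bi)
    tot_mse <- tot_mse + l$mse * length(bi)
    n <- n + length(bi)
  }
  c(loss = tot / n, mse = tot_mse / n)
}

#' Train the residual V-Net
#'
#' Trains on residual targets (`abp - ppg_scaled`, in mmHg) with the
#' two-part loss plus the L2 activity penalty on the network output.
#' A patient-disjoint validation split of `val_fraction` of the windows is
#' held out; training stops early when the validation loss has not improved
#' for `patience` epochs, and the best-validation weights are restored.
#' Deterministic for a fixed seed.
#'
#' @param model a [build_vnet1d()] model.
#' @param windows list of training windows, each a list with `x`
#'   (standardized 9-channel tensor), `r` (residual target, mmHg), `fid`
#'   (fiducial sample indices), `patient` (id used for the split).
#' @param cfg a [vnet_config()] (defaults to the model's).
#' @param quiet suppress per-epoch messages.
#' @return the trained model; `model$history` holds per-epoch train and
#'   validation loss (total and plain MSE).
#' @export
train_vnet <- function(model, windows, cfg = model$cfg, quiet = TRUE) {
  if (!length(windows)) stop("empty training set")
  with_seed(derive_seed(cfg$seed, 2L), {
    pats <- vapply(windows, function(w) as.character(w$patient), character(1))
    upat <- unique(pats)
    val_idx <- integer(0)
    if (cfg$val_fraction > 0 && length(upat) >= 2) {
      target <- cfg$val_fraction * length(windows)
      for (p in sample(upat)) {
        val_idx <- c(val_idx, which(pats == p))
        if (length(val_idx) >= target) break
      }
      if (length(val_idx) >= length(windows))  # keep at least one train patient
        val_idx <- which(pats == upat[1])
    }
    tr_idx <- setdiff(seq_along(windows), val_idx)
    opt <- nadam_new(model$params, lr = cfg$lr, beta1 = cfg$beta1,
                     beta2 = cfg$beta2, schedule_decay = cfg$schedule_decay)
    hist <- data.frame()
    best_val <- Inf; best_snap <- NULL; wait <- 0L
    for (ep in seq_len(cfg$max_epochs)) {
      if (cfg$lr_decay != 1 && cfg$max_epochs > 1)
        opt$lr <- cfg$lr * cfg$lr_decay^((ep - 1) / (cfg$max_epochs - 1))
      ord <- tr_idx[sample.int(length(tr_idx))]
      tot <- 0; tot_mse <- 0
      for (b0 in seq(1, length(ord), by = cfg$batch)) {
        bi <- ord[b0:min(b0 + cfg$batch - 1, length(ord))]
        st <- vnet_stack(windows, bi)
        fw <- vnet_forward(model, st$X)
        l <- vnet_batch_loss(fw$out$val, st$R, st$pts, cfg)
        nn_backward(fw$tape, fw$out, l$grad)
        nadam_step(opt, fw$tape$pgrads)
        tot <- tot + l$loss * length(bi)
        tot_mse <- tot_mse + l$mse * length(bi)
      }
      tr_loss <- tot / length(ord); tr_mse <- tot_mse / length(ord)
      if (length(val_idx)) {
        v <- vnet_eval_loss(model, windows, val_idx, cfg)
      } else v <- c(loss = NA_real_, mse = NA_real_)
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = tr_loss,
                                     train_mse = tr_mse,
                                     val_loss = v[["loss"]],
                                     val_mse = v[["mse"]]))
      if (!quiet)
        message(sprintf("epoch %3d  train %.4f  val %s", ep, tr_loss,
                        if (is.na(v[["loss"]])) "-" else
                          sprintf("%.4f", v[["loss"]])))
      if (length(val_idx)) {
        if (v[["loss"]] < best_val - 1e-12) {
          best_val <- v[["loss"]]
          if (cfg$restore_best) best_snap <- params_snapshot(model$params)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= cfg$patience) break
        }
      }
    }
    if (cfg$restore_best && !is.null(best_snap))
      params_restore(model$params, best_snap)
    model$history <- hist
    model$val_patients <- unique(pats[val_idx])
    model
  })
}

#' Predict the ABP waveform for one window
#'
#' The network's residual output is added back to the PPG-scaling baseline.
#'
#' @param model a trained [build_vnet1d()] model.
#' @param x standardized 9-channel feature tensor (attribute
#'   `standardized = TRUE` set by [apply_feature_transform()]).
#' @param ppg_scaled the window's [ppg_scale()] baseline (mmHg).
#' @return predicted ABP waveform (mmHg), same length as the input.
#' @export
predict_abp <- function(model, x, ppg_scaled) {
  if (!isTRUE(attr(x, "standardized")))
    stop("features must be standardized with the frozen training transform")
  if (anyNA(x)) stop("NaN/NA in feature tensor")
  fw <- vnet_forward(model, array(x, c(nrow(x), ncol(x), 1)))
  pred <- as.numeric(ppg_scaled) + as.numeric(fw$out$val[1, , 1])
  stopifnot(all(is.finite(pred)))
  pred
}

# batched prediction over a window list (returns matrix, one row per window)
predict_abp_batch <- function(model, windows, batch = 32) {
  n <- length(windows)
  L <- ncol(windows[[1]]$x)
  out <- matrix(0, n, L)
  for (b0 in seq(1, n, by = batch)) {
    bi <- b0:min(b0 + batch - 1, n)
    X <- array(0, c(nrow(windows[[1]]$x), L, length(bi)))
    for (k in seq_along(bi)) X[, , k] <- windows[[bi[k]]]$x
    fw <- vnet_forward(model, X)
    for (k in seq_along(bi))
      out[bi[k], ] <- windows[[bi[k]]]$ppg_scaled + fw$out$val[1, , k]
  }
  out
}

#' Fine-tune a trained model on a calibration cohort
#'
#' Continues training (all parameters trainable) with the same optimizer
#' settings and early stopping on a held-out fraction of the calibration
#' windows — the site-transfer calibration step. Calibration patients must
#' be disjoint from any test patients.
#'
#' @param model a trained model.
#' @param windows calibration windows (as in [train_vnet()]).
#' @param cfg a [vnet_config()]; defaults to the model's.
#' @param epochs epoch cap for fine-tuning (0 = no-op).
#' @param test_patients ids that must not appear among the calibration
#'   patients (leakage guard).
#' @return the fine-tuned model.
#' @export
fine_tune <- function(model, windows, cfg = model$cfg,
                      epochs = cfg$max_epochs, test_patients = NULL) {
  if (epochs == 0) return(model)
  pats <- unique(vapply(windows, function(w) as.character(w$patient),
                        character(1)))
  if (!is.null(test_patients) && length(intersect(pats, test_patients)))
    stop("split-integrity error: calibration patients overlap test patients: ",
         paste(intersect(pats, test_patients), collapse = ", "))
  cfg$max_epochs <- epochs
  cfg$seed <- derive_seed(cfg$seed, 3L)
  train_vnet(model, windows, cfg)
}
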