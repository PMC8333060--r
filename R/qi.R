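# Learned PPG quality index: a small 1-D CNN over 4-s PPG windows, with
# precision-targeted threshold selection and the 8-subwindow minimum rule.

#' QI model configuration
#'
#' Three 1-D convolution blocks (16/32/64 filters, kernel 7, stride 2, ReLU),
#' global average pooling and a sigmoid output unit: a minimal standard
#' design for a 3-layer CNN signal classifier.
#'
#' @param input_len subwindow length in samples (4 s at 100 Hz).
#' @param filters filters per conv block.
#' @param kernel kernel width.
#' @param stride stride per block.
#' @param target_ppv precision targeted when selecting the score threshold.
#' @param lr,epochs,batch training hyperparameters (Nadam).
#' @param val_patient_frac fraction of patients held out for validation
#'   (threshold selection).
#' @param seed RNG seed for init and shuffling.
#' @return a `qi_config` list.
#' @export
qi_config <- function(input_len = 400, filters = c(16, 32, 64), kernel = 7,
                      stride = 2, target_ppv = 0.95, lr = 1e-3, epochs = 25,
                      batch = 32, val_patient_frac = 0.3, seed = 1L) {
  stopifnot(length(filters) == 3, target_ppv > 0, target_ppv < 1)
  cfg <- as.list(environment())
  class(cfg) <- "qi_config"
  cfg
}

qi_init_params <- function(cfg) {
  p <- nn_params()
  c_in <- 1L
  for (i in seq_along(cfg$filters)) {
    init_conv(p, paste0("conv", i), c_in, cfg$filters[i], cfg$kernel)
    c_in <- cfg$filters[i]
  }
  init_dense(p, "out", c_in, 1L)
  p
}

# forward to logits; x is (1, input_len, N)
qi_forward <- function(params, cfg, x) {
  tape <- nn_tape(params)
  h <- tp_input(tape, x)
  for (i in seq_along(cfg$filters)) {
    h <- op_conv(tape, h, paste0("conv", i), cfg$kernel, stride = cfg$stride)
    h <- op_relu(tape, h)
  }
  h <- op_gap(tape, h)
  h <- op_dense(tape, h, "out")
  list(tape = tape, logits = h)
}

# per-subwindow scaling onto the training scale: median/IQR, falling back to
# median-centering for degenerate (for example flatlined) subwindows.
qi_scale <- function(x) {
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- qs[3] - qs[1]
  if (iqr <= 1e-12) x - qs[2] else (x - qs[2]) / iqr
}

qi_batch <- function(x) {
  # rows of x are subwindows; returns (1, len, N) array
  xs <- t(apply(x, 1, qi_scale))
  array(t(xs), dim = c(1, ncol(x), nrow(x)))
}

#' Score PPG subwindows with a fitted QI model
#'
#' @param model a [train_qi_model()] fit.
#' @param x matrix of subwindows (one per row, `input_len` columns).
#' @return vector of probabilities of being a valid (artifact-free) window.
#' @export
qi_score <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopifnot(ncol(x) == model$cfg$input_len)
  fw <- qi_forward(model$params, model$cfg, qi_batch(x))
  as.numeric(1 / (1 + exp(-fw$logits$val)))
}

#' Train the PPG quality-index classifier
#'
#' Patients are split patient-disjoint into a training and a validation
#' group; the CNN is trained with binary cross-entropy (Nadam), and the
#' filtering threshold is selected on the validation group as the minimum
#' score achieving the target precision (see [select_threshold()]).
#' Training is deterministic given the seed.
#'
#' @param x matrix of labeled subwindows (one per row).
#' @param labels factor/character with levels `invalid`, `valid`.
#' @param patient integer/character patient id per row (splits are by
#'   patient, never by window).
#' @param cfg a [qi_config()].
#' @return a `qi_model` list: `params`, `cfg`, `threshold`,
#'   `threshold_unattainable`, `val_scores`, `val_labels`, `history`.
#' @export
train_qi_model <- function(x, labels, patient, cfg = qi_config()) {
  y <- as.integer(as.character(labels) == "valid")
  pats <- unique(patient)
  if (length(pats) < 2) stop("need at least 2 patients for a disjoint split")
  model <- with_seed(cfg$seed, {
    val_pats <- sample(pats, max(1, round(cfg$val_patient_frac * length(pats))))
    tr <- which(!(patient %in% val_pats))
    va <- which(patient %in% val_pats)
    if (length(unique(y[tr])) < 2)
      stop("degenerate labels: training split contains a single class")
    params <- qi_init_params(cfg)
    opt <- nadam_new(params, lr = cfg$lr)
    n_tr <- length(tr)
    history <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- tr[sample.int(n_tr)]
      ep_loss <- 0
      for (b0 in seq(1, n_tr, by = cfg$batch)) {
        idx <- ord[b0:min(b0 + cfg$batch - 1, n_tr)]
        xb <- qi_batch(x[idx, , drop = FALSE])
        yb <- y[idx]
        fw <- qi_forward(params, cfg, xb)
        z <- as.numeric(fw$logits$val)
        p <- 1 / (1 + exp(-z))
        ep_loss <- ep_loss - sum(yb * log(pmax(p, 1e-12)) +
                                 (1 - yb) * log(pmax(1 - p, 1e-12)))
        g <- array((p - yb) / length(yb), dim = dim(fw$logits$val))
        nn_backward(fw$tape, fw$logits, g)
        nadam_step(opt, fw$tape$pgrads)
      }
      history[ep] <- ep_loss / n_tr
    }
    m <- structure(list(params = params, cfg = cfg), class = "qi_model")
    val_scores <- qi_score(m, x[va, , drop = FALSE])
    thr <- select_threshold(val_scores, y[va], target_ppv = cfg$target_ppv)
    m$threshold <- as.numeric(thr)
    m$threshold_unattainable <- isTRUE(attr(thr, "unattainable"))
    m$val_scores <- val_scores
    m$val_labels <- y[va]
    m$val_patients <- val_pats
    m$history <- history
    m
  })
  model
}

#' Select the minimum score threshold achieving a target precision
#'
#' Sweeps the observed score values as candidate cut points and returns the
#' smallest threshold `t` such that the positive predictive value of
#' `score >= t` is at least `target_ppv`. When no threshold attains the
#' target, the maximum score is returned with attribute
#' `unattainable = TRUE` and a warning.
#'
#' @param scores numeric scores (probability of valid).
#' @param labels 0/1 (or logical / factor with `valid` positive) truth.
#' @param target_ppv required precision.
#' @return the threshold (numeric scalar).
#' @export
select_threshold <- function(scores, labels, target_ppv = 0.95) {
  if (!length(scores) || length(scores) != length(labels))
    stop("scores and labels must be non-empty and equal length")
  y <- if (is.numeric(labels)) as.integer(labels)
       else as.integer(as.character(labels) == "valid" | labels == TRUE)
  cand <- sort(unique(scores))
  for (t in cand) {
    pos <- scores >= t
    ppv <- sum(y[pos]) / sum(pos)
    if (ppv >= target_ppv) return(t)
  }
  warning("target PPV ", target_ppv, " unattainable; returning max score",
          call. = FALSE)
  structure(max(scores), unattainable = TRUE)
}

#' Quality indices of the eight 4-s subwindows of a 32-s window
#'
#' The window's QI is the minimum of the eight subwindow probabilities; the
#' window passes the quality filter iff that minimum reaches the threshold.
#'
#' @param ppg 32-s PPG window (`8 * input_len` samples).
#' @param model a [train_qi_model()] fit.
#' @return list with `qi` (8 probabilities, in subwindow order) and `min`.
#' @export
window_min_qi <- function(ppg, model) {
  len <- model$cfg$input_len
  if (length(ppg) != 8 * len)
    stop("window length ", length(ppg), " != 8 x ", len)
  sub <- matrix(ppg, nrow = 8, byrow = TRUE)
  qi <- qi_score(model, sub)
  list(qi = qi, min = min(qi))
}
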