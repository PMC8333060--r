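# Closed-form PPG-scaling baseline.

#' Scale a PPG window to the most recent NIBP pressures
#'
#' The baseline ABP predictor: the PPG is used as a template shape and
#' stretched affinely so that its window maximum equals the most recent
#' systolic NIBP and its minimum equals the diastolic NIBP:
#'
#' `scaled = (ppg - min(ppg)) * (sys - dias) / (max(ppg) - min(ppg)) + dias`
#'
#' The map is monotone (shape-preserving, correlation 1 with the input) and
#' idempotent: re-scaling an already scaled window with the same NIBP
#' reproduces it exactly. It is computed on the unstandardized PPG after
#' drift correction and low-pass filtering, and also serves as the
#' residual-learning anchor for the V-Net.
#'
#' @param ppg PPG window samples (any scale; must be non-constant).
#' @param nibp a [nibp_sample()] with `sys > dias`.
#' @return numeric vector in mmHg, with attributes `nibp` (the source
#'   sample) and `class` `"ppg_scaled"`.
#' @export
ppg_scale <- function(ppg, nibp) {
  lo <- min(ppg); hi <- max(ppg)
  if (hi <= lo) stop("degenerate window: constant PPG cannot be scaled")
  if (!(nibp$sys > nibp$dias))
    stop("invalid NIBP: systolic must exceed diastolic")
  out <- (ppg - lo) * (nibp$sys - nibp$dias) / (hi - lo) + nibp$dias
  attr(out, "nibp") <- nibp
  out
}
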