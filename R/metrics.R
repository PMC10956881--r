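# Pixel-wise confusion counts and the standard segmentation metric suite.
# Foreground (lesion) is 1, background 0.

#' Pixel-wise confusion counts
#'
#' @param pred binarized prediction in `{0, 1}`.
#' @param target ground truth in `{0, 1}`, same shape.
#' @return list with integer fields `tp`, `fp`, `tn`, `fn`
#'   (`tp + fp + tn + fn == length(pred)`).
#' @export
#' @examples
#' confusion(c(1, 1, 0, 1), c(1, 0, 0, 1))
confusion <- function(pred, target) {
  if (!identical(dim2(pred), dim2(target)))
    stop("pred and target must have identical shapes", call. = FALSE)
  if (!all(pred %in% c(0, 1)) || !all(target %in% c(0, 1)))
    stop("pred and target must be binary (0/1)", call. = FALSE)
  tp <- sum(pred == 1 & target == 1)
  fp <- sum(pred == 1 & target == 0)
  tn <- sum(pred == 0 & target == 0)
  fn <- sum(pred == 0 & target == 1)
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Segmentation metrics from confusion counts
#'
#' IoU = TP/(TP+FP+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), Dice = 2TP/(FP+2TP+FN).
#' Empty-denominator convention: when prediction and truth are both empty
#' (no positives anywhere) the overlap metrics are 1; a metric whose
#' denominator is zero is reported as 1 since there was nothing to miss.
#' `Dice = 2*IoU/(1+IoU)` holds identically.
#'
#' @param counts list with `tp`, `fp`, `tn`, `fn` (see [confusion()]).
#' @return named list with `dice`, `iou`, `sen`, `spe`, each in `[0, 1]`.
#' @export
#' @examples
#' seg_metrics(list(tp = 3, fp = 1, tn = 5, fn = 1))
seg_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (any(c(tp, fp, tn, fn) < 0))
    stop("confusion counts must be non-negative", call. = FALSE)
  if (tp + fp + tn + fn == 0) {
    warning("all confusion counts are zero; returning convention value 1")
    return(list(dice = 1, iou = 1, sen = 1, spe = 1))
  }
  safe <- function(num, den) if (den == 0) 1 else num / den
  list(dice = safe(2 * tp, fp + 2 * tp + fn),
       iou = safe(tp, tp + fp + fn),
       sen = safe(tp, tp + fn),
       spe = safe(tn, tn + fp))
}

binarize <- function(probs, threshold = 0.5) (probs > threshold) * 1
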