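# Compound segmentation loss: soft Dice + mean binary cross-entropy.
# Dice handles the foreground/background class imbalance; the cross-entropy
# term stabilizes backpropagation.

check_probs <- function(probs, target) {
  if (!identical(dim2(probs), dim2(target)))
    stop("probs and target must have identical shapes", call. = FALSE)
  if (any(probs < 0 | probs > 1))
    stop("probs must lie in [0, 1]", call. = FALSE)
  invisible(NULL)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Soft Dice loss
#'
#' `1 - (2 * sum(probs * target) + smooth) / (sum(probs) + sum(target) + smooth)`,
#' computed over all supplied elements. Uses soft probabilities (not
#' binarized predictions) so it is differentiable.
#'
#' @param probs predicted probabilities in `[0, 1]`.
#' @param target ground truth in `{0, 1}`, same shape.
#' @param smooth small positive smoothing constant (default 1).
#' @return a value in `[0, 1]`.
#' @export
#' @examples
#' dice_loss(c(1, 1, 0, 0), c(1, 0, 0, 0), smooth = 0)  # 1 - 2/3
dice_loss <- function(probs, target, smooth = 1) {
  check_probs(probs, target)
  num <- 2 * sum(probs * target) + smooth
  den <- sum(probs) + sum(target) + smooth
  1 - num / den
}

dice_loss_grad <- function(probs, target, smooth = 1) {
  num <- 2 * sum(probs * target) + smooth
  den <- sum(probs) + sum(target) + smooth
  -(2 * target * den - num) / den^2
}

#' Mean binary cross-entropy loss
#'
#' Probabilities are clamped to `[eps, 1 - eps]` for numerical safety.
#'
#' @inheritParams dice_loss
#' @param eps clamping constant.
#' @return non-negative mean cross-entropy (nats).
#' @export
#' @examples
#' bce_loss(rep(0.5, 10), rep(1, 10))  # log(2)
bce_loss <- function(probs, target, eps = 1e-7) {
  check_probs(probs, target)
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(target * log(p) + (1 - target) * log1p(-p))
}

bce_loss_grad <- function(probs, target, eps = 1e-7) {
  p <- pmin(pmax(probs, eps), 1 - eps)
  g <- (p - target) / (p * (1 - p)) / length(p)
  g[probs < eps | probs > 1 - eps] <- 0
  dim(g) <- dim(probs)
  g
}

#' Compound loss: Dice + binary cross-entropy
#'
#' @inheritParams dice_loss
#' @param eps clamping constant for the cross-entropy term.
#' @return list with `total`, `dice_term`, `bce_term`
#'   (`total = dice_term + bce_term`).
#' @export
combined_loss <- function(probs, target, smooth = 1, eps = 1e-7) {
  d <- dice_loss(probs, target, smooth)
  b <- bce_loss(probs, target, eps)
  list(total = d + b, dice_term = d, bce_term = b)
}

#' Gradient of the compound loss with respect to the probabilities
#'
#' @inheritParams combined_loss
#' @return array of the same shape as `probs`.
#' @export
combined_loss_grad <- function(probs, target, smooth = 1, eps = 1e-7) {
  g <- dice_loss_grad(probs, target, smooth) + bce_loss_grad(probs, target, eps)
  dim(g) <- dim(probs)
  g
}
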