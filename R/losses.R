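# Compound BCE + Dice training loss.
#
#   loss = w_bce * BCE(sigmoid(z), t) + w_dice * (1 - softDice)
#   softDice = (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps),  eps = 1
#
# BCE is the mean over pixels, computed in the numerically stable
# logits form max(z,0) - z*t + log(1 + exp(-|z|)). The smoothing eps is used
# in the loss only; evaluation metrics use raw counts.

bce_term <- function(logits, truth) {
  mean(pmax(logits, 0) - logits * truth + log1p(exp(-abs(logits))))
}

soft_dice <- function(prob, truth, eps = 1) {
  (2 * sum(prob * truth) + eps) / (sum(prob) + sum(truth) + eps)
}

#' Compound BCE + Dice loss
#'
#' Weighted sum of the binary cross-entropy (on logits, numerically stable)
#' and the soft Dice complement, the standard compound objective for extremely
#' foreground-imbalanced binary segmentation. Default weights are 0.5 / 0.5.
#'
#' @param logits numeric array of raw scores (any shape).
#' @param truth binary array (0/1), same shape.
#' @param w_bce,w_dice nonnegative component weights (defaults 0.5 each).
#' @param eps soft-Dice smoothing constant (default 1).
#' @return scalar loss.
#' @export
#' @examples
#' t <- matrix(c(1, 1, 0, 0), 2)
#' bce_dice_loss(matrix(0, 2, 2), t) # BCE term = log(2)
bce_dice_loss <- function(logits, truth, w_bce = 0.5, w_dice = 0.5, eps = 1) {
  if (!all(truth %in% c(0, 1))) stop("`truth` must be strictly binary (0/1)")
  stopifnot(length(logits) == length(truth), w_bce >= 0, w_dice >= 0)
  prob <- stats::plogis(logits)
  w_bce * bce_term(logits, truth) + w_dice * (1 - soft_dice(prob, truth, eps))
}

# tape node for the batched loss: logits variable (H, W, 1, B), truth array of
# the same shape. BCE averages over all pixels; the Dice term is computed per
# image and averaged over the batch.
op_bce_dice <- function(tape, logits, truth, w_bce = 0.5, w_dice = 0.5,
                        eps = 1) {
  z <- logits$v
  d <- dim(z)
  B <- d[4]
  npix <- length(z)
  prob <- stats::plogis(z)
  dim(prob) <- d
  bce <- bce_term(z, truth)
  np <- npix / B
  dice_grad <- array(0, d)
  dice_mean <- 0
  for (b in seq_len(B)) {
    p <- prob[, , , b]
    t <- truth[, , , b]
    num <- 2 * sum(p * t) + eps
    den <- sum(p) + sum(t) + eps
    dice_mean <- dice_mean + num / den
    # d softDice / d p_i = (2 t_i * den - num) / den^2
    dice_grad[, , , b] <- (2 * t * den - num) / den^2
  }
  dice_mean <- dice_mean / B
  val <- w_bce * bce + w_dice * (1 - dice_mean)
  if (!is.finite(val)) stop("non-finite loss value")
  make_node(tape, val, function(g) {
    dz_bce <- (prob - truth) / npix
    dz_dice <- -dice_grad / B * prob * (1 - prob)
    acc_grad(logits, g * (w_bce * dz_bce + w_dice * dz_dice))
  })
}
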