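# Multi-class soft Dice loss.
#
# Per class c the soft Dice is (2 * sum(p_c * g_c) + eps) /
# (sum(p_c) + sum(g_c) + eps) with one-hot ground truth g; the loss is
# 1 - mean over classes.  With eps = 1e-6 a class absent from both the
# target and the prediction scores a soft Dice of 1 (no penalty).  Sums run
# jointly over the whole batch.

onehot_mask <- function(gt, num_classes) {
  d <- dim(gt)
  if (length(d) == 2L) {
    gt <- array(gt, c(d, 1L))
    d <- dim(gt)
  }
  G <- array(0, c(d[1], d[2], num_classes, d[3]))
  for (k in seq_len(num_classes)) G[, , k, ] <- as.numeric(gt == (k - 1L))
  G
}

dice_per_class <- function(P, G, eps = 1e-6) {
  C <- dim(P)[3]
  vapply(seq_len(C), function(k) {
    p <- P[, , k, , drop = FALSE]
    g <- G[, , k, , drop = FALSE]
    (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)
  }, numeric(1))
}

#' Multi-class soft Dice loss
#'
#' @param probs `(H, W, C, N)` (or `(H, W, C)`) per-pixel class probability
#'   array; per-pixel channel sums must be within `1e-3` of 1.
#' @param gt `(H, W, N)` (or `(H, W)`) integer label array over
#'   `0:(C-1)`.
#' @param eps Dice smoothing constant (default `1e-6`).
#' @return A list of class `dice_loss` with `loss` (`1 - mean` soft Dice)
#'   and `per_class` soft Dice scores.
#' @export
dice_loss <- function(probs, gt, eps = 1e-6) {
  d <- dim(probs)
  if (length(d) == 3L) {
    dim(probs) <- c(d, 1L)
    d <- dim(probs)
  }
  sums <- apply(probs, c(1, 2, 4), sum)
  if (max(abs(sums - 1)) > 1e-3)
    stop("dice_loss: probabilities are not normalized over classes ",
         "(max |sum - 1| = ", format(max(abs(sums - 1))), ")")
  G <- onehot_mask(gt, d[3])
  pc <- dice_per_class(probs, G, eps)
  structure(list(loss = 1 - mean(pc), per_class = pc), class = "dice_loss")
}

# Autograd version used by the training loop: gt is constant, probs is a
# graph node (typically a softmax output).
ag_dice_loss <- function(probs, gt, eps = 1e-6) {
  probs <- ag_wrap(probs)
  d <- dim(probs$v)
  C <- d[3]
  G <- onehot_mask(gt, C)
  num <- den <- numeric(C)
  for (k in seq_len(C)) {
    num[k] <- 2 * sum(probs$v[, , k, ] * G[, , k, ]) + eps
    den[k] <- sum(probs$v[, , k, ]) + sum(G[, , k, ]) + eps
  }
  out <- ag_tensor(1 - mean(num / den))
  ag_record(out, list(probs), function(g) {
    gp <- array(0, d)
    for (k in seq_len(C)) {
      # d/dp of -dice_k / C at each pixel: -(2 g den_k - num_k) / (C den_k^2)
      gp[, , k, ] <- -g * (2 * G[, , k, ] * den[k] - num[k]) / (C * den[k]^2)
    }
    ag_accum(probs, gp)
  })
}
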