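# Compound segmentation loss — weighted cross-entropy plus class-averaged
# soft Dice — and the four evaluation metrics (overall accuracy, sensitivity,
# IoU, Dice similarity coefficient) computed from pooled pixel confusion
# counts.

softmax_channels <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, d[1L] * d[2L], d[3L])
  m <- m - row_max(m)
  e <- exp(m)
  p <- e / rowSums(e)
  dim(p) <- d
  p
}

check_mask <- function(mask, n_classes, shape = NULL) {
  if (!is.null(shape) && !identical(dim(mask), shape[1:2])) {
    stop("mask spatial shape does not match logits")
  }
  if (any(mask != floor(mask)) || any(mask < 0) || any(mask >= n_classes)) {
    stop(sprintf("mask labels must be integers in [0, %d)", n_classes))
  }
  invisible(TRUE)
}

#' Pixelwise cross-entropy loss
#'
#' Mean over pixels of the negative log softmax-probability of the true class.
#'
#' @param logits numeric array `[H, W, C]` of unnormalized class scores.
#' @param mask integer array `[H, W]` of class labels in `0..C-1`.
#' @return scalar loss.
#' @export
ce_loss <- function(logits, mask) {
  d <- dim(logits)
  check_mask(mask, d[3L], d)
  p <- matrix(softmax_channels(logits), d[1L] * d[2L], d[3L])
  idx <- cbind(seq_len(d[1L] * d[2L]), as.vector(mask) + 1L)
  -mean(log(pmax(p[idx], 1e-300)))
}

#' Soft Dice loss for one class
#'
#' `1 - (2 * sum(p_c * g_c) + eps) / (sum(p_c) + sum(g_c) + eps)` over all
#' pixels, with `p_c` the softmax probability of class `c` and `g_c` its
#' one-hot target.
#'
#' @param probs numeric array `[H, W, C]` of softmax probabilities.
#' @param mask integer array `[H, W]` of labels in `0..C-1`.
#' @param class_id class index in `0..C-1`.
#' @param eps smoothing constant preventing 0/0 on empty classes.
#' @return scalar loss in `[0, 1]`.
#' @export
dice_loss_per_class <- function(probs, mask, class_id, eps = 1e-5) {
  d <- dim(probs)
  check_mask(mask, d[3L], d)
  pc <- as.vector(probs[, , class_id + 1L])
  gc <- as.numeric(as.vector(mask) == class_id)
  1 - (2 * sum(pc * gc) + eps) / (sum(pc) + sum(gc) + eps)
}

#' Loss weights for the compound segmentation loss
#'
#' @param w_ce cross-entropy weight (default 0.7).
#' @param w_dice Dice weight (default 0.3).
#' @param dice_smooth Dice smoothing epsilon.
#' @return list of weights.
#' @export
loss_weights <- function(w_ce = 0.7, w_dice = 0.3, dice_smooth = 1e-5) {
  stopifnot(w_ce >= 0, w_dice >= 0, dice_smooth > 0)
  list(w_ce = w_ce, w_dice = w_dice, dice_smooth = dice_smooth)
}

#' Compound segmentation loss
#'
#' `w_ce * CE + w_dice * (1/C) * sum_c Dice_c`: weighted cross-entropy plus
#' the mean over classes of the soft Dice loss (defaults 0.7 / 0.3).
#'
#' @param logits numeric array `[H, W, C]`.
#' @param mask integer array `[H, W]` of labels in `0..C-1`.
#' @param weights a [loss_weights()] list.
#' @return scalar loss.
#' @export
combined_loss <- function(logits, mask, weights = loss_weights()) {
  d <- dim(logits)
  check_mask(mask, d[3L], d)
  p <- softmax_channels(logits)
  dice <- mean(vapply(seq_len(d[3L]) - 1L, function(c) {
    dice_loss_per_class(p, mask, c, eps = weights$dice_smooth)
  }, numeric(1)))
  weights$w_ce * ce_loss(logits, mask) + weights$w_dice * dice
}

# Fused tape op: combined loss from a logits node, with analytic gradient.
# Value agrees with combined_loss(); gradient is checked numerically in tests.
tn_combined_loss <- function(logits, mask, weights = loss_weights()) {
  lv <- logits$v
  d <- dim(lv)
  n <- d[1L] * d[2L]
  C <- d[3L]
  check_mask(mask, C, d)
  p <- matrix(softmax_channels(lv), n, C)
  g1h <- matrix(0, n, C)
  g1h[cbind(seq_len(n), as.vector(mask) + 1L)] <- 1
  eps <- weights$dice_smooth
  num <- 2 * colSums(p * g1h) + eps
  den <- colSums(p) + colSums(g1h) + eps
  dice <- mean(1 - num / den)
  ce <- -mean(log(pmax(p[cbind(seq_len(n), as.vector(mask) + 1L)], 1e-300)))
  val <- weights$w_ce * ce + weights$w_dice * dice
  tn_op(val, list(logits), function(g) {
    dce <- (p - g1h) / n
    # d Dice_c / d p_c = -(2 g_c * den_c - num_c) / den_c^2, averaged over C
    ddice <- -(2 * g1h * matrix(den, n, C, byrow = TRUE) -
                 matrix(num, n, C, byrow = TRUE)) /
      matrix(den^2, n, C, byrow = TRUE) / C
    dp <- weights$w_dice * ddice
    # chain through softmax for the Dice part; CE already includes it
    dz <- p * (dp - rowSums(dp * p)) + weights$w_ce * dce
    dz <- g * dz
    dim(dz) <- d
    list(dz)
  })
}

## ---- metrics --------------------------------------------------------------

#' Pixel confusion counts for a foreground class
#'
#' @param pred_mask,true_mask equal-shape integer arrays of class labels.
#' @param foreground_class label treated as foreground (default 1, the lesion
#'   class in the binary setting).
#' @return list of counts `tp`, `fp`, `fn`, `tn`, `total`.
#' @export
confusion <- function(pred_mask, true_mask, foreground_class = 1L) {
  if (!identical(dim(pred_mask), dim(true_mask))) {
    stop("confusion: prediction and truth shapes differ")
  }
  p <- as.vector(pred_mask) == foreground_class
  t <- as.vector(true_mask) == foreground_class
  list(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t), tn = sum(!p & !t),
       total = length(p))
}

add_confusion <- function(a, b) {
  list(tp = a$tp + b$tp, fp = a$fp + b$fp, fn = a$fn + b$fn, tn = a$tn + b$tn,
       total = a$total + b$total)
}

safe_ratio <- function(num, den) if (den == 0) 1 else num / den

#' Segmentation metrics from confusion counts
#'
#' Overall accuracy `(tp+tn)/total`, sensitivity `tp/(tp+fn)`, intersection
#' over union `tp/(tp+fp+fn)` and Dice similarity `2tp/(2tp+fp+fn)`, as
#' fractions in `[0, 1]`. A zero denominator (the condition is vacuously met)
#' reports 1.
#'
#' @param counts a [confusion()] list.
#' @return list `oa`, `sensitivity`, `iou`, `dsc`.
#' @export
metrics <- function(counts) {
  if (counts$total <= 0) stop("metrics: empty evaluation set")
  list(
    oa = (counts$tp + counts$tn) / counts$total,
    sensitivity = safe_ratio(counts$tp, counts$tp + counts$fn),
    iou = safe_ratio(counts$tp, counts$tp + counts$fp + counts$fn),
    dsc = safe_ratio(2 * counts$tp, 2 * counts$tp + counts$fp + counts$fn)
  )
}

format_metrics_pct <- function(m) {
  vapply(m, function(v) round(100 * v, 2), numeric(1))
}
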