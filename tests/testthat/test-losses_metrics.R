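# Closed-form loss values, the compound loss, and metric identities against
# a pixel-loop oracle.

test_that("cross-entropy matches closed forms", {
  # uniform logits, two classes: -log(1/2)
  logits <- array(0, c(4, 4, 2))
  mask <- array(sample(0:1, 16, TRUE), c(4, 4))
  expect_equal(ce_loss(logits, mask), log(2), tolerance = 1e-12)
  # single pixel, logits (0, log 3), true class 0: softmax (1/4, 3/4) -> log 4
  l1 <- array(c(0, log(3)), c(1, 1, 2))
  expect_equal(ce_loss(l1, array(0L, c(1, 1))), log(4), tolerance = 1e-12)
  # hugely confident correct prediction: loss ~ 0
  big <- array(0, c(3, 3, 2))
  m <- array(sample(0:1, 9, TRUE), c(3, 3))
  for (i in 1:3) for (j in 1:3) big[i, j, m[i, j] + 1] <- 50
  expect_lt(ce_loss(big, m), 1e-8)
  expect_error(ce_loss(logits, array(2L, c(4, 4))), "labels")
})

test_that("soft Dice matches hand-computed values", {
  # p_c = 0.5 everywhere, target all class c on 4 pixels:
  # 1 - (2*2 + eps) / (2 + 4 + eps) ~ 1/3
  probs <- array(0.5, c(2, 2, 2))
  mask <- array(1L, c(2, 2))
  expect_equal(dice_loss_per_class(probs, mask, 1L), 1 / 3, tolerance = 1e-4)
  # perfect hard prediction -> ~ 0; fully disjoint -> ~ 1
  hard <- array(0, c(2, 2, 2)); hard[, , 2] <- 1
  expect_lt(dice_loss_per_class(hard, mask, 1L), 1e-5)
  expect_gt(dice_loss_per_class(hard, array(0L, c(2, 2)), 1L), 1 - 1e-4)
})

test_that("combined loss weights cross-entropy and mean per-class Dice", {
  set.seed(40)
  logits <- array(rnorm(2 * 1 * 2), c(2, 1, 2))
  mask <- array(c(0L, 1L), c(2, 1))
  # independent scalar computation of 0.7*CE + 0.3*mean-Dice
  p <- exp(logits)
  for (i in 1:2) p[i, 1, ] <- p[i, 1, ] / sum(p[i, 1, ])
  ce_hand <- -(log(p[1, 1, 1]) + log(p[2, 1, 2])) / 2
  eps <- 1e-5
  dice_hand <- mean(c(
    1 - (2 * p[1, 1, 1] + eps) / (p[1, 1, 1] + p[2, 1, 1] + 1 + eps),
    1 - (2 * p[2, 1, 2] + eps) / (p[1, 1, 2] + p[2, 1, 2] + 1 + eps)
  ))
  expect_equal(combined_loss(logits, mask), 0.7 * ce_hand + 0.3 * dice_hand,
               tolerance = 1e-10)
  # weight (0, 1) reduces to the mean per-class Dice loss
  expect_equal(combined_loss(logits, mask, loss_weights(0, 1)), dice_hand,
               tolerance = 1e-10)
  # perfect prediction: both terms ~ 0
  big <- array(0, c(2, 1, 2)); big[1, 1, 1] <- 60; big[2, 1, 2] <- 60
  expect_lt(combined_loss(big, mask), 1e-5)
})

test_that("combined loss is non-negative and decreases with confidence", {
  mask <- array(1L, c(1, 1))
  losses <- vapply(seq(-2, 6, by = 1), function(z) {
    combined_loss(array(c(0, z), c(1, 1, 2)), mask)
  }, numeric(1))
  expect_true(all(losses >= 0))
  expect_true(all(diff(losses) < 0))
})

test_that("fused training-loss op agrees with the public loss and its gradient checks out", {
  set.seed(41)
  logits <- array(rnorm(4 * 3 * 2), c(4, 3, 2))
  mask <- array(sample(0:1, 12, TRUE), c(4, 3))
  node <- hyperseg:::tn_param(logits)
  loss <- hyperseg:::tn_combined_loss(node, mask)
  expect_equal(loss$v, combined_loss(logits, mask), tolerance = 1e-12)
  hyperseg:::tn_backward(loss)
  ng <- num_grad(function(v) combined_loss(array(v, dim(logits)), mask), logits)
  expect_lt(max(abs(node$grad - ng)), 1e-6)
})

test_that("confusion counts match the pixel-loop oracle", {
  # 4-pixel toy: pred (f,f,b,b) vs true (f,b,f,b)
  pred <- array(c(1L, 1L, 0L, 0L), c(2, 2))
  true <- array(c(1L, 0L, 1L, 0L), c(2, 2))
  cc <- confusion(pred, true)
  expect_equal(cc[c("tp", "fp", "fn", "tn")], list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))

  set.seed(42)
  for (rep in 1:5) {
    p <- array(sample(0:1, 64, TRUE), c(8, 8))
    t <- array(sample(0:1, 64, TRUE), c(8, 8))
    expect_equal(confusion(p, t), ref_confusion(p, t))
  }
  expect_error(confusion(array(0L, c(2, 2)), array(0L, c(3, 3))), "shapes")
  allfg <- confusion(array(1L, c(2, 5)), array(0L, c(2, 5)))
  expect_equal(c(allfg$fp, allfg$tp), c(10L, 0L))
})

test_that("metrics reproduce plug-in values and the DSC-IoU identity", {
  m <- metrics(list(tp = 1, fp = 1, fn = 1, tn = 1, total = 4))
  expect_equal(m$oa, 0.5)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$iou, 1 / 3)
  expect_equal(m$dsc, 0.5)
  perfect <- metrics(list(tp = 5, fp = 0, fn = 0, tn = 5, total = 10))
  expect_true(all(unlist(perfect) == 1))
  expect_gte(m$dsc, m$iou)

  set.seed(43)
  for (rep in 1:20) {
    cc <- as.list(c(stats::setNames(sample(0:20, 4, TRUE), c("tp", "fp", "fn", "tn"))))
    cc$total <- cc$tp + cc$fp + cc$fn + cc$tn
    if (cc$total == 0) next
    mm <- metrics(cc)
    expect_equal(mm$dsc, 2 * mm$iou / (1 + mm$iou), tolerance = 1e-12)
  }
  expect_error(metrics(list(tp = 0, fp = 0, fn = 0, tn = 0, total = 0)), "empty")
})
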