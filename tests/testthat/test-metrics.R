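# Confusion counts and the four evaluation metrics.

test_that("confusion counts match the per-pixel loop oracle", {
  set.seed(21)
  for (i in 1:100) {
    pred <- matrix(sample(0:1, 256, TRUE), 16, 16)
    gt <- matrix(sample(0:1, 256, TRUE), 16, 16)
    cc <- confusion_counts(pred, gt, K = 2)
    orc <- oracle_confusion(pred, gt, 2)
    expect_identical(as.integer(cc$tp), orc$tp)
    expect_identical(as.integer(cc$fp), orc$fp)
    expect_identical(as.integer(cc$fn), orc$fn)
    expect_identical(as.integer(cc$tn), orc$tn)
  }
})

test_that("count identities hold", {
  set.seed(22)
  pred <- matrix(sample(0:1, 64, TRUE), 8, 8)
  gt <- matrix(sample(0:1, 64, TRUE), 8, 8)
  cc <- confusion_counts(pred, gt)
  expect_true(all(cc$tp + cc$fp + cc$fn + cc$tn == 64))
  # binary complementarity: class-0 TP = class-1 TN
  expect_equal(cc$tp[1], cc$tn[2])
  expect_equal(cc$tp[2], cc$tn[1])
  # exact agreement / total disagreement
  agree <- confusion_counts(gt, gt)
  expect_true(all(agree$fp == 0) && all(agree$fn == 0))
  dis <- confusion_counts(1L - gt, gt)
  expect_true(all(dis$tp == 0) && all(dis$tn == 0))
  expect_error(confusion_counts(matrix(2L, 2, 2), matrix(0L, 2, 2), K = 2),
               class = "capseg_invalid_input")
})

test_that("metrics reproduce the constructed 100-pixel example", {
  # fg GT 65 (TP 50, FN 15), bg GT 35 (TN 25, FP 10)
  gt <- c(rep(1L, 65), rep(0L, 35))
  pred <- c(rep(1L, 50), rep(0L, 15), rep(1L, 10), rep(0L, 25))
  m <- compute_metrics(confusion_counts(pred, gt))
  expect_equal(m$miou, 100 * mean(c(50 / 75, 25 / 50)), tolerance = 1e-10)
  expect_equal(round(m$miou, 2), 58.33)
  expect_equal(round(m$mpa, 2), 74.18)
  expect_equal(round(m$precision, 2), 72.92)
  expect_equal(m$mpa, m$recall)  # macro-recall reading of mPA
  expect_equal(m$global_acc, 75)
})

test_that("perfect prediction scores 100 everywhere", {
  gt <- matrix(sample(0:1, 100, TRUE), 10, 10)
  m <- compute_metrics(confusion_counts(gt, gt))
  expect_equal(c(m$miou, m$mpa, m$precision, m$recall, m$global_acc),
               rep(100, 5))
})

test_that("macro averaging is symmetric under label swap", {
  set.seed(23)
  pred <- matrix(sample(0:1, 144, TRUE), 12, 12)
  gt <- matrix(sample(0:1, 144, TRUE), 12, 12)
  m1 <- compute_metrics(confusion_counts(pred, gt))
  m2 <- compute_metrics(confusion_counts(1L - pred, 1L - gt))
  expect_equal(m1$miou, m2$miou)
  expect_equal(m1$mpa, m2$mpa)
})

test_that("per-class IoU never exceeds recall or precision", {
  set.seed(24)
  for (i in 1:20) {
    pred <- matrix(sample(0:1, 64, TRUE), 8, 8)
    gt <- matrix(sample(0:1, 64, TRUE, prob = c(0.7, 0.3)), 8, 8)
    m <- compute_metrics(confusion_counts(pred, gt))
    pc <- m$per_class
    ok <- !is.na(pc$iou)
    expect_true(all(pc$iou[ok] <= pc$recall[ok] + 1e-9, na.rm = TRUE))
    expect_true(all(pc$iou[ok] <= pc$precision[ok] + 1e-9, na.rm = TRUE))
  }
})

test_that("pooled counts equal the concatenated pixel stream", {
  set.seed(25)
  p1 <- matrix(sample(0:1, 64, TRUE), 8, 8)
  g1 <- matrix(sample(0:1, 64, TRUE), 8, 8)
  p2 <- matrix(sample(0:1, 36, TRUE), 6, 6)
  g2 <- matrix(sample(0:1, 36, TRUE), 6, 6)
  pooled <- confusion_counts(p1, g1) + confusion_counts(p2, g2)
  stream <- confusion_counts(c(p1, p2), c(g1, g2))
  expect_identical(unclass(pooled), unclass(stream))
  expect_equal(compute_metrics(pooled)$miou, compute_metrics(stream)$miou)
})

test_that("classes absent from prediction and truth are skipped", {
  pred <- matrix(0L, 4, 4)
  gt <- matrix(0L, 4, 4)
  m <- compute_metrics(confusion_counts(pred, gt, K = 2))
  expect_equal(m$miou, 100)       # only the background class participates
  expect_true(is.na(m$fg_iou))
})
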