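#' Per-class confusion counts
#'
#' Exact integer tallies of true/false positives/negatives per class, the
#' sole input to all evaluation metrics. Counts from several images can be
#' pooled with [add_counts()] (or `+`); metrics of pooled counts equal
#' metrics of the concatenated pixel stream.
#'
#' @param pred Integer predicted mask, entries in `0..K-1`.
#' @param gt Integer ground-truth mask, same shape.
#' @param K Number of classes (default 2).
#' @return Object of class `confusion_counts`: `K`, `tp`, `fp`, `fn`, `tn`
#'   (length-K integer vectors) and `total` pixels.
#' @export
confusion_counts <- function(pred, gt, K = 2L) {
  K <- as.integer(K)
  pv <- as.integer(pred)
  gv <- as.integer(gt)
  if (length(pv) != length(gv))
    stop_invalid("prediction and ground truth sizes disagree")
  if (any(pv < 0L | pv >= K) || any(gv < 0L | gv >= K))
    stop_invalid("mask labels outside 0..%d", K - 1L)
  # cm[i, j] = #(gt == i-1 & pred == j-1)
  cm <- matrix(tabulate(gv + K * pv + 1L, nbins = K * K), K, K)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  total <- length(gv)
  structure(list(K = K, tp = tp, fp = fp, fn = fn,
                 tn = total - tp - fp - fn, total = total),
            class = "confusion_counts")
}

#' Pool confusion counts
#' @param a,b `confusion_counts` objects with the same K.
#' @return Pooled `confusion_counts`.
#' @export
add_counts <- function(a, b) {
  if (a$K != b$K) stop_invalid("cannot pool counts with different K")
  structure(list(K = a$K, tp = a$tp + b$tp, fp = a$fp + b$fp,
                 fn = a$fn + b$fn, tn = a$tn + b$tn,
                 total = a$total + b$total),
            class = "confusion_counts")
}

#' @export
`+.confusion_counts` <- function(e1, e2) add_counts(e1, e2)

#' Segmentation metrics from confusion counts
#'
#' Per-class IoU `TP / (TP + FP + FN)`, precision `TP / (TP + FP)` and
#' recall `TP / (TP + FN)` are macro-averaged over classes (background
#' included) and reported as percentages. Mean pixel accuracy (mPA) is the
#' macro mean of per-class recall, which reproduces the identity
#' `mPA == Recall` seen in class-mean reporting; the literal global pixel
#' accuracy `sum(TP) / total` is reported separately. Classes absent from
#' both prediction and ground truth are skipped from the macro means; any
#' per-metric zero denominator skips that class and is flagged.
#'
#' @param cc A [confusion_counts()] object.
#' @return Object of class `metrics_report`: `miou`, `mpa`, `precision`,
#'   `recall`, `global_acc`, foreground-only `fg_iou`, `fg_precision`,
#'   `fg_recall` (all percentages), `skipped` (per-metric skip flags) and
#'   `per_class` (data frame of per-class values).
#' @export
compute_metrics <- function(cc) {
  if (cc$total < 1L) stop_invalid("no pixels tallied")
  present <- (cc$tp + cc$fn + cc$fp) > 0L
  iou_den <- cc$tp + cc$fp + cc$fn
  pre_den <- cc$tp + cc$fp
  rec_den <- cc$tp + cc$fn
  safe_mean <- function(num, den, ok) {
    use <- ok & den > 0L
    if (!any(use)) return(list(v = NA_real_, skip = which(ok & den == 0L)))
    list(v = 100 * mean(num[use] / den[use]), skip = which(ok & den == 0L))
  }
  iou <- safe_mean(cc$tp, iou_den, present)
  pre <- safe_mean(cc$tp, pre_den, present)
  rec <- safe_mean(cc$tp, rec_den, present)
  per_class <- data.frame(
    class = seq_len(cc$K) - 1L,
    tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
    iou = ifelse(iou_den > 0, 100 * cc$tp / iou_den, NA_real_),
    precision = ifelse(pre_den > 0, 100 * cc$tp / pre_den, NA_real_),
    recall = ifelse(rec_den > 0, 100 * cc$tp / rec_den, NA_real_))
  structure(list(
    miou = iou$v, mpa = rec$v, precision = pre$v, recall = rec$v,
    global_acc = 100 * sum(cc$tp) / cc$total,
    fg_iou = per_class$iou[2L], fg_precision = per_class$precision[2L],
    fg_recall = per_class$recall[2L],
    skipped = list(iou = iou$skip, precision = pre$skip, recall = rec$skip),
    per_class = per_class, n_pixels = cc$total),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "mIoU %s%%  mPA %s%%  Precision %s%%  Recall %s%%  GlobalAcc %s%%\n",
    fmt_pct(x$miou), fmt_pct(x$mpa), fmt_pct(x$precision),
    fmt_pct(x$recall), fmt_pct(x$global_acc)))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(mIoU = x$miou, mPA = x$mpa, Precision = x$precision,
             Recall = x$recall, GlobalAcc = x$global_acc,
             FgIoU = x$fg_iou, FgPrecision = x$fg_precision,
             FgRecall = x$fg_recall)
}
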