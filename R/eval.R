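# Two-level screening evaluation.
#
# Image level: an image is called positive when total clue-cell box area
# exceeds 20% (strictly) of the combined clue + epithelial box area; SEN,
# SPE and ACC are computed over image labels. Object level: greedy
# confidence-ordered one-to-one matching at an IoU threshold gives
# precision, recall and F1 (clue class by default). Zero-denominator
# metrics are reported as NA, never as a silent 0.

#' Image-level positive/negative label
#'
#' Let `A_c` be the total clue-cell box area and `A_e` the total epithelial
#' box area. The image is positive iff `A_c / (A_c + A_e) > threshold`
#' (strict: a fraction of exactly 20% is negative); an image with no boxes
#' is negative. Works on ground-truth boxes and on detections alike.
#'
#' @param boxes `data.frame` with a `class` column (0 = clue,
#'   1 = epithelial) and either pixel corners `x1, y1, x2, y2` or
#'   normalised `w, h`.
#' @param threshold Area-fraction threshold (default 0.2).
#' @return `"positive"` or `"negative"`.
#' @export
image_level_label <- function(boxes, threshold = 0.2) {
  if (nrow(boxes) == 0) return("negative")
  areas <- if (all(c("x1", "x2", "y1", "y2") %in% names(boxes))) {
    (boxes$x2 - boxes$x1) * (boxes$y2 - boxes$y1)
  } else {
    boxes$w * boxes$h
  }
  a_c <- sum(areas[boxes$class == 0L])
  a_e <- sum(areas[boxes$class == 1L])
  if (a_c + a_e <= 0) return("negative")
  if (a_c / (a_c + a_e) > threshold) "positive" else "negative"
}

#' Image-level confusion counts and SEN/SPE/ACC
#'
#' @param pred,truth Equal-length vectors of `"positive"`/`"negative"`
#'   labels (logicals are accepted, `TRUE` = positive).
#' @return List with `counts` (tp, tn, fp, fn), `sen`, `spe`, `acc`;
#'   metrics with empty denominators are `NA`.
#' @export
image_metrics <- function(pred, truth) {
  as_pos <- function(x) {
    if (is.logical(x)) x else x == "positive"
  }
  p <- as_pos(pred)
  t <- as_pos(truth)
  if (length(p) != length(t)) stop("`pred` and `truth` lengths differ")
  tp <- sum(p & t); tn <- sum(!p & !t)
  fp <- sum(p & !t); fn <- sum(!p & t)
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- if (length(p) > 0) (tp + tn) / length(p) else NA_real_
  list(counts = list(tp = tp, tn = tn, fp = fp, fn = fn),
       sen = sen, spe = spe, acc = acc)
}

#' Object-level precision/recall/F1
#'
#' Detections are matched to ground truth greedily in descending
#' confidence: each detection claims the unmatched same-class ground-truth
#' box with the highest IoU at or above `iou_threshold`. Unmatched
#' detections count as FP, unmatched ground truth as FN. By default the
#' metrics are computed on the clue class only (`classes = 0`); pass
#' `classes = NULL` for all classes pooled. If both inputs carry an
#' `image` column, matching is done within images.
#'
#' @param detections `data.frame` with `class`, `confidence`,
#'   `x1, y1, x2, y2` (and optionally `image`).
#' @param gt `data.frame` with `class`, `x1, y1, x2, y2` (and optionally
#'   `image`).
#' @param iou_threshold Match threshold (default 0.5).
#' @param classes Class ids the metrics are restricted to, or `NULL`.
#' @return List with `counts` (tp, fp, fn), `precision`, `recall`, `f1`
#'   (`NA` where the denominator is empty).
#' @export
object_metrics <- function(detections, gt, iou_threshold = 0.5,
                           classes = 0L) {
  if (!is.null(classes)) {
    detections <- detections[detections$class %in% classes, , drop = FALSE]
    gt <- gt[gt$class %in% classes, , drop = FALSE]
  }
  imgs <- if ("image" %in% names(detections) && "image" %in% names(gt)) {
    unique(c(detections$image, gt$image))
  } else {
    detections$image <- rep("img", nrow(detections))
    gt$image <- rep("img", nrow(gt))
    "img"
  }
  tp <- 0L; fp <- 0L; fn <- 0L
  for (im in imgs) {
    d <- detections[detections$image == im, , drop = FALSE]
    g <- gt[gt$image == im, , drop = FALSE]
    d <- d[order(d$confidence, decreasing = TRUE), , drop = FALSE]
    matched <- rep(FALSE, nrow(g))
    for (i in seq_len(nrow(d))) {
      best <- 0
      bestj <- 0L
      for (j in seq_len(nrow(g))) {
        if (matched[j] || g$class[j] != d$class[i]) next
        iou <- box_iou_matrix(
          matrix(as.numeric(d[i, c("x1", "y1", "x2", "y2")]), 1),
          matrix(as.numeric(g[j, c("x1", "y1", "x2", "y2")]), 1))[1, 1]
        if (iou >= iou_threshold && iou > best) {
          best <- iou
          bestj <- j
        }
      }
      if (bestj > 0L) {
        matched[bestj] <- TRUE
        tp <- tp + 1L
      } else {
        fp <- fp + 1L
      }
    }
    fn <- fn + sum(!matched)
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  list(counts = list(tp = tp, fp = fp, fn = fn),
       precision = precision, recall = recall, f1 = f1)
}

#' ROC and PR curves with AUC / AUPRC
#'
#' Threshold sweep over the unique scores (ties grouped). ROC AUC by the
#' trapezoid rule (equals the Mann-Whitney statistic with the usual 1/2 tie
#' credit); AUPRC by the step-wise rule `sum (R_i - R_{i-1}) * P_i` without
#' interpolation.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels 0/1 or logical truth; needs at least one of each class.
#' @return List with `roc` (data frame `threshold`, `fpr`, `tpr`), `auc`,
#'   `pr` (data frame `threshold`, `recall`, `precision`), `auprc`.
#' @export
curves <- function(scores, labels) {
  y <- if (is.logical(labels)) labels else labels == 1
  if (!any(y) || all(y)) {
    stop("`labels` must contain at least one positive and one negative")
  }
  np <- sum(y)
  nn <- sum(!y)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yy <- y[ord]
  cum_tp <- cumsum(yy)
  cum_fp <- cumsum(!yy)
  last <- !duplicated(s, fromLast = TRUE) # last index within each tie group
  tp <- cum_tp[last]
  fp <- cum_fp[last]
  thr <- s[last]
  tpr <- c(0, tp / np)
  fpr <- c(0, fp / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  precision <- tp / (tp + fp)
  recall <- tp / np
  auprc <- sum(diff(c(0, recall)) * precision)
  list(roc = data.frame(threshold = thr, fpr = fpr[-1], tpr = tpr[-1]),
       auc = auc,
       pr = data.frame(threshold = thr, recall = recall,
                       precision = precision),
       auprc = auprc)
}
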