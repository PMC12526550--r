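test_that("image-level 20% area rule with strict boundary", {
  b <- function(classes, areas) {
    data.frame(class = classes, x1 = rep(0, length(classes)),
               y1 = rep(0, length(classes)), x2 = sqrt(areas),
               y2 = sqrt(areas))
  }
  expect_equal(image_level_label(b(c(0, 1), c(300, 700))), "positive")
  expect_equal(image_level_label(b(1, 500)), "negative")
  expect_equal(image_level_label(b(integer(0), numeric(0))), "negative")
  # exactly 20% is negative: "more than" is strict
  expect_equal(image_level_label(b(c(0, 1), c(200, 800))), "negative")
  expect_equal(image_level_label(b(c(0, 1), c(200 + 1e-9, 800))), "positive")
})

test_that("image_metrics worked example and edge conventions", {
  pred <- c(rep("positive", 17), rep("negative", 83))
  truth <- c(rep("positive", 7), rep("negative", 10),
             rep("positive", 3), rep("negative", 80))
  m <- image_metrics(pred, truth)
  expect_equal(m$counts, list(tp = 7, tn = 80, fp = 10, fn = 3))
  expect_equal(m$sen, 0.7)
  expect_equal(m$spe, 80 / 90, tolerance = 1e-9)
  expect_equal(m$acc, 0.87)
  all_pos <- image_metrics(rep("positive", 5), rep("positive", 5))
  expect_equal(all_pos$sen, 1)
  expect_true(is.na(all_pos$spe)) # no negatives: undefined, not 0
  expect_error(image_metrics("positive", c("positive", "negative")),
               "length")
})

test_that("image_metrics agrees with a brute-force tally on random vectors", {
  set.seed(100)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    pred <- sample(c(TRUE, FALSE), n, replace = TRUE)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    m <- image_metrics(pred, truth)
    tp <- 0L; tn <- 0L; fp <- 0L; fn <- 0L
    for (j in seq_len(n)) {
      if (pred[j] && truth[j]) tp <- tp + 1L
      else if (!pred[j] && !truth[j]) tn <- tn + 1L
      else if (pred[j]) fp <- fp + 1L
      else fn <- fn + 1L
    }
    expect_equal(m$counts, list(tp = tp, tn = tn, fp = fp, fn = fn))
    if (tp + fn > 0) expect_equal(m$sen, tp / (tp + fn))
    expect_equal(m$acc, (tp + tn) / n)
  }
})

test_that("object_metrics matching arithmetic", {
  gt <- data.frame(class = 0L, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  det_same <- data.frame(class = 0L, confidence = 0.9, x1 = 0, y1 = 0,
                         x2 = 10, y2 = 10)
  m <- object_metrics(det_same, gt)
  expect_equal(m$counts$tp, 1)
  expect_equal(m$f1, 1)
  # IoU 1/3 < 0.5: detection unmatched -> 1 FP and 1 FN
  det_shift <- data.frame(class = 0L, confidence = 0.9, x1 = 0, y1 = 5,
                          x2 = 10, y2 = 15)
  m2 <- object_metrics(det_shift, gt)
  expect_equal(m2$counts, list(tp = 0, fp = 1, fn = 1))
  # two detections on one gt: 1 TP + 1 FP, F1 = 2/3
  det_two <- rbind(det_same, transform(det_same, confidence = 0.5))
  m3 <- object_metrics(det_two, gt)
  expect_equal(m3$counts, list(tp = 1, fp = 1, fn = 0))
  expect_equal(m3$recall, 1)
  expect_equal(m3$precision, 0.5)
  expect_equal(m3$f1, 2 * 0.5 / 1.5)
  # class mismatch never matches
  det_wrong <- transform(det_same, class = 1L)
  expect_equal(object_metrics(det_wrong, gt, classes = NULL)$counts$tp, 0)
})

test_that("precision/recall move monotonically with confidence threshold", {
  set.seed(7)
  gt <- data.frame(class = 0L,
                   x1 = runif(8, 0, 200), y1 = runif(8, 0, 200))
  gt$x2 <- gt$x1 + 30
  gt$y2 <- gt$y1 + 30
  det <- gt
  det$x1 <- det$x1 + rnorm(8, sd = 8)
  det$x2 <- det$x2 + rnorm(8, sd = 8)
  det$confidence <- runif(8)
  det <- rbind(det, data.frame(class = 0L, x1 = 300, y1 = 300, x2 = 330,
                               y2 = 330, confidence = runif(1)))
  rec <- prec <- numeric(0)
  for (thr in seq(0, 1, by = 0.1)) {
    d <- det[det$confidence >= thr, , drop = FALSE]
    m <- object_metrics(d, gt)
    rec <- c(rec, ifelse(is.na(m$recall), 0, m$recall))
  }
  expect_true(all(diff(rec) <= 1e-12)) # recall never increases
})

test_that("curves: trivial cases and the 4-item hand case", {
  p <- curves(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(p$auc, 1)
  expect_equal(p$auprc, 1)
  tied <- curves(rep(0.5, 10), rep(c(1, 0), 5))
  expect_equal(tied$auc, 0.5)
  # hand case: scores .9 .8 .4 .1, labels 1 0 1 0
  h <- curves(c(0.9, 0.8, 0.4, 0.1), c(1, 0, 1, 0))
  # brute-force threshold enumeration: points (0,1/2), (1/2,1/2), (1/2,1), (1,1)
  expect_equal(h$auc, 0.75)
  # stepwise AUPRC: 1/2 * 1 + 1/2 * 2/3
  expect_equal(h$auprc, 0.5 * 1 + 0.5 * 2 / 3)
  expect_error(curves(c(1, 2), c(1, 1)), "positive and one negative")
})

test_that("trapezoid AUC equals the rank statistic on seeded score sets", {
  set.seed(55)
  for (i in 1:100) {
    n <- sample(6:25, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.4))
    s <- round(rnorm(n), sample(0:2, 1)) # rounding induces ties
    expect_equal(curves(s, y)$auc, oracle_auc_rank(s, y), tolerance = 1e-9)
  }
})

test_that("detections round-trip through YOLO-with-confidence text", {
  det <- data.frame(class = c(0L, 1L), confidence = c(0.91, 0.42),
                    x1 = c(10, 100), y1 = c(20, 110),
                    x2 = c(60, 180), y2 = c(70, 150))
  pth <- tempfile(fileext = ".txt")
  write_detections(det, pth, 256, 256)
  back <- read_detections(pth, 256, 256)
  expect_equal(back$class, det$class)
  expect_equal(back$confidence, det$confidence, tolerance = 1e-6)
  expect_equal(back$x1, det$x1, tolerance = 256 * 2e-6)
  write_detections(det[0, ], pth, 256, 256)
  expect_equal(nrow(read_detections(pth, 256, 256)), 0)
  unlink(pth)
})
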