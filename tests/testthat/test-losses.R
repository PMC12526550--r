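test_that("bce_loss closed forms", {
  expect_equal(bce_loss(1, 1 - 1e-9), 0, tolerance = 1e-6)
  expect_equal(bce_loss(1, 0.5), log(2))
  expect_equal(bce_loss(0, 0.5), log(2))
  expect_error(bce_loss(2, 0.5), "0 and 1")
})

test_that("focal_loss closed forms and limits", {
  expect_equal(focal_loss(1), 0, tolerance = 1e-6)
  expect_equal(focal_loss(0.5, gamma = 0, alpha = 1), log(2))
  # direct evaluation of the formula: 0.25 * 0.1^2 * (-ln 0.9)
  expect_equal(focal_loss(0.9, gamma = 2, alpha = 0.25),
               0.25 * 0.01 * -log(0.9), tolerance = 1e-9)
  expect_equal(focal_loss(0.9, gamma = 2, alpha = 0.25), 2.63401e-4,
               tolerance = 1e-4)
  expect_error(focal_loss(0.5, gamma = -1), "nonnegative")
})

test_that("focal with gamma=0, alpha=1 equals BCE on a 1000-point grid", {
  ys <- rep(c(0, 1), each = 500)
  ps <- rep(seq(0.001, 0.999, length.out = 500), 2)
  pt <- ifelse(ys == 1, ps, 1 - ps)
  expect_lt(max(abs(focal_loss(pt, gamma = 0, alpha = 1) -
                      bce_loss(ys, ps))), 1e-9)
})

test_that("focal loss is strictly decreasing in pt and ordered in gamma", {
  pt <- seq(0.01, 0.99, by = 0.01)
  for (g in c(0.5, 1.5, 3)) {
    v <- focal_loss(pt, gamma = g)
    expect_true(all(diff(v) < 0))
  }
  # easy examples (pt > 0.5): larger gamma down-weights more
  easy <- seq(0.55, 0.99, by = 0.01)
  expect_true(all(focal_loss(easy, gamma = 3) < focal_loss(easy, gamma = 1.5)))
  expect_true(all(focal_loss(easy, gamma = 1.5) < focal_loss(easy, gamma = 0.5)))
})

test_that("alpha_from_frequency implements normalised inverse frequency", {
  expect_equal(alpha_from_frequency(c(10, 10)), c(1, 1))
  a <- alpha_from_frequency(c(90, 10))
  expect_equal(a, c(0.2, 1.8))
  expect_equal(a[2] / a[1], 9)
  expect_equal(alpha_from_frequency(42), 1)
  expect_error(alpha_from_frequency(c(5, 0)), "positive")
})

test_that("ciou_loss basic contracts and oracle value", {
  b <- c(0, 0, 10, 10)
  expect_equal(ciou_loss(b, b), 0)
  # disjoint far-apart boxes stay within [0, 2]
  far <- ciou_loss(c(0, 0, 10, 10), c(500, 500, 520, 505))
  expect_gt(far, 1)
  expect_lte(far, 2)
  # explicit-formula oracle for the (0,0,10,10) vs (0,5,10,15) pair
  p <- c(0, 0, 10, 10); g <- c(0, 5, 10, 15)
  iou <- 50 / 150
  rho2 <- 25
  c2 <- 10^2 + 15^2
  v <- 4 / pi^2 * (atan(10 / 10) - atan(10 / 10))^2
  expect_equal(iou, 1 / 3)
  expect_equal(ciou_loss(p, g), 1 - (iou - rho2 / c2 - 0))
  expect_equal(v, 0)
  expect_error(ciou_loss(c(0, 0, 0, 10), g), "positive")
})

test_that("ciou_grad matches finite differences", {
  set.seed(31)
  for (i in 1:20) {
    g <- c(0, 0, 0, 0)
    g[1] <- runif(1, 0, 20); g[2] <- runif(1, 0, 20)
    g[3] <- g[1] + runif(1, 5, 30); g[4] <- g[2] + runif(1, 5, 30)
    p <- g + rnorm(4, sd = 4)
    if (p[3] - p[1] < 1) p[3] <- p[1] + 1
    if (p[4] - p[2] < 1) p[4] <- p[2] + 1
    gr <- cayolo:::ciou_grad(p, g)
    eps <- 1e-5
    for (j in 1:4) {
      pp <- p; pp[j] <- pp[j] + eps
      pm <- p; pm[j] <- pm[j] - eps
      num <- (ciou_loss(pp, g) - ciou_loss(pm, g)) / (2 * eps)
      expect_lt(abs(gr$grad[j] - num), 1e-4 + 1e-3 * abs(num))
    }
  }
})

test_that("dfl_loss closed forms and locality", {
  one_hot <- c(0, 0, 1, 0)
  expect_lt(dfl_loss(one_hot, 2), 1e-6 - log(1))
  expect_equal(dfl_loss(c(0.5, 0.5), 0.5), log(2))
  expect_error(dfl_loss(c(0.5, 0.5), 3), "range")
  expect_error(dfl_loss(c(0.5, 0.6), 0.5), "sum")
  # loss depends on non-bracketing bins only through their mass:
  # permuting bins 3 and 4 when the target lies in [0, 1] changes nothing
  d <- c(0.4, 0.3, 0.2, 0.1)
  dp <- c(0.4, 0.3, 0.1, 0.2)
  for (tgt in c(0.25, 0.5, 0.9)) {
    expect_equal(dfl_loss(d, tgt), dfl_loss(dp, tgt))
  }
})

test_that("dfl_loss_grad is softmax cross-entropy against the soft target", {
  set.seed(5)
  z <- rnorm(8)
  tgt <- 3.3
  r <- cayolo:::dfl_loss_grad(z, tgt)
  expect_equal(r$loss, dfl_loss(r$probs, tgt), tolerance = 1e-9)
  eps <- 1e-6
  for (j in c(1, 4, 8)) {
    zp <- z; zp[j] <- zp[j] + eps
    zm <- z; zm[j] <- zm[j] - eps
    num <- (cayolo:::dfl_loss_grad(zp, tgt)$loss -
              cayolo:::dfl_loss_grad(zm, tgt)$loss) / (2 * eps)
    expect_lt(abs(r$grad[j] - num), 1e-6)
  }
})

test_that("total_loss additivity identities hold exactly", {
  set.seed(8)
  A <- 20; K <- 2; n <- 5; nb <- 8
  pred <- list(cls = matrix(runif(A * K, 0.05, 0.95), A, K),
               box = cbind(runif(n, 0, 10), runif(n, 0, 10),
                           runif(n, 20, 30), runif(n, 20, 30)),
               dist = array(1 / nb, c(n, 4, nb)))
  target <- list(cls = matrix(rbinom(A * K, 1, 0.2), A, K),
                 box = cbind(runif(n, 0, 10), runif(n, 0, 10),
                             runif(n, 20, 30), runif(n, 20, 30)),
                 dfl = matrix(runif(n * 4, 0, nb - 1), n, 4))
  lb <- total_loss(pred, target, focal = focal_params(gamma = 1.5,
                                                      alpha = c(1.8, 0.2)))
  expect_identical(lb$l_cls_enhanced, lb$l_bce + lb$l_fl)
  expect_identical(lb$l_bbox, lb$l_ciou + lb$l_dfl)
  expect_identical(lb$l_total, lb$l_cls_enhanced + lb$l_bbox)
  expect_true(all(unlist(lb) >= 0))
  # gamma = 0, alpha = 1: enhanced classification is exactly twice BCE
  lb0 <- total_loss(pred, target, focal = focal_params(gamma = 0, alpha = 1))
  expect_equal(lb0$l_cls_enhanced, 2 * lb0$l_bce, tolerance = 1e-12)
  # empty assignment: classification on negatives only, box terms zero
  lbe <- total_loss(list(cls = pred$cls), list(cls = target$cls * 0))
  expect_identical(lbe$l_ciou, 0)
  expect_identical(lbe$l_dfl, 0)
  # perfect predictions drive everything to ~0
  lbp <- total_loss(
    list(cls = matrix(c(1 - 1e-9, 1e-9), 1),
         box = matrix(c(0, 0, 10, 10), 1),
         dist = array(rep(c(0, 1, 0, 0), each = 4), c(1, 4, 4))),
    list(cls = matrix(c(1, 0), 1), box = matrix(c(0, 0, 10, 10), 1),
         dfl = matrix(1, 1, 4)))
  expect_lt(lbp$l_total, 1e-5)
})

test_that("classification loss gradient matches finite differences", {
  set.seed(12)
  z <- matrix(rnorm(12), 6, 2)
  y <- matrix(rbinom(12, 1, 0.3), 6, 2)
  for (cfgi in list(list(g = 1.5, a = c(1.8, 0.2), uf = TRUE, fo = FALSE),
                    list(g = 0, a = 1, uf = TRUE, fo = FALSE),
                    list(g = 1.5, a = 1, uf = TRUE, fo = TRUE),
                    list(g = 1.5, a = 1, uf = FALSE, fo = FALSE))) {
    r <- cayolo:::cls_loss_grad(z, y, gamma = cfgi$g, alpha = cfgi$a,
                                use_focal = cfgi$uf, focal_only = cfgi$fo)
    lossf <- function(zz) {
      rr <- cayolo:::cls_loss_grad(zz, y, gamma = cfgi$g, alpha = cfgi$a,
                                   use_focal = cfgi$uf, focal_only = cfgi$fo)
      if (cfgi$fo && cfgi$uf) rr$l_fl else rr$l_bce + rr$l_fl
    }
    eps <- 1e-6
    for (idx in c(1, 5, 9)) {
      zp <- z; zp[idx] <- zp[idx] + eps
      zm <- z; zm[idx] <- zm[idx] - eps
      num <- (lossf(zp) - lossf(zm)) / (2 * eps)
      expect_lt(abs(r$grad[idx] - num), 1e-6)
    }
  }
})
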