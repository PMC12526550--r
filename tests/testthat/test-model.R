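# Build correctness, prediction contracts, parameter accounting. Uses the
# tiny preset throughout (CPU scale).

sgam_param_count <- function(C, ratio = 4, groups = 2) {
  cb <- max(1, C %/% ratio)
  # 1x1 squeeze/restore FCs + two 7x7 convs + BN affine
  (C * cb + cb) + (cb * C + C) + (49 * C * cb + cb) + (49 * cb * C + C) +
    2 * cb
}

cam_param_count <- function(C, ratio = 4) {
  cb <- max(1, C %/% ratio)
  (C * C + C) + (C * cb + cb) + 2 * cb + (cb * C + C)
}

test_that("sgam_position controls the number of SGAM instances", {
  base <- build_model(model_config(preset = "tiny", sgam_position = "none",
                                   cam_positions = character(0)), seed = 1)
  one <- build_model(model_config(preset = "tiny",
                                  sgam_position = "1_layer_P5",
                                  cam_positions = character(0)), seed = 1)
  three <- build_model(model_config(preset = "tiny",
                                    sgam_position = "3_layers_P345",
                                    cam_positions = character(0)), seed = 1)
  g <- function(m) cayolo:::module_graph(m)
  expect_equal(sum(grepl("^sgam_", g(base))), 0)
  expect_equal(sum(grepl("^sgam_", g(one))), 1)
  expect_true("sgam_P5" %in% g(one))
  expect_equal(sum(grepl("^sgam_", g(three))), 3)
  # ablation identity: no attention => module graph equals plain baseline
  expect_identical(g(base), g(build_model(model_config(
    preset = "tiny", sgam_position = "none",
    cam_positions = character(0)), seed = 2)))
  expect_error(model_config(sgam_position = "2_layers"), "valid")
})

test_that("attention parameter overhead matches analytic counts", {
  cfg0 <- model_config(preset = "tiny", sgam_position = "none",
                       cam_positions = character(0))
  base <- count_params(build_model(cfg0, seed = 1))
  w <- cfg0$widths
  one <- count_params(build_model(model_config(
    preset = "tiny", sgam_position = "1_layer_P5",
    cam_positions = character(0)), seed = 1))
  expect_equal(one - base, sgam_param_count(w[["p5"]]))
  cam3 <- count_params(build_model(model_config(
    preset = "tiny", sgam_position = "none",
    cam_positions = c("P3", "P4", "P5")), seed = 1))
  expect_equal(cam3 - base, cam_param_count(w[["p3"]]) +
                 cam_param_count(w[["p4"]]) + cam_param_count(w[["p5"]]))
  # identical configs give identical counts
  expect_equal(count_params(build_model(cfg0, seed = 5)),
               count_params(build_model(cfg0, seed = 9)))
})

test_that("512x512 forward yields strides 8/16/32 with correct extents", {
  m <- build_model(model_config(preset = "tiny", input_size = 512), seed = 3)
  img <- rand_fmap(512, 512, 3, seed = 3)
  fw <- cayolo:::forward_model(m, img)
  expect_equal(dim(fw$P3$cls$val)[1:2], c(64, 64))
  expect_equal(dim(fw$P4$cls$val)[1:2], c(32, 32))
  expect_equal(dim(fw$P5$cls$val)[1:2], c(16, 16))
  expect_equal(m$cfg$strides, c(8L, 16L, 32L))
  expect_equal(dim(fw$P3$cls$val)[3], m$cfg$n_classes)
  expect_equal(dim(fw$P3$reg$val)[3], 4 * m$cfg$nbins)
})

test_that("predict honours confidence, NMS and determinism contracts", {
  m <- build_model(model_config(preset = "tiny"), seed = 4)
  img <- array(runif(256 * 256 * 3), c(256, 256, 3))
  expect_equal(nrow(predict(m, img, conf_threshold = 1.0)), 0)
  d1 <- predict(m, img, conf_threshold = 0.01)
  d2 <- predict(m, img, conf_threshold = 0.01)
  expect_identical(d1, d2)
  if (nrow(d1) > 1) {
    for (k in unique(d1$class)) {
      dd <- d1[d1$class == k, , drop = FALSE]
      if (nrow(dd) > 1) {
        iou <- cayolo:::box_iou_matrix(
          as.matrix(dd[, c("x1", "y1", "x2", "y2")]),
          as.matrix(dd[, c("x1", "y1", "x2", "y2")]))
        diag(iou) <- 0
        expect_true(all(iou < 0.45))
      }
    }
  }
  expect_true(all(d1$confidence >= 0.01))
})

test_that("NMS collapses duplicate boxes", {
  boxes <- rbind(c(10, 10, 50, 50), c(10, 10, 50, 50), c(100, 100, 150, 150))
  keep <- cayolo:::nms_indices(boxes, c(0.9, 0.8, 0.7), 0.45)
  expect_equal(sort(keep), c(1, 3))
})

test_that("model gradients match finite differences end to end", {
  cfg <- model_config(preset = "tiny", input_size = 64)
  m <- build_model(cfg, seed = 6)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  gt <- matrix(c(10, 12, 40, 44, 30, 20, 58, 60), 2, 4, byrow = TRUE)
  cls <- c(0L, 1L)
  lossf <- function() {
    cayolo:::sample_loss(m, img, gt, cls, compute_grads = FALSE,
                         training = FALSE)$l_total
  }
  cayolo:::ag_zero_grad(m$params)
  cayolo:::sample_loss(m, img, gt, cls, compute_grads = TRUE,
                       grad_scale = 1, training = FALSE)
  set.seed(19)
  picks <- sample(length(m$params), 8)
  eps <- 1e-5
  for (pi in picks) {
    p <- m$params[[pi]]
    if (is.null(p$grad)) next
    idx <- sample(length(p$val), 1)
    orig <- p$val[idx]
    p$val[idx] <- orig + eps
    lp <- lossf()
    p$val[idx] <- orig - eps
    lm <- lossf()
    p$val[idx] <- orig
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(p$grad[idx] - num), 1e-4 + 1e-2 * abs(num))
  }
})

test_that("one optimiser step moves every attention parameter", {
  cfg <- model_config(preset = "tiny", input_size = 64,
                      sgam_position = "3_layers_P345")
  m <- build_model(cfg, seed = 7)
  before <- lapply(cayolo:::collect_params(m$attn), function(p) p$val)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  gt <- matrix(c(8, 8, 40, 40, 20, 30, 60, 62), 2, 4, byrow = TRUE)
  cayolo:::ag_zero_grad(m$params)
  cayolo:::sample_loss(m, img, gt, c(0L, 1L), compute_grads = TRUE,
                       grad_scale = 1, training = TRUE)
  st <- cayolo:::adam_state()
  cayolo:::adam_step(m$params, st, lr = 0.01)
  after <- lapply(cayolo:::collect_params(m$attn), function(p) p$val)
  moved <- mapply(function(a, b) max(abs(a - b)) > 0, before, after)
  expect_true(all(moved))
})

test_that("checkpoint round-trip preserves predictions", {
  m <- build_model(model_config(preset = "tiny"), seed = 8)
  img <- array(runif(256 * 256 * 3), c(256, 256, 3))
  d1 <- predict(m, img, conf_threshold = 0.01)
  pth <- tempfile(fileext = ".rds")
  save_model(m, pth)
  m2 <- load_model(pth)
  expect_identical(predict(m2, img, conf_threshold = 0.01), d1)
  unlink(pth)
})
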