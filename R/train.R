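# Training protocol: patient-level splitting, augmentation, random
# hyper-parameter search, Adam with early stopping on validation F1.

#' Patient-level dataset split
#'
#' Two-step split: patients are first divided into a training pool (80%)
#' and a held-out test set (20%); the pool is then divided into training
#' (70%) and validation (30%). All images of a patient land in exactly one
#' subset; patient counts are within 1 of the target fractions;
#' deterministic given the seed.
#'
#' @param manifest `data.frame` with columns `image` and `patient`.
#' @param fractions `c(pool_fraction, train_within_pool)`, default
#'   `c(0.8, 0.7)`.
#' @param seed Integer seed.
#' @return List with character vectors `train`, `val`, `test` of image ids.
#' @export
split_dataset <- function(manifest, fractions = c(0.8, 0.7), seed = 1L) {
  if (!all(c("image", "patient") %in% names(manifest))) {
    stop("`manifest` needs `image` and `patient` columns")
  }
  if (any(is.na(manifest$patient)) || any(manifest$patient == "")) {
    stop("every image must carry a patient id")
  }
  pats <- unique(manifest$patient)
  local_seed(seed, {
    pats <- sample(pats)
    n_pool <- round(fractions[1] * length(pats))
    pool <- pats[seq_len(n_pool)]
    test_p <- setdiff(pats, pool)
    n_train <- round(fractions[2] * length(pool))
    train_p <- pool[seq_len(n_train)]
    val_p <- setdiff(pool, train_p)
    list(train = manifest$image[manifest$patient %in% train_p],
         val = manifest$image[manifest$patient %in% val_p],
         test = manifest$image[manifest$patient %in% test_p])
  })
}

#' Augmentation parameters
#'
#' Defaults follow single-stage-detector convention: mosaic on (disabled
#' for the final `mosaic_close` epochs by [fit()]), MixUp and Copy-paste at
#' 0.1, horizontal flip 0.5, rotation up to 10 degrees, scale jitter 10%,
#' translation 10%, shear up to 2 degrees.
#'
#' @param hflip,mosaic,mixup,copy_paste Application probabilities.
#' @param rotate Max absolute rotation, degrees.
#' @param scale Max relative scale jitter.
#' @param translate Max translation, fraction of the canvas.
#' @param shear Max absolute shear, degrees.
#' @param mosaic_close Final epochs with mosaic disabled.
#' @param min_visibility Boxes kept only if at least this fraction of the
#'   transformed box area remains inside the canvas.
#' @return An `augment_params` list.
#' @export
augment_params <- function(hflip = 0.5, rotate = 10, scale = 0.1,
                           translate = 0.1, shear = 2, mosaic = 1.0,
                           mixup = 0.1, copy_paste = 0.1, mosaic_close = 10,
                           min_visibility = 0.25) {
  structure(as.list(environment()), class = "augment_params")
}

# Apply a 2x3 affine matrix (dst <- M %*% src about pixel coords) by inverse
# nearest-neighbour mapping; background filled with the dark base level.
affine_image <- function(img, M, fill = 0.04) {
  d <- dim(img)
  Mi <- solve(rbind(M, c(0, 0, 1)))
  xs <- matrix(seq_len(d[2]) - 0.5, d[1], d[2], byrow = TRUE)
  ys <- matrix(seq_len(d[1]) - 0.5, d[1], d[2])
  sx <- Mi[1, 1] * xs + Mi[1, 2] * ys + Mi[1, 3]
  sy <- Mi[2, 1] * xs + Mi[2, 2] * ys + Mi[2, 3]
  ci <- round(sx + 0.5)
  ri <- round(sy + 0.5)
  valid <- ri >= 1 & ri <= d[1] & ci >= 1 & ci <= d[2]
  out <- array(fill, d)
  idx_dst <- which(valid)
  idx_src <- ri[idx_dst] + (ci[idx_dst] - 1L) * d[1]
  hw <- d[1] * d[2]
  for (ch in seq_len(d[3])) {
    pl <- matrix(out[, , ch], d[1], d[2])
    pl[idx_dst] <- img[idx_src + (ch - 1L) * hw]
    out[, , ch] <- pl
  }
  out
}

transform_boxes <- function(boxes_px, M, S, min_visibility = 0.25) {
  if (nrow(boxes_px) == 0) return(boxes_px)
  keep <- logical(nrow(boxes_px))
  out <- boxes_px
  for (i in seq_len(nrow(boxes_px))) {
    b <- as.numeric(boxes_px[i, c("x1", "y1", "x2", "y2")])
    cs <- rbind(c(b[1], b[2]), c(b[3], b[2]), c(b[1], b[4]), c(b[3], b[4]))
    tx <- M[1, 1] * cs[, 1] + M[1, 2] * cs[, 2] + M[1, 3]
    ty <- M[2, 1] * cs[, 1] + M[2, 2] * cs[, 2] + M[2, 3]
    nb <- c(min(tx), min(ty), max(tx), max(ty))
    area_full <- (nb[3] - nb[1]) * (nb[4] - nb[2])
    cl <- c(max(0, nb[1]), max(0, nb[2]), min(S, nb[3]), min(S, nb[4]))
    w <- cl[3] - cl[1]
    h <- cl[4] - cl[2]
    if (w >= 2 && h >= 2 && area_full > 0 &&
        (w * h) / area_full >= min_visibility) {
      keep[i] <- TRUE
      out[i, c("x1", "y1", "x2", "y2")] <- cl
    }
  }
  out[keep, , drop = FALSE]
}

boxes_px_from_sample <- function(sample, S) {
  b <- sample$boxes
  if (all(c("x1", "y1", "x2", "y2") %in% names(b))) {
    b[, c("class", "x1", "y1", "x2", "y2")]
  } else {
    cbind(b["class"], as.data.frame(yolo_to_xyxy(b, S, S)))
  }
}

sample_from_px <- function(image, boxes_px, S) {
  yolo <- xyxy_to_yolo(as.matrix(boxes_px[, c("x1", "y1", "x2", "y2")]), S, S)
  list(image = image, boxes = cbind(boxes_px["class"], yolo,
                                    boxes_px[, c("x1", "y1", "x2", "y2")]),
       label = image_level_label(boxes_px))
}

mosaic4 <- function(samples, S) {
  half <- S %/% 2L
  img <- array(0.04, dim = c(S, S, 3))
  rows <- list()
  for (q in 1:4) {
    sm <- samples[[q]]
    sq <- resize_image(sm$image, half, half)
    qr <- if (q <= 2) 0L else half
    qc <- if (q %% 2 == 1) 0L else half
    img[qr + seq_len(half), qc + seq_len(half), ] <- sq
    b <- boxes_px_from_sample(sm, dim(sm$image)[1])
    if (nrow(b) > 0) {
      sc <- half / dim(sm$image)[1]
      b$x1 <- b$x1 * sc + qc; b$x2 <- b$x2 * sc + qc
      b$y1 <- b$y1 * sc + qr; b$y2 <- b$y2 * sc + qr
      rows[[length(rows) + 1L]] <- b
    }
  }
  boxes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class = integer(0), x1 = numeric(0), y1 = numeric(0),
               x2 = numeric(0), y2 = numeric(0))
  boxes <- boxes[(boxes$x2 - boxes$x1) >= 2 & (boxes$y2 - boxes$y1) >= 2, ,
                 drop = FALSE]
  sample_from_px(img, boxes, S)
}

#' Augment one training sample
#'
#' Applies (with the configured probabilities) mosaic composition from a
#' source pool, a random affine (rotation, scale, translation, mild shear),
#' horizontal flip, MixUp and Copy-paste. Output boxes are transformed with
#' the image, clipped to the canvas and dropped when mostly outside.
#' Deterministic given `seed`.
#'
#' @param sample List with `image` (`(S, S, 3)` array) and `boxes`
#'   (YOLO-style data frame).
#' @param params An [augment_params()].
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @param pool Optional list of further samples (mosaic/MixUp/Copy-paste
#'   sources); with fewer than 3 pool images mosaic falls back to the
#'   single-image pipeline.
#' @param use_mosaic Allows [fit()] to disable mosaic near the end.
#' @return An augmented sample of the same structure.
#' @export
augment <- function(sample, params = augment_params(), seed = NULL,
                    pool = NULL, use_mosaic = TRUE) {
  local_seed(seed, {
    S <- dim(sample$image)[1]
    if (use_mosaic && length(pool) >= 3 &&
        stats::runif(1) < params$mosaic) {
      picks <- sample(length(pool), 3)
      sample <- mosaic4(c(list(sample), pool[picks]), S)
    }
    img <- sample$image
    boxes <- boxes_px_from_sample(sample, S)
    ang <- stats::runif(1, -params$rotate, params$rotate) * pi / 180
    sc <- 1 + stats::runif(1, -params$scale, params$scale)
    shx <- tan(stats::runif(1, -params$shear, params$shear) * pi / 180)
    tx <- stats::runif(1, -params$translate, params$translate) * S
    ty <- stats::runif(1, -params$translate, params$translate) * S
    cx <- S / 2
    A <- sc * matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2) %*%
      matrix(c(1, 0, shx, 1), 2, 2)
    off <- c(cx + tx, cx + ty) - A %*% c(cx, cx)
    M <- cbind(A, off)
    if (abs(ang) + abs(sc - 1) + abs(shx) + abs(tx) + abs(ty) > 0) {
      img <- affine_image(img, M)
      boxes <- transform_boxes(boxes, M, S, params$min_visibility)
    }
    if (stats::runif(1) < params$hflip) {
      img <- img[, rev(seq_len(S)), , drop = FALSE]
      if (nrow(boxes) > 0) {
        x1 <- S - boxes$x2
        boxes$x2 <- S - boxes$x1
        boxes$x1 <- x1
      }
    }
    if (length(pool) >= 1 && stats::runif(1) < params$mixup) {
      other <- pool[[sample(length(pool), 1)]]
      oimg <- other$image
      if (dim(oimg)[1] != S) oimg <- resize_image(oimg, S, S)
      lam <- 0.5
      img <- lam * img + (1 - lam) * oimg
      ob <- boxes_px_from_sample(other, dim(other$image)[1])
      if (dim(other$image)[1] != S && nrow(ob) > 0) {
        scb <- S / dim(other$image)[1]
        ob[, c("x1", "y1", "x2", "y2")] <- ob[, c("x1", "y1", "x2", "y2")] *
          scb
      }
      boxes <- rbind(boxes, ob)
    }
    if (length(pool) >= 1 && stats::runif(1) < params$copy_paste) {
      donor <- pool[[sample(length(pool), 1)]]
      db <- boxes_px_from_sample(donor, dim(donor$image)[1])
      db <- db[db$class == 0L, , drop = FALSE]
      if (nrow(db) > 0 && dim(donor$image)[1] == S) {
        b <- as.numeric(db[sample(nrow(db), 1), c("x1", "y1", "x2", "y2")])
        b <- pmax(1, pmin(S, round(b)))
        w <- b[3] - b[1]
        h <- b[4] - b[2]
        if (w >= 4 && h >= 4) {
          nx <- sample(seq_len(S - w), 1)
          ny <- sample(seq_len(S - h), 1)
          crop <- donor$image[b[2]:(b[2] + h), b[1]:(b[1] + w), , drop = FALSE]
          reg <- img[ny:(ny + h), nx:(nx + w), , drop = FALSE]
          img[ny:(ny + h), nx:(nx + w), ] <- pmax(reg, crop)
          boxes <- rbind(boxes, data.frame(class = 0L, x1 = nx, y1 = ny,
                                           x2 = nx + w, y2 = ny + h))
        }
      }
    }
    sample_from_px(img, boxes, S)
  })
}

#' Random hyper-parameter search
#'
#' Samples `n_trials` distinct combinations from the grids in `space`
#' (fewer if the grid is smaller; the full grid is evaluated exhaustively
#' when `n_trials` covers it), evaluates the objective on each, and returns
#' the candidate with the highest validation F1; ties break towards the
#' earlier trial. A failing trial is logged (`f1 = NA`) and skipped.
#'
#' @param space Named list of value grids, e.g.
#'   `search_space()`.
#' @param objective Function taking a named list of hyper-parameter values
#'   and returning the validation F1 (numeric scalar) or a list with `f1`.
#' @param n_trials Number of sampled combinations (default 20).
#' @param seed Integer seed.
#' @return List with `best` (named list), `best_f1`, and `log`
#'   (data frame of trials).
#' @export
random_search <- function(space, objective, n_trials = 20L, seed = 1L) {
  grid <- expand.grid(space, stringsAsFactors = FALSE)
  if (nrow(grid) == 0) stop("empty search space")
  idx <- local_seed(seed, {
    if (n_trials >= nrow(grid)) seq_len(nrow(grid)) else
      sample(nrow(grid), n_trials)
  })
  log <- grid[idx, , drop = FALSE]
  log$trial <- seq_along(idx)
  log$f1 <- NA_real_
  for (i in seq_along(idx)) {
    cand <- as.list(grid[idx[i], , drop = FALSE])
    res <- try(objective(cand), silent = TRUE)
    if (inherits(res, "try-error")) next
    log$f1[i] <- if (is.list(res)) res$f1 else as.numeric(res)
  }
  if (all(is.na(log$f1))) stop("all search trials failed")
  best_i <- which(log$f1 == max(log$f1, na.rm = TRUE))[1]
  list(best = as.list(grid[idx[best_i], , drop = FALSE]),
       best_f1 = log$f1[best_i], log = log)
}

#' Default hyper-parameter search space
#'
#' The learning-rate / batch-size / weight-decay grids used for the
#' random search; the shipped default configuration (`lr = 0.001`,
#' `batch_size = 64`, `weight_decay = 5e-4`) is the selected optimum of
#' that search.
#'
#' @return Named list of grids.
#' @export
search_space <- function() {
  list(learning_rate = c(0.0001, 0.0005, 0.001, 0.005, 0.01),
       batch_size = c(16L, 32L, 64L),
       weight_decay = c(0.0, 0.0005, 1e-5, 1e-4, 1e-3))
}

# Clue-class validation F1 of a model over a list of samples.
validate_f1 <- function(model, samples, conf = 0.25, iou = 0.5) {
  S <- model$cfg$input_size
  det <- NULL
  gt <- NULL
  for (i in seq_along(samples)) {
    sm <- samples[[i]]
    img <- sm$image
    scale <- S / dim(img)[1]
    if (dim(img)[1] != S) img <- resize_image(img, S, S)
    d <- predict(model, img, conf_threshold = conf)
    if (nrow(d) > 0) {
      d$image <- i
      det <- rbind(det, d[, c("image", "class", "confidence",
                              "x1", "y1", "x2", "y2")])
    }
    g <- boxes_px_from_sample(sm, dim(sm$image)[1])
    if (nrow(g) > 0) {
      g[, c("x1", "y1", "x2", "y2")] <- g[, c("x1", "y1", "x2", "y2")] * scale
      g$image <- i
      gt <- rbind(gt, g)
    }
  }
  if (is.null(det)) det <- data.frame(image = integer(0), class = integer(0),
                                      confidence = numeric(0),
                                      x1 = numeric(0), y1 = numeric(0),
                                      x2 = numeric(0), y2 = numeric(0))
  if (is.null(gt)) gt <- data.frame(image = integer(0), class = integer(0),
                                    x1 = numeric(0), y1 = numeric(0),
                                    x2 = numeric(0), y2 = numeric(0))
  m <- object_metrics(det, gt, iou_threshold = iou, classes = 0L)
  list(f1 = if (is.na(m$f1)) 0 else m$f1, metrics = m)
}

#' Train a detector
#'
#' Adam optimisation of the composite objective with optional augmentation,
#' early stopping on validation F1 (`patience` epochs without improvement),
#' and best-checkpoint selection: the returned model carries the weights of
#' the epoch with the highest validation F1.
#'
#' @param model A `cayolo_model` (modified in place and returned).
#' @param data List with `train` and `val`: lists of samples
#'   (`image`, `boxes`).
#' @param epochs Maximum epochs.
#' @param lr,batch_size,weight_decay Optimiser settings (defaults are the
#'   search optimum: 0.001 / 64 / 5e-4; pass a smaller batch on CPU).
#' @param patience Early-stopping patience in epochs (default 50;
#'   `patience = 0` stops one epoch after the best).
#' @param schedule Learning-rate schedule: `"constant"` (default, the
#'   stated protocol) or `"cosine"` decay over `epochs`.
#' @param focal A [focal_params()] or `NULL` for the BCE-only ablation.
#' @param focal_only Replace BCE by focal loss instead of adding it.
#' @param use_augment Apply the augmentation pipeline to training samples.
#' @param aug An [augment_params()].
#' @param val_conf,val_iou Confidence / IoU-match thresholds for the
#'   validation F1.
#' @param seed Integer seed controlling shuffling and augmentation.
#' @param verbose Print per-epoch progress.
#' @return List with `model`, `history` (per-epoch data frame), `best_epoch`
#'   and `best_f1`.
#' @export
fit <- function(model, data, epochs = 500L, lr = 0.001, batch_size = 64L,
                weight_decay = 5e-4, patience = 50L,
                schedule = c("constant", "cosine"),
                focal = focal_params(), focal_only = FALSE,
                use_augment = TRUE, aug = augment_params(),
                val_conf = 0.25, val_iou = 0.5, seed = 1L, verbose = FALSE) {
  schedule <- match.arg(schedule)
  if (length(data$train) == 0 || length(data$val) == 0) {
    stop("`data` must provide non-empty train and val sample lists")
  }
  S <- model$cfg$input_size
  prep <- function(sm) {
    img <- sm$image
    scale <- S / dim(img)[1]
    if (dim(img)[1] != S) img <- resize_image(img, S, S)
    b <- boxes_px_from_sample(sm, dim(sm$image)[1])
    if (nrow(b) > 0 && scale != 1) {
      b[, c("x1", "y1", "x2", "y2")] <- b[, c("x1", "y1", "x2", "y2")] * scale
    }
    list(image = img, boxes = b)
  }
  train <- lapply(data$train, prep)
  val <- lapply(data$val, prep)
  state <- adam_state()
  history <- NULL
  best_f1 <- -Inf
  best_epoch <- 0L
  best_w <- NULL
  for (ep in seq_len(epochs)) {
    lr_ep <- if (schedule == "cosine") {
      lr * (1 + cos(pi * (ep - 1) / epochs)) / 2
    } else {
      lr
    }
    ord <- local_seed(derive_seed(seed, ep), sample(length(train)))
    tot <- 0
    nb <- 0L
    mosaic_on <- use_augment && (epochs - ep >= aug$mosaic_close)
    for (start in seq(1, length(ord), by = batch_size)) {
      bidx <- ord[start:min(start + batch_size - 1L, length(ord))]
      ag_zero_grad(model$params)
      for (bi in seq_along(bidx)) {
        sm <- train[[bidx[bi]]]
        if (use_augment) {
          sm <- augment(sm, aug,
                        seed = derive_seed(seed, ep * 100000 + bidx[bi]),
                        pool = train[-bidx[bi]], use_mosaic = mosaic_on)
          sm <- prep(sm)
        }
        lb <- sample_loss(model, sm$image,
                          as.matrix(sm$boxes[, c("x1", "y1", "x2", "y2")]),
                          sm$boxes$class, focal = focal,
                          focal_only = focal_only, compute_grads = TRUE,
                          grad_scale = 1 / length(bidx))
        if (!is.finite(lb$l_total)) {
          stop("non-finite training loss at epoch ", ep,
               "; lower the learning rate")
        }
        tot <- tot + lb$l_total
      }
      adam_step(model$params, state, lr = lr_ep,
                weight_decay = weight_decay)
      nb <- nb + length(bidx)
    }
    vl <- 0
    for (sm in val) {
      lb <- sample_loss(model, sm$image,
                        as.matrix(sm$boxes[, c("x1", "y1", "x2", "y2")]),
                        sm$boxes$class, focal = focal,
                        focal_only = focal_only, compute_grads = FALSE)
      vl <- vl + lb$l_total
    }
    vf <- validate_f1(model, val, conf = val_conf, iou = val_iou)
    history <- rbind(history, data.frame(
      epoch = ep, train_loss = tot / nb, val_loss = vl / length(val),
      val_f1 = vf$f1))
    if (vf$f1 > best_f1) {
      best_f1 <- vf$f1
      best_epoch <- ep
      best_w <- snapshot_weights(model)
    }
    if (verbose) {
      message(sprintf("epoch %d  train %.4f  val %.4f  F1 %.3f", ep,
                      tot / nb, vl / length(val), vf$f1))
    }
    if (ep - best_epoch > patience) break
  }
  if (!is.null(best_w)) set_model_weights(model, best_w)
  list(model = model, history = history, best_epoch = best_epoch,
       best_f1 = best_f1)
}
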