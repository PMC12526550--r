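# Compact single-stage detector: CSP-less backbone -> PAN-style neck ->
# decoupled anchor-free heads at strides 8/16/32, with CAM and SGAM blocks
# inserted at configured neck positions. Boxes are regressed as discrete
# per-side distance distributions (DFL bins) and decoded by expectation.

#' Detector configuration
#'
#' @param input_size Input image side in pixels (default 512; the `"tiny"`
#'   preset defaults to 256).
#' @param preset Width preset: `"tiny"` (CPU-scale) or `"s"`.
#' @param sgam_position Where SGAM is inserted: `"1_layer_P5"` (one block
#'   after the P5 neck output — the better-performing configuration),
#'   `"3_layers_P345"` (after each of P3, P4, P5), or `"none"`.
#' @param cam_positions Character subset of `c("P3", "P4", "P5")` naming
#'   neck outputs that receive a CAM block (default all three).
#' @param n_classes Number of object classes (default 2: clue, epithelial).
#' @param nbins DFL bins per box side (default 16).
#' @param sgam_ratio,sgam_groups,cam_ratio Attention hyper-parameters.
#' @param class_names Class names, clue class first.
#' @return A `model_config` list.
#' @export
model_config <- function(input_size = NULL,
                         preset = c("tiny", "s"),
                         sgam_position = c("1_layer_P5", "3_layers_P345",
                                           "none"),
                         cam_positions = c("P3", "P4", "P5"),
                         n_classes = 2L, nbins = 16L,
                         sgam_ratio = 4L, sgam_groups = 2L, cam_ratio = 4L,
                         class_names = c("clue", "epithelial")) {
  preset <- match.arg(preset)
  if (length(sgam_position) != 1 ||
      !sgam_position %in% c("1_layer_P5", "3_layers_P345", "none")) {
    if (length(sgam_position) > 1) {
      sgam_position <- match.arg(sgam_position)
    } else {
      stop("unknown `sgam_position` \"", sgam_position,
           "\"; valid: 1_layer_P5, 3_layers_P345, none")
    }
  }
  if (!all(cam_positions %in% c("P3", "P4", "P5"))) {
    stop("`cam_positions` must be a subset of P3, P4, P5")
  }
  if (is.null(input_size)) input_size <- if (preset == "tiny") 256L else 512L
  if (input_size %% 32 != 0) stop("`input_size` must be a multiple of 32")
  widths <- switch(preset,
                   tiny = c(stem = 8L, c1 = 16L, p3 = 24L, p4 = 32L, p5 = 48L),
                   s = c(stem = 24L, c1 = 48L, p3 = 64L, p4 = 96L, p5 = 128L))
  structure(list(input_size = as.integer(input_size), preset = preset,
                 widths = widths, sgam_position = sgam_position,
                 cam_positions = cam_positions,
                 n_classes = as.integer(n_classes), nbins = as.integer(nbins),
                 sgam_ratio = sgam_ratio, sgam_groups = sgam_groups,
                 cam_ratio = cam_ratio, class_names = class_names,
                 strides = c(8L, 16L, 32L)),
            class = "model_config")
}

#' Build a detector
#'
#' Assembles backbone, neck and three decoupled heads and inserts the
#' configured attention blocks. `"1_layer_P5"` yields exactly one SGAM
#' instance (after the P5 neck output), `"3_layers_P345"` three;
#' `"none"` with `cam_positions = character(0)` is the plain baseline.
#'
#' @param cfg A [model_config()].
#' @param seed Seed for weight initialisation.
#' @return A `cayolo_model` object.
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  local_seed(seed, {
    w <- cfg$widths
    k <- cfg$n_classes
    nb <- cfg$nbins
    layers <- list(
      stem = conv_params(3L, w["stem"], 3L),
      d1 = conv_params(w["stem"], w["c1"], 3L),
      d2 = conv_params(w["c1"], w["p3"], 3L),
      r3 = conv_params(w["p3"], w["p3"], 3L),
      d3 = conv_params(w["p3"], w["p4"], 3L),
      r4 = conv_params(w["p4"], w["p4"], 3L),
      d4 = conv_params(w["p4"], w["p5"], 3L),
      r5 = conv_params(w["p5"], w["p5"], 3L),
      t4 = conv_params(w["p5"] + w["p4"], w["p4"], 3L),
      n3 = conv_params(w["p4"] + w["p3"], w["p3"], 3L),
      dn3 = conv_params(w["p3"], w["p3"], 3L),
      n4 = conv_params(w["p3"] + w["p4"], w["p4"], 3L),
      dn4 = conv_params(w["p4"], w["p4"], 3L),
      n5 = conv_params(w["p4"] + w["p5"], w["p5"], 3L))
    node_width <- c(P3 = unname(w["p3"]), P4 = unname(w["p4"]),
                    P5 = unname(w["p5"]))
    attn <- list()
    for (pos in cfg$cam_positions) {
      attn[[paste0("cam_", pos)]] <- new_cam(node_width[[pos]],
                                             ratio = cfg$cam_ratio)
    }
    sgam_nodes <- switch(cfg$sgam_position,
                         "1_layer_P5" = "P5",
                         "3_layers_P345" = c("P3", "P4", "P5"),
                         "none" = character(0))
    for (pos in sgam_nodes) {
      attn[[paste0("sgam_", pos)]] <- new_sgam(node_width[[pos]],
                                               ratio = cfg$sgam_ratio,
                                               groups = cfg$sgam_groups)
    }
    heads <- list()
    for (pos in c("P3", "P4", "P5")) {
      cw <- node_width[[pos]]
      cls_out <- conv_params(cw, k, 1L)
      # rare-object prior on the classification bias to stabilise early
      # training (start predicting ~1% positives everywhere)
      cls_out$b$val[] <- -log(99)
      heads[[paste0("head_", pos)]] <- list(
        cls_stem = conv_params(cw, cw, 1L),
        cls_out = cls_out,
        reg_stem = conv_params(cw, cw, 1L),
        reg_out = conv_params(cw, 4L * nb, 1L))
    }
    model <- structure(list(cfg = cfg, layers = layers, attn = attn,
                            heads = heads, sgam_nodes = sgam_nodes),
                       class = "cayolo_model")
    model$params <- collect_params(list(layers, attn, heads))
    model
  })
}

# Names of all module instances in the graph (for build-correctness checks).
module_graph <- function(model) {
  c(names(model$layers), names(model$attn),
    unlist(lapply(names(model$heads), function(h) {
      paste0(h, "_", c("cls_stem", "cls_out", "reg_stem", "reg_out"))
    })))
}

#' Count trainable parameters
#'
#' @param model A `cayolo_model`.
#' @return Integer total of trainable scalar parameters.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, function(p) length(p$val), numeric(1)))
}

# Forward pass. Returns per-scale head output nodes plus the tape.
forward_model <- function(model, image, training = FALSE, tape = NULL) {
  if (is.null(tape)) tape <- ag_tape()
  L <- model$layers
  x <- ag_leaf(image)
  s <- ag_conv(tape, x, L$stem, stride = 2L, act = TRUE)
  s <- ag_conv(tape, s, L$d1, stride = 2L, act = TRUE)
  p3 <- ag_conv(tape, s, L$d2, stride = 2L, act = TRUE)
  p3 <- ag_conv(tape, p3, L$r3, act = TRUE)
  p4 <- ag_conv(tape, p3, L$d3, stride = 2L, act = TRUE)
  p4 <- ag_conv(tape, p4, L$r4, act = TRUE)
  p5 <- ag_conv(tape, p4, L$d4, stride = 2L, act = TRUE)
  p5 <- ag_conv(tape, p5, L$r5, act = TRUE)
  t4 <- ag_conv(tape, ag_concat_c(tape, ag_upsample2(tape, p5), p4), L$t4,
                act = TRUE)
  n3 <- ag_conv(tape, ag_concat_c(tape, ag_upsample2(tape, t4), p3), L$n3,
                act = TRUE)
  d3 <- ag_conv(tape, n3, L$dn3, stride = 2L, act = TRUE)
  n4 <- ag_conv(tape, ag_concat_c(tape, d3, t4), L$n4, act = TRUE)
  d4 <- ag_conv(tape, n4, L$dn4, stride = 2L, act = TRUE)
  n5 <- ag_conv(tape, ag_concat_c(tape, d4, p5), L$n5, act = TRUE)
  nodes <- list(P3 = n3, P4 = n4, P5 = n5)
  for (pos in c("P3", "P4", "P5")) {
    cam <- model$attn[[paste0("cam_", pos)]]
    if (!is.null(cam)) nodes[[pos]] <- forward_cam(tape, nodes[[pos]], cam)
    sg <- model$attn[[paste0("sgam_", pos)]]
    if (!is.null(sg)) {
      nodes[[pos]] <- forward_sgam(tape, nodes[[pos]], sg,
                                   training = training)
    }
  }
  out <- list(tape = tape)
  for (pos in c("P3", "P4", "P5")) {
    h <- model$heads[[paste0("head_", pos)]]
    f <- nodes[[pos]]
    cls <- ag_conv(tape, ag_conv(tape, f, h$cls_stem, act = TRUE), h$cls_out)
    reg <- ag_conv(tape, ag_conv(tape, f, h$reg_stem, act = TRUE), h$reg_out)
    out[[pos]] <- list(cls = cls, reg = reg)
  }
  out
}

# Decode one scale's head outputs into candidate detections.
decode_scale <- function(cls_val, reg_val, stride, nbins, conf_threshold) {
  d <- dim(cls_val)
  H <- d[1]; W <- d[2]; K <- d[3]
  probs <- 1 / (1 + exp(-cls_val))
  bins <- 0:(nbins - 1)
  # expectation over softmaxed bins for the 4 sides
  reg <- array(reg_val, dim = c(H, W, nbins, 4L))
  expd <- array(0, dim = c(H, W, 4L))
  for (sdx in 1:4) {
    z <- matrix(reg[, , , sdx], H * W, nbins)
    z <- exp(z - apply(z, 1, max))
    z <- z / rowSums(z)
    expd[, , sdx] <- matrix(z %*% bins, H, W)
  }
  rows <- NULL
  for (k in seq_len(K)) {
    sel <- which(probs[, , k] >= conf_threshold, arr.ind = TRUE)
    if (nrow(sel) == 0) next
    r <- sel[, 1]; cc <- sel[, 2]
    ax <- (cc - 0.5) * stride
    ay <- (r - 0.5) * stride
    l <- expd[, , 1][sel] * stride
    t <- expd[, , 2][sel] * stride
    rt <- expd[, , 3][sel] * stride
    bt <- expd[, , 4][sel] * stride
    rows <- rbind(rows, data.frame(
      class = k - 1L, confidence = probs[, , k][sel],
      x1 = ax - l, y1 = ay - t, x2 = ax + rt, y2 = ay + bt))
  }
  rows
}

#' Run the detector on an image
#'
#' Forward pass in evaluation mode, expectation decoding of the per-side
#' distance distributions, confidence filtering, and per-class greedy NMS.
#' Deterministic given fixed weights and input.
#'
#' @param object A `cayolo_model`.
#' @param image `(H, W, 3)` array in `[0, 1]`; resized (nearest neighbour)
#'   to the configured input size if needed.
#' @param conf_threshold Minimum confidence (default 0.25).
#' @param nms_iou NMS IoU threshold (default 0.45).
#' @param ... Unused.
#' @return `data.frame` with `class` (id, 0 = clue), `name`, `confidence`,
#'   `x1, y1, x2, y2` in pixels of the network input.
#' @export
predict.cayolo_model <- function(object, image, conf_threshold = 0.25,
                                 nms_iou = 0.45, ...) {
  S <- object$cfg$input_size
  if (!is.array(image) || length(dim(image)) != 3) {
    stop("`image` must be an (H, W, 3) array")
  }
  if (dim(image)[1] != S || dim(image)[2] != S) {
    image <- resize_image(image, S, S)
  }
  fw <- forward_model(object, image, training = FALSE)
  out <- NULL
  for (i in seq_along(object$cfg$strides)) {
    pos <- c("P3", "P4", "P5")[i]
    out <- rbind(out, decode_scale(fw[[pos]]$cls$val, fw[[pos]]$reg$val,
                                   object$cfg$strides[i], object$cfg$nbins,
                                   conf_threshold))
  }
  empty <- data.frame(class = integer(0), name = character(0),
                      confidence = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), x2 = numeric(0), y2 = numeric(0))
  if (is.null(out) || nrow(out) == 0) return(empty)
  out$x1 <- pmax(0, out$x1); out$y1 <- pmax(0, out$y1)
  out$x2 <- pmin(S, out$x2); out$y2 <- pmin(S, out$y2)
  out <- out[out$x2 > out$x1 & out$y2 > out$y1, , drop = FALSE]
  keep <- NULL
  for (k in unique(out$class)) {
    idx <- which(out$class == k)
    surv <- nms_indices(as.matrix(out[idx, c("x1", "y1", "x2", "y2")]),
                        out$confidence[idx], nms_iou)
    keep <- c(keep, idx[surv])
  }
  out <- out[sort(keep), , drop = FALSE]
  out$name <- object$cfg$class_names[out$class + 1L]
  rownames(out) <- NULL
  out[, c("class", "name", "confidence", "x1", "y1", "x2", "y2")]
}

#' Save / load model weights
#'
#' Checkpoints are RDS files holding the configuration and parameter
#' values (plus batch-norm running statistics).
#'
#' @param model A `cayolo_model`.
#' @param path File path.
#' @return `save_model` the path invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  vals <- lapply(model$params, function(p) p$val)
  bn <- lapply(model$attn, function(a) {
    if (!is.null(a$sa_bn)) list(rmean = a$sa_bn$rmean, rvar = a$sa_bn$rvar)
  })
  saveRDS(list(cfg = model$cfg, vals = vals, bn = bn), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$cfg)
  set_model_weights(model, ck$vals, ck$bn)
  model
}

# In-place weight replacement (parameter leaves are environments).
set_model_weights <- function(model, vals, bn = NULL) {
  stopifnot(length(vals) == length(model$params))
  for (i in seq_along(vals)) model$params[[i]]$val <- vals[[i]]
  if (!is.null(bn)) {
    for (nm in names(bn)) {
      if (!is.null(bn[[nm]]) && !is.null(model$attn[[nm]]$sa_bn)) {
        model$attn[[nm]]$sa_bn$rmean <- bn[[nm]]$rmean
        model$attn[[nm]]$sa_bn$rvar <- bn[[nm]]$rvar
      }
    }
  }
  invisible(model)
}

snapshot_weights <- function(model) lapply(model$params, function(p) p$val)
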