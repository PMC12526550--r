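# Anchor-free target assignment and the per-sample training loss.
#
# Assignment is static and deterministic: each ground-truth box is routed to
# the pyramid level whose size range matches its longer side, and claims the
# anchors whose centres lie inside the box within a small radius of its
# centre (centre sampling). Conflicts go to the smaller box; a box that
# claims nothing falls back to the closest anchor on its level.

assign_targets <- function(gt_xyxy, gt_class, input_size,
                           strides = c(8L, 16L, 32L), nbins = 16L,
                           centre_radius = 2.5) {
  n_gt <- nrow(gt_xyxy)
  lims <- c(0, input_size / 8, input_size / 4, Inf)
  out <- vector("list", length(strides))
  for (s in seq_along(strides)) {
    H <- input_size %/% strides[s]
    out[[s]] <- list(H = H, W = H, stride = strides[s],
                     owner = matrix(0L, H, H), pos = NULL)
  }
  if (n_gt > 0) {
    areas <- (gt_xyxy[, 3] - gt_xyxy[, 1]) * (gt_xyxy[, 4] - gt_xyxy[, 2])
    ord <- order(areas, decreasing = TRUE) # small boxes assigned last => win
    for (gi in ord) {
      g <- gt_xyxy[gi, ]
      size <- max(g[3] - g[1], g[4] - g[2])
      lv <- min(max(findInterval(size, lims), 1L), 3L)
      st <- strides[lv]
      H <- out[[lv]]$H
      gcx <- (g[1] + g[3]) / 2
      gcy <- (g[2] + g[4]) / 2
      cols <- which(abs((seq_len(H) - 0.5) * st - gcx) <= centre_radius * st)
      rows <- which(abs((seq_len(H) - 0.5) * st - gcy) <= centre_radius * st)
      hit <- FALSE
      for (cc in cols) {
        ax <- (cc - 0.5) * st
        if (ax <= g[1] || ax >= g[3]) next
        for (r in rows) {
          ay <- (r - 0.5) * st
          if (ay <= g[2] || ay >= g[4]) next
          out[[lv]]$owner[r, cc] <- gi
          hit <- TRUE
        }
      }
      if (!hit) {
        r <- min(max(ceiling(gcy / st), 1L), H)
        cc <- min(max(ceiling(gcx / st), 1L), H)
        out[[lv]]$owner[r, cc] <- gi
      }
    }
  }
  for (s in seq_along(strides)) {
    idx <- which(out[[s]]$owner > 0L, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    st <- strides[s]
    gi <- out[[s]]$owner[idx]
    ax <- (idx[, 2] - 0.5) * st
    ay <- (idx[, 1] - 0.5) * st
    maxd <- nbins - 1 - 1e-3
    pos <- data.frame(
      r = idx[, 1], c = idx[, 2], gt = gi, class = gt_class[gi],
      l = pmin(pmax((ax - gt_xyxy[gi, 1]) / st, 0), maxd),
      t = pmin(pmax((ay - gt_xyxy[gi, 2]) / st, 0), maxd),
      rr = pmin(pmax((gt_xyxy[gi, 3] - ax) / st, 0), maxd),
      b = pmin(pmax((gt_xyxy[gi, 4] - ay) / st, 0), maxd),
      x1 = gt_xyxy[gi, 1], y1 = gt_xyxy[gi, 2],
      x2 = gt_xyxy[gi, 3], y2 = gt_xyxy[gi, 4])
    out[[s]]$pos <- pos
  }
  out
}

# Forward pass + loss + (optionally) gradient seeding for one image.
# Returns the loss breakdown; when compute_grads = TRUE, backpropagates into
# the model parameters with gradients scaled by grad_scale (1 / batch size).
sample_loss <- function(model, image, gt_xyxy, gt_class,
                        focal = focal_params(), focal_only = FALSE,
                        compute_grads = FALSE, grad_scale = 1,
                        training = compute_grads) {
  cfg <- model$cfg
  fw <- forward_model(model, image, training = training)
  tg <- assign_targets(gt_xyxy, gt_class, cfg$input_size, cfg$strides,
                       cfg$nbins)
  K <- cfg$n_classes
  nb <- cfg$nbins
  scales <- c("P3", "P4", "P5")
  zs <- list()
  ys <- list()
  for (s in 1:3) {
    v <- fw[[scales[s]]]$cls$val
    H <- dim(v)[1]
    z <- matrix(v, H * H, K)
    y <- matrix(0, H * H, K)
    if (!is.null(tg[[s]]$pos)) {
      p <- tg[[s]]$pos
      y[cbind(p$r + (p$c - 1L) * H, p$class + 1L)] <- 1
    }
    zs[[s]] <- z
    ys[[s]] <- y
  }
  zall <- do.call(rbind, zs)
  yall <- do.call(rbind, ys)
  use_focal <- !is.null(focal)
  cl <- cls_loss_grad(zall, yall,
                      gamma = if (use_focal) focal$gamma else 1.5,
                      alpha = if (use_focal) focal$alpha else 1,
                      use_focal = use_focal, focal_only = focal_only)
  n_pos <- sum(vapply(tg, function(t) {
    if (is.null(t$pos)) 0L else nrow(t$pos)
  }, integer(1)))
  l_ciou <- 0
  l_dfl <- 0
  seeds <- list()
  if (compute_grads) {
    off <- 0L
    for (s in 1:3) {
      H <- tg[[s]]$H
      gz <- cl$grad[off + seq_len(H * H), , drop = FALSE]
      off <- off + H * H
      seeds[[length(seeds) + 1L]] <- list(
        node = fw[[scales[s]]]$cls,
        grad = array(gz * grad_scale, dim = c(H, H, K)))
    }
  }
  bins <- 0:(nb - 1)
  for (s in 1:3) {
    p <- tg[[s]]$pos
    if (is.null(p)) next
    st <- tg[[s]]$stride
    H <- tg[[s]]$H
    regv <- fw[[scales[s]]]$reg$val
    greg <- if (compute_grads) array(0, dim = dim(regv)) else NULL
    tmat <- as.matrix(p[, c("l", "t", "rr", "b")])
    for (i in seq_len(nrow(p))) {
      ax <- (p$c[i] - 0.5) * st
      ay <- (p$r[i] - 0.5) * st
      e <- numeric(4)
      qlist <- vector("list", 4)
      glist <- vector("list", 4)
      for (sdx in 1:4) {
        z <- regv[p$r[i], p$c[i], (sdx - 1L) * nb + seq_len(nb)]
        dg <- dfl_loss_grad(z, unname(tmat[i, sdx]))
        l_dfl <- l_dfl + unname(dg$loss)
        e[sdx] <- sum(dg$probs * bins)
        qlist[[sdx]] <- dg$probs
        glist[[sdx]] <- dg$grad
      }
      pred_box <- c(ax - e[1] * st, ay - e[2] * st,
                    ax + e[3] * st, ay + e[4] * st)
      # guard: expectation decode can give degenerate boxes early in training
      if (pred_box[3] - pred_box[1] < 1e-3) {
        pred_box[3] <- pred_box[1] + 1e-3
      }
      if (pred_box[4] - pred_box[2] < 1e-3) {
        pred_box[4] <- pred_box[2] + 1e-3
      }
      cg <- ciou_grad(pred_box, as.numeric(p[i, c("x1", "y1", "x2", "y2")]))
      l_ciou <- l_ciou + cg$loss
      if (compute_grads) {
        dLde <- c(-cg$grad[1] * st, -cg$grad[2] * st,
                  cg$grad[3] * st, cg$grad[4] * st)
        for (sdx in 1:4) {
          q <- qlist[[sdx]]
          gz <- glist[[sdx]] / (4 * n_pos) +
            dLde[sdx] * q * (bins - e[sdx]) / n_pos
          ch <- (sdx - 1L) * nb + seq_len(nb)
          greg[p$r[i], p$c[i], ch] <- greg[p$r[i], p$c[i], ch] + gz
        }
      }
    }
    if (compute_grads) {
      seeds[[length(seeds) + 1L]] <- list(node = fw[[scales[s]]]$reg,
                                          grad = greg * grad_scale)
    }
  }
  if (n_pos > 0) {
    l_ciou <- l_ciou / n_pos
    l_dfl <- l_dfl / (4 * n_pos)
  }
  if (compute_grads) ag_backward(fw$tape, seeds)
  l_cls <- if (focal_only && use_focal) cl$l_fl else cl$l_bce + cl$l_fl
  structure(list(l_bce = cl$l_bce, l_fl = cl$l_fl, l_ciou = l_ciou,
                 l_dfl = l_dfl, l_cls_enhanced = l_cls,
                 l_bbox = l_ciou + l_dfl, l_total = l_cls + l_ciou + l_dfl,
                 n_pos = n_pos),
            class = "loss_breakdown")
}
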