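# Detection objective: BCE + focal classification loss, CIoU + DFL box
# regression, composed as
#   l_total = l_cls_enhanced + l_bbox,
#   l_cls_enhanced = l_bce + l_fl,   l_bbox = l_ciou + l_dfl.
# Probabilities are clamped at eps = 1e-7 before logarithms.

LOSS_EPS <- 1e-7

clamp01 <- function(p, eps = LOSS_EPS) pmin(pmax(p, eps), 1 - eps)

#' Binary cross-entropy loss
#'
#' Elementwise `-y log(y_hat) - (1 - y) log(1 - y_hat)` with probabilities
#' clamped to `[eps, 1 - eps]` before the logarithms.
#'
#' @param y Ground-truth indicators in \{0, 1\} (vectorised).
#' @param y_hat Predicted probabilities in (0, 1).
#' @param eps Clamp applied before logs.
#' @return Nonnegative loss values, same length as the inputs.
#' @export
bce_loss <- function(y, y_hat, eps = LOSS_EPS) {
  if (!all(y %in% c(0, 1))) stop("`y` must contain only 0 and 1")
  p <- clamp01(y_hat, eps)
  -y * log(p) - (1 - y) * log(1 - p)
}

#' Focal loss
#'
#' `-alpha * (1 - pt)^gamma * log(pt)`, where `pt` is the probability the
#' model assigns to the true class (`pt = y_hat` for a positive, `1 - y_hat`
#' for a negative). With `gamma = 0` and `alpha = 1` this reduces to
#' [bce_loss()]. The focusing exponent `gamma` down-weights well-classified
#' examples; the default 1.5 is the value at which clue-cell sensitivity and
#' F1 peak in the sensitivity analysis this package follows.
#'
#' @param pt Probability of the true class, in (0, 1]; vectorised.
#' @param gamma Focusing exponent, >= 0.
#' @param alpha Class-balance weight(s), positive; recycled against `pt`.
#' @param eps Clamp applied before the logarithm.
#' @return Nonnegative loss values.
#' @export
focal_loss <- function(pt, gamma = 1.5, alpha = 1, eps = LOSS_EPS) {
  if (gamma < 0) stop("`gamma` must be nonnegative")
  if (any(alpha <= 0)) stop("`alpha` entries must be positive")
  p <- pmin(pmax(pt, eps), 1)
  -alpha * (1 - p)^gamma * log(p)
}

#' Inverse-frequency class weights
#'
#' Per-class focal-loss weights proportional to the inverse instance
#' frequency in the training set, normalised to sum to the number of classes
#' so that uniform class frequencies give unit weights (and `gamma = 0`
#' reduces the objective to unweighted BCE).
#'
#' @param class_counts Positive instance counts, one per class.
#' @return Weight vector of the same length, summing to the class count.
#' @examples
#' alpha_from_frequency(c(90, 10)) # c(0.2, 1.8): the rare class weighs more
#' @export
alpha_from_frequency <- function(class_counts) {
  if (any(class_counts <= 0)) {
    stop("all class counts must be positive; add smoothing (e.g. +1) to ",
         "handle classes absent from the training set")
  }
  a <- 1 / class_counts
  a * length(a) / sum(a)
}

#' Complete-IoU loss
#'
#' `1 - CIoU` where `CIoU = IoU - rho^2 / c^2 - alpha * v`: overlap, squared
#' centre distance over the squared enclosing-box diagonal, and an
#' aspect-ratio consistency penalty. Zero for identical boxes; bounded by
#' `[0, 2]`.
#'
#' @param pred,gt Boxes `c(x1, y1, x2, y2)` with positive width and height.
#' @return Nonnegative scalar loss.
#' @export
ciou_loss <- function(pred, gt) {
  ciou_terms(pred, gt)$loss
}

ciou_terms <- function(b, g) {
  w <- b[3] - b[1]; h <- b[4] - b[2]
  wg <- g[3] - g[1]; hg <- g[4] - g[2]
  if (w <= 0 || h <= 0 || wg <= 0 || hg <= 0) {
    stop("boxes must have positive width and height")
  }
  xi1 <- max(b[1], g[1]); yi1 <- max(b[2], g[2])
  xi2 <- min(b[3], g[3]); yi2 <- min(b[4], g[4])
  iw <- max(0, xi2 - xi1); ih <- max(0, yi2 - yi1)
  inter <- iw * ih
  union <- w * h + wg * hg - inter
  iou <- inter / union
  rho2 <- ((b[1] + b[3]) / 2 - (g[1] + g[3]) / 2)^2 +
    ((b[2] + b[4]) / 2 - (g[2] + g[4]) / 2)^2
  cw <- max(b[3], g[3]) - min(b[1], g[1])
  ch <- max(b[4], g[4]) - min(b[2], g[2])
  c2 <- cw^2 + ch^2
  dd <- atan(wg / hg) - atan(w / h)
  v <- 4 / pi^2 * dd^2
  av <- if (iou < 1) v / (1 - iou + v) else 0
  list(loss = 1 - (iou - rho2 / c2 - av * v),
       iou = iou, rho2 = rho2, c2 = c2, v = v, alpha = av,
       inter = inter, union = union, iw = iw, ih = ih,
       w = w, h = h, wg = wg, hg = hg, cw = cw, ch = ch, dd = dd)
}

# Analytic gradient of ciou_loss w.r.t. the predicted box, including the
# dependence of the aspect-ratio weight alpha = v / (1 - IoU + v) on the
# box. Verified against finite differences in the test suite.
ciou_grad <- function(b, g) {
  t <- ciou_terms(b, g)
  dI <- c(
    if (t$iw > 0 && t$ih > 0 && b[1] > g[1]) -t$ih else 0,
    if (t$iw > 0 && t$ih > 0 && b[2] > g[2]) -t$iw else 0,
    if (t$iw > 0 && t$ih > 0 && b[3] < g[3]) t$ih else 0,
    if (t$iw > 0 && t$ih > 0 && b[4] < g[4]) t$iw else 0)
  dU <- c(-t$h, -t$w, t$h, t$w) - dI
  dIoU <- (dI * t$union - t$inter * dU) / t$union^2
  bcx <- (b[1] + b[3]) / 2; bcy <- (b[2] + b[4]) / 2
  gcx <- (g[1] + g[3]) / 2; gcy <- (g[2] + g[4]) / 2
  drho2 <- c(bcx - gcx, bcy - gcy, bcx - gcx, bcy - gcy)
  dc2 <- c(if (b[1] < g[1]) -2 * t$cw else 0,
           if (b[2] < g[2]) -2 * t$ch else 0,
           if (b[3] > g[3]) 2 * t$cw else 0,
           if (b[4] > g[4]) 2 * t$ch else 0)
  dR <- (drho2 * t$c2 - t$rho2 * dc2) / t$c2^2
  dv_dw <- -(8 / pi^2) * t$dd * t$h / (t$w^2 + t$h^2)
  dv_dh <- (8 / pi^2) * t$dd * t$w / (t$w^2 + t$h^2)
  dv <- c(-dv_dw, -dv_dh, dv_dw, dv_dh)
  # penalty P = alpha * v = v^2 / D with D = 1 - IoU + v (quotient rule)
  D <- 1 - t$iou + t$v
  dP <- if (t$iou < 1) {
    (2 * t$v * dv * D - t$v^2 * (-dIoU + dv)) / D^2
  } else {
    rep(0, 4)
  }
  list(loss = t$loss, grad = -dIoU + dR + dP)
}

#' Distribution focal loss
#'
#' Box-side regression as classification over discrete bins: the loss is the
#' cross-entropy against the two bins bracketing the continuous target,
#' weighted by linear interpolation. Zero (up to the clamp) when the
#' distribution is one-hot at an integer target.
#'
#' @param dist Probability vector over bins `0 .. n-1` (sums to 1).
#' @param target Continuous coordinate within `[0, n-1]`.
#' @param eps Clamp applied before logs.
#' @return Nonnegative scalar.
#' @export
dfl_loss <- function(dist, target, eps = LOSS_EPS) {
  n <- length(dist)
  if (abs(sum(dist) - 1) > 1e-6) stop("`dist` must sum to 1")
  if (target < 0 || target > n - 1) {
    stop("`target` must lie within the bin range [0, n-1]")
  }
  lo <- floor(target)
  if (lo == n - 1) lo <- n - 2 # target exactly on the last bin
  wl <- lo + 1 - target
  wr <- target - lo
  -wl * log(max(dist[lo + 1], eps)) - wr * log(max(dist[lo + 2], eps))
}

#' Focal-loss hyper-parameters
#'
#' @param gamma Focusing exponent (default 1.5).
#' @param alpha Per-class weight vector (e.g. from [alpha_from_frequency()])
#'   or a scalar.
#' @return A `focal_params` list.
#' @export
focal_params <- function(gamma = 1.5, alpha = 1) {
  if (gamma < 0) stop("`gamma` must be nonnegative")
  structure(list(gamma = gamma, alpha = alpha), class = "focal_params")
}

#' Composite detection loss
#'
#' Combines the classification terms (BCE over every anchor-class entry plus
#' focal loss, unless disabled) with the box terms (CIoU plus DFL over the
#' assigned positives). Classification terms are averaged over all
#' anchor-class entries; box terms over positives.
#'
#' @param pred List with `cls` (anchors x classes matrix of predicted
#'   probabilities), and for positives `box` (n x 4 decoded boxes) and
#'   `dist` (n x 4 x bins array of per-side bin distributions). `box`/`dist`
#'   may be omitted when there are no assigned positives.
#' @param target List with `cls` (anchors x classes 0/1 matrix), `box`
#'   (n x 4), `dfl` (n x 4 continuous bin coordinates).
#' @param focal A [focal_params()] object, or `NULL` to drop the focal term
#'   (the BCE-only ablation).
#' @param focal_only If `TRUE` the focal term replaces BCE instead of being
#'   added to it (ablation switch).
#' @return A `loss_breakdown` list with components `l_bce`, `l_fl`,
#'   `l_ciou`, `l_dfl`, `l_cls_enhanced`, `l_bbox`, `l_total`.
#' @export
total_loss <- function(pred, target, focal = focal_params(),
                       focal_only = FALSE) {
  y <- target$cls
  p <- pred$cls
  if (!all(dim(y) == dim(p))) stop("cls prediction/target shape mismatch")
  l_bce <- mean(bce_loss(as.numeric(y), as.numeric(p)))
  l_fl <- 0
  if (!is.null(focal)) {
    alpha <- focal$alpha
    if (length(alpha) > 1 && length(alpha) != ncol(y)) {
      stop("`alpha` length must equal the number of classes")
    }
    amat <- matrix(alpha, nrow(y), ncol(y), byrow = TRUE)
    at <- ifelse(y == 1, amat, 1) # static per-class weight on positives
    pt <- ifelse(y == 1, p, 1 - p)
    l_fl <- mean(focal_loss(as.numeric(pt), gamma = focal$gamma,
                            alpha = as.numeric(at)))
  }
  n_pos <- if (is.null(target$box)) 0L else nrow(target$box)
  l_ciou <- 0
  l_dfl <- 0
  if (n_pos > 0) {
    lc <- numeric(n_pos)
    for (i in seq_len(n_pos)) {
      lc[i] <- ciou_loss(pred$box[i, ], target$box[i, ])
    }
    l_ciou <- mean(lc)
    ld <- numeric(n_pos * 4)
    k <- 0L
    for (i in seq_len(n_pos)) {
      for (s in 1:4) {
        k <- k + 1L
        ld[k] <- dfl_loss(pred$dist[i, s, ], target$dfl[i, s])
      }
    }
    l_dfl <- mean(ld)
  }
  l_cls <- if (focal_only && !is.null(focal)) l_fl else l_bce + l_fl
  structure(list(l_bce = l_bce, l_fl = l_fl, l_ciou = l_ciou, l_dfl = l_dfl,
                 l_cls_enhanced = l_cls, l_bbox = l_ciou + l_dfl,
                 l_total = l_cls + l_ciou + l_dfl),
            class = "loss_breakdown")
}

## ---- training-time loss with analytic gradients ---------------------------

# Classification loss on logits with gradient. z, y: anchors x classes.
# Returns mean losses and d(loss)/dz for the configured composition.
cls_loss_grad <- function(z, y, gamma = 1.5, alpha = 1, use_focal = TRUE,
                          focal_only = FALSE, eps = LOSS_EPS) {
  p <- 1 / (1 + exp(-z))
  n <- length(z)
  pc <- clamp01(p, eps)
  l_bce <- mean(-y * log(pc) - (1 - y) * log(1 - pc))
  g_bce <- (p - y) / n
  l_fl <- 0
  g_fl <- 0
  if (use_focal) {
    amat <- matrix(alpha, nrow(y), ncol(y), byrow = TRUE)
    at <- ifelse(y == 1, amat, 1)
    pt <- ifelse(y == 1, p, 1 - p)
    ptc <- pmin(pmax(pt, eps), 1 - 1e-12)
    omp <- 1 - ptc
    l_fl <- mean(at * -(omp^gamma) * log(ptc))
    # dL/dpt, then chain through pt = p or 1-p and p = sigmoid(z)
    dldpt <- at * (gamma * omp^(gamma - 1) * log(ptc) - omp^gamma / ptc)
    dptdz <- ifelse(y == 1, 1, -1) * p * (1 - p)
    g_fl <- dldpt * dptdz / n
  }
  if (focal_only && use_focal) {
    list(l_bce = l_bce, l_fl = l_fl, grad = g_fl)
  } else {
    list(l_bce = l_bce, l_fl = l_fl, grad = g_bce + g_fl)
  }
}

# DFL on logits (pre-softmax) for one side; returns loss and gradient.
dfl_loss_grad <- function(logits, target) {
  n <- length(logits)
  q <- exp(logits - max(logits))
  q <- q / sum(q)
  lo <- floor(target)
  if (lo == n - 1) lo <- n - 2
  wl <- lo + 1 - target
  wr <- target - lo
  tdist <- numeric(n)
  tdist[lo + 1] <- wl
  tdist[lo + 2] <- wr
  loss <- -wl * log(max(q[lo + 1], LOSS_EPS)) -
    wr * log(max(q[lo + 2], LOSS_EPS))
  list(loss = loss, grad = q - tdist, probs = q)
}
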