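# Feature-enhancement blocks: the context-aware module (CAM) and the shuffle
# global attention mechanism (SGAM).
#
# Package convention: a feature map is a numeric array of dim c(H, W, C)
# ("image layout", channels on the third axis). All blocks preserve shape.

## ---- channel shuffle -------------------------------------------------------

# Permutation vector: output channel k (0-based k = i*(C/g)+j) takes input
# channel j*g+i, i.e. the reshape-to-(g, C/g), transpose, flatten rule.
shuffle_perm <- function(channels, groups) {
  if (groups < 1L || groups != round(groups)) {
    stop("`groups` must be a positive integer")
  }
  if (channels %% groups != 0L) {
    stop(sprintf("`groups` (%d) must divide the channel count (%d)",
                 groups, channels))
  }
  k <- 0:(channels - 1L)
  i <- k %/% (channels %/% groups)
  j <- k %% (channels %/% groups)
  as.integer(j * groups + i + 1L)
}

#' Channel shuffle
#'
#' Deterministic channel permutation used at the end of SGAM: channels are
#' reshaped to `groups` groups, transposed, and flattened, so information is
#' mixed across groups. The operation is a bijection on channel indices;
#' applying it again with `C / groups` groups restores the original order.
#'
#' @param x Numeric array of dim `c(H, W, C)`.
#' @param groups Positive integer dividing `C`.
#' @return Array of the same shape with channels permuted.
#' @examples
#' x <- array(rep(0:3, each = 4), dim = c(2, 2, 4))
#' y <- channel_shuffle(x, 2) # channel order 0,2,1,3
#' @export
channel_shuffle <- function(x, groups) {
  d <- dim(x)
  if (length(d) != 3) stop("`x` must be an (H, W, C) array")
  x[, , shuffle_perm(d[3], groups), drop = FALSE]
}

## ---- internal block constructors ------------------------------------------

bn_layer <- function(channels, momentum = 0.1) {
  e <- new.env(parent = emptyenv())
  e$gamma <- ag_leaf(rep(1, channels))
  e$beta <- ag_leaf(rep(0, channels))
  e$rmean <- rep(0, channels)
  e$rvar <- rep(1, channels)
  e$momentum <- momentum
  e
}

bottleneck_width <- function(channels, ratio) max(1L, channels %/% ratio)

new_sgam <- function(channels, ratio = 4L, groups = 2L) {
  shuffle_perm(channels, groups) # validates groups
  cb <- bottleneck_width(channels, ratio)
  list(type = "sgam", channels = channels, ratio = ratio, groups = groups,
       ca_w1 = conv_params(channels, cb, 1L),
       ca_w2 = conv_params(cb, channels, 1L),
       sa_f1 = conv_params(channels, cb, 7L),
       sa_bn = bn_layer(cb),
       sa_f2 = conv_params(cb, channels, 7L))
}

new_cam <- function(channels, ratio = 4L) {
  cb <- bottleneck_width(channels, ratio)
  list(type = "cam", channels = channels, ratio = ratio,
       ctx = conv_params(channels, channels, 1L),
       conv_a = conv_params(channels, cb, 1L),
       ln_gamma = ag_leaf(rep(1, cb)),
       ln_beta = ag_leaf(rep(0, cb)),
       conv_b = conv_params(cb, channels, 1L))
}

forward_sgam_ca <- function(tape, x, blk) {
  a1 <- ag_relu(tape, ag_conv(tape, x, blk$ca_w1))
  ac <- ag_sigmoid(tape, ag_conv(tape, a1, blk$ca_w2))
  list(weights = ac, output = ag_mul(tape, x, ac))
}

forward_sgam_sa <- function(tape, xca, blk, training = FALSE) {
  h <- ag_relu(tape, ag_conv(tape, xca, blk$sa_f1))
  h <- ag_batchnorm_c(tape, h, blk$sa_bn, training = training)
  as_map <- ag_sigmoid(tape, ag_conv(tape, h, blk$sa_f2))
  perm <- shuffle_perm(blk$channels, blk$groups)
  shuffled <- ag_permute_c(tape, as_map, perm)
  list(weights = as_map, output = ag_mul(tape, xca, shuffled))
}

forward_sgam <- function(tape, x, blk, training = FALSE) {
  ca <- forward_sgam_ca(tape, x, blk)
  forward_sgam_sa(tape, ca$output, blk, training = training)$output
}

forward_cam <- function(tape, x, blk) {
  s <- ag_conv(tape, x, blk$ctx)
  p <- ag_softmax_spatial(tape, s)
  xw <- ag_mul(tape, x, p)
  h <- ag_conv(tape, xw, blk$conv_a)
  h <- ag_layernorm_c(tape, h, blk$ln_gamma, blk$ln_beta)
  h <- ag_conv(tape, h, blk$conv_b)
  gate <- ag_sigmoid(tape, h)
  ag_add(tape, x, ag_mul(tape, xw, gate))
}

## ---- exported functional API ----------------------------------------------

# Wrap plain numeric SGAM/CAM parameter lists into autograd leaves.
leaves_from_sgam_params <- function(channel, spatial, channels) {
  cb_c <- ncol(channel$w1)
  cb_s <- dim(spatial$f1)[4]
  bn <- bn_layer(cb_s)
  if (!is.null(spatial$bn)) {
    bn$rmean <- spatial$bn$mean
    bn$rvar <- spatial$bn$var
    bn$gamma <- ag_leaf(spatial$bn$gamma)
    bn$beta <- ag_leaf(spatial$bn$beta)
  }
  list(type = "sgam", channels = channels, groups = spatial$groups,
       ca_w1 = list(w = ag_leaf(channel$w1), b = ag_leaf(channel$b1), k = 1L,
                    cin = channels, cout = cb_c),
       ca_w2 = list(w = ag_leaf(channel$w2), b = ag_leaf(channel$b2), k = 1L,
                    cin = cb_c, cout = channels),
       sa_f1 = list(w = ag_leaf(matrix(spatial$f1, 7 * 7 * channels, cb_s)),
                    b = ag_leaf(spatial$b1), k = 7L,
                    cin = channels, cout = cb_s),
       sa_bn = bn,
       sa_f2 = list(w = ag_leaf(matrix(spatial$f2, 7 * 7 * cb_s, channels)),
                    b = ag_leaf(spatial$b2), k = 7L,
                    cin = cb_s, cout = channels))
}

check_featuremap <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3) {
    stop("feature maps are numeric arrays of dim c(H, W, C)")
  }
  invisible(dim(x))
}

#' SGAM channel attention
#'
#' Per-position channel gate: two fully connected transforms act on the
#' channel vector at every spatial location (a squeeze to `C / ratio` with
#' ReLU, then a restore to `C`), followed by a sigmoid. The input map is
#' multiplied elementwise by the resulting weights, which lie strictly in
#' (0, 1).
#'
#' @param x Feature map, array of dim `c(H, W, C)`.
#' @param params List with `w1` (`C x Cb` matrix), `b1` (length `Cb`),
#'   `w2` (`Cb x C`), `b2` (length `C`), e.g. from [sgam_params()].
#' @return List with `weights` (the attention map `Ac`) and `output`
#'   (`x * Ac`), both of the input shape.
#' @export
sgam_channel_attention <- function(x, params) {
  d <- check_featuremap(x)
  if (nrow(params$w1) != d[3] || ncol(params$w2) != d[3]) {
    stop("channel-attention parameter shapes do not match C")
  }
  blk <- list(
    ca_w1 = list(w = ag_leaf(params$w1), b = ag_leaf(params$b1), k = 1L),
    ca_w2 = list(w = ag_leaf(params$w2), b = ag_leaf(params$b2), k = 1L))
  r <- forward_sgam_ca(NULL, ag_leaf(x), blk)
  list(weights = r$weights$val, output = r$output$val)
}

#' SGAM spatial attention
#'
#' Two 7x7 convolutions (squeeze then restore) with ReLU and batch
#' normalisation between them and a sigmoid at the end produce a spatial
#' attention map, which is channel-shuffled with `params$groups` groups and
#' multiplied elementwise into the input. The 7x7 kernel is a fixed design
#' element (wide receptive field for cell contours) and is validated.
#'
#' @param xca Feature map, array of dim `c(H, W, C)` (typically the channel
#'   attention output).
#' @param params List with `f1` (array `c(7, 7, C, Cb)`), `b1`, `bn`
#'   (list `mean`, `var`, `gamma`, `beta`, per intermediate channel),
#'   `f2` (array `c(7, 7, Cb, C)`), `b2`, and `groups`.
#' @return List with `weights` (the unshuffled map `As`) and `output`.
#' @export
sgam_spatial_attention <- function(xca, params) {
  d <- check_featuremap(xca)
  if (!all(dim(params$f1)[1:2] == 7) || !all(dim(params$f2)[1:2] == 7)) {
    stop("spatial attention requires 7x7 convolution kernels")
  }
  if (dim(params$f1)[3] != d[3] || dim(params$f2)[4] != d[3]) {
    stop("spatial-attention parameter shapes do not match C")
  }
  blk <- leaves_from_sgam_params(
    channel = list(w1 = matrix(0, d[3], 1), b1 = 0,
                   w2 = matrix(0, 1, d[3]), b2 = numeric(d[3])),
    spatial = params, channels = d[3])
  r <- forward_sgam_sa(NULL, ag_leaf(xca), blk, training = FALSE)
  list(weights = r$weights$val, output = r$output$val)
}

#' SGAM forward pass
#'
#' Composition of [sgam_channel_attention()] followed by
#' [sgam_spatial_attention()] (channel-then-spatial order), the full shuffle
#' global attention mechanism.
#'
#' @param x Feature map, array of dim `c(H, W, C)`.
#' @param channel Channel-attention parameters (see
#'   [sgam_channel_attention()]).
#' @param spatial Spatial-attention parameters (see
#'   [sgam_spatial_attention()]).
#' @return Feature map of the input shape.
#' @export
sgam_forward <- function(x, channel, spatial) {
  ca <- sgam_channel_attention(x, channel)
  sgam_spatial_attention(ca$output, spatial)$output
}

#' CAM forward pass
#'
#' The context-aware module: a 1x1 convolution scores spatial context, a
#' softmax over the spatial positions of each channel turns the scores into a
#' probability distribution, and the input is reweighted by it. The weighted
#' map is then transformed (1x1 conv, layer normalisation over channels, 1x1
#' conv, sigmoid) and gated back onto itself; the result is added to the
#' original input (residual structure).
#'
#' @param x Feature map, array of dim `c(H, W, C)`.
#' @param params List with `ctx_w` (`C x C`), `ctx_b`, `a_w` (`C x Cb`),
#'   `a_b`, `ln_gamma`, `ln_beta` (length `Cb`), `b_w` (`Cb x C`), `b_b`,
#'   e.g. from [cam_params()].
#' @return Feature map of the input shape.
#' @export
cam_forward <- function(x, params) {
  d <- check_featuremap(x)
  if (nrow(params$ctx_w) != d[3]) stop("CAM parameter shapes do not match C")
  blk <- list(
    ctx = list(w = ag_leaf(params$ctx_w), b = ag_leaf(params$ctx_b), k = 1L),
    conv_a = list(w = ag_leaf(params$a_w), b = ag_leaf(params$a_b), k = 1L),
    ln_gamma = ag_leaf(params$ln_gamma),
    ln_beta = ag_leaf(params$ln_beta),
    conv_b = list(w = ag_leaf(params$b_w), b = ag_leaf(params$b_b), k = 1L))
  forward_cam(NULL, ag_leaf(x), blk)$val
}

#' Random SGAM parameters
#'
#' Draws a parameter set for [sgam_forward()] at a given width. The reduction
#' ratio defaults to 4 (bottleneck `max(1, floor(C / ratio))`) and the
#' shuffle group count to 2; both are validated against `channels`.
#'
#' @param channels Channel count `C` of the maps the block will see.
#' @param ratio Positive integer reduction ratio.
#' @param groups Shuffle group count; must divide `channels`.
#' @return List with `channel` and `spatial` parameter lists.
#' @export
sgam_params <- function(channels, ratio = 4, groups = 2) {
  shuffle_perm(channels, groups)
  cb <- bottleneck_width(channels, ratio)
  rn <- function(...) array(stats::rnorm(prod(...), sd = 0.1), dim = c(...))
  list(
    channel = list(w1 = rn(channels, cb), b1 = numeric(cb),
                   w2 = rn(cb, channels), b2 = numeric(channels)),
    spatial = list(f1 = rn(7, 7, channels, cb), b1 = numeric(cb),
                   bn = list(mean = rep(0, cb), var = rep(1, cb),
                             gamma = rep(1, cb), beta = rep(0, cb)),
                   f2 = rn(7, 7, cb, channels), b2 = numeric(channels),
                   groups = groups))
}

#' Random CAM parameters
#'
#' @param channels Channel count `C`.
#' @param ratio Bottleneck ratio of the transform branch (default 4).
#' @return Parameter list for [cam_forward()].
#' @export
cam_params <- function(channels, ratio = 4) {
  cb <- bottleneck_width(channels, ratio)
  rn <- function(...) array(stats::rnorm(prod(...), sd = 0.1), dim = c(...))
  list(ctx_w = rn(channels, channels), ctx_b = numeric(channels),
       a_w = rn(channels, cb), a_b = numeric(cb),
       ln_gamma = rep(1, cb), ln_beta = rep(0, cb),
       b_w = rn(cb, channels), b_b = numeric(channels))
}
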