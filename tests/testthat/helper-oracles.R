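# Independent straight-line oracles: explicit-loop recomputations of every
# forward pass, written directly from the math with no shared code paths
# with the package internals.

oracle_conv2d <- function(x, warr, b, stride = 1, pad = (dim(warr)[1] - 1) / 2) {
  d <- dim(x)
  k <- dim(warr)[1]
  cout <- dim(warr)[4]
  Ho <- (d[1] + 2 * pad - k) %/% stride + 1
  Wo <- (d[2] + 2 * pad - k) %/% stride + 1
  out <- array(0, c(Ho, Wo, cout))
  for (oc in seq_len(cout)) {
    for (oh in seq_len(Ho)) {
      for (ow in seq_len(Wo)) {
        acc <- b[oc]
        for (ic in seq_len(d[3])) {
          for (kh in seq_len(k)) {
            for (kw in seq_len(k)) {
              ih <- (oh - 1) * stride - pad + kh
              iw <- (ow - 1) * stride - pad + kw
              if (ih >= 1 && ih <= d[1] && iw >= 1 && iw <= d[2]) {
                acc <- acc + x[ih, iw, ic] * warr[kh, kw, ic, oc]
              }
            }
          }
        }
        out[oh, ow, oc] <- acc
      }
    }
  }
  out
}

# Brute-force channel permutation from the reshape-(g, C/g)-transpose rule.
oracle_shuffle_perm <- function(C, g) {
  src <- integer(C)
  for (k in 0:(C - 1)) {
    i <- k %/% (C / g)
    j <- k %% (C / g)
    src[k + 1] <- j * g + i + 1
  }
  src
}

oracle_channel_shuffle <- function(x, g) {
  d <- dim(x)
  out <- array(0, d)
  src <- oracle_shuffle_perm(d[3], g)
  for (k in seq_len(d[3])) out[, , k] <- x[, , src[k]]
  out
}

# Eq-style channel attention: per spatial location, FC squeeze + ReLU +
# FC restore + sigmoid over the channel vector, then elementwise product.
oracle_sgam_channel <- function(x, params) {
  d <- dim(x)
  C <- d[3]
  Cb <- ncol(params$w1)
  ac <- array(0, d)
  for (h in seq_len(d[1])) {
    for (w in seq_len(d[2])) {
      hid <- numeric(Cb)
      for (cb in seq_len(Cb)) {
        s <- params$b1[cb]
        for (c in seq_len(C)) s <- s + x[h, w, c] * params$w1[c, cb]
        hid[cb] <- max(s, 0)
      }
      for (c in seq_len(C)) {
        s <- params$b2[c]
        for (cb in seq_len(Cb)) s <- s + hid[cb] * params$w2[cb, c]
        ac[h, w, c] <- 1 / (1 + exp(-s))
      }
    }
  }
  list(weights = ac, output = x * ac)
}

# 7x7 conv -> ReLU -> BN (given statistics) -> 7x7 conv -> sigmoid ->
# channel shuffle -> elementwise product.
oracle_sgam_spatial <- function(xca, params) {
  h1 <- oracle_conv2d(xca, params$f1, params$b1, 1, 3)
  h1 <- pmax(h1, 0)
  bn <- params$bn
  for (c in seq_len(dim(h1)[3])) {
    h1[, , c] <- (h1[, , c] - bn$mean[c]) / sqrt(bn$var[c] + 1e-5) *
      bn$gamma[c] + bn$beta[c]
  }
  as_map <- 1 / (1 + exp(-oracle_conv2d(h1, params$f2, params$b2, 1, 3)))
  list(weights = as_map,
       output = xca * oracle_channel_shuffle(as_map, params$groups))
}

oracle_sgam <- function(x, channel, spatial) {
  ca <- oracle_sgam_channel(x, channel)
  oracle_sgam_spatial(ca$output, spatial)$output
}

# The seven CAM steps: 1x1 conv, per-channel spatial softmax, reweighting,
# 1x1 conv, channel-axis layer norm, 1x1 conv, sigmoid gate, residual add.
oracle_cam <- function(x, params) {
  d <- dim(x)
  conv1x1 <- function(inp, w, b) {
    dd <- dim(inp)
    out <- array(0, c(dd[1], dd[2], ncol(w)))
    for (h in seq_len(dd[1])) {
      for (ww in seq_len(dd[2])) {
        for (oc in seq_len(ncol(w))) {
          s <- b[oc]
          for (ic in seq_len(dd[3])) s <- s + inp[h, ww, ic] * w[ic, oc]
          out[h, ww, oc] <- s
        }
      }
    }
    out
  }
  sc <- conv1x1(x, params$ctx_w, params$ctx_b)
  p <- array(0, d)
  for (c in seq_len(d[3])) {
    e <- exp(sc[, , c] - max(sc[, , c]))
    p[, , c] <- e / sum(e)
  }
  xw <- x * p
  t1 <- conv1x1(xw, params$a_w, params$a_b)
  cb <- dim(t1)[3]
  for (h in seq_len(d[1])) {
    for (w in seq_len(d[2])) {
      v <- t1[h, w, ]
      mu <- mean(v)
      sd2 <- mean((v - mu)^2)
      t1[h, w, ] <- (v - mu) / sqrt(sd2 + 1e-5) * params$ln_gamma +
        params$ln_beta
    }
  }
  t2 <- conv1x1(t1, params$b_w, params$b_b)
  gate <- 1 / (1 + exp(-t2))
  x + xw * gate
}

# Rank-statistic (Mann-Whitney) AUC with 1/2 tie credit.
oracle_auc_rank <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# Random small feature map.
rand_fmap <- function(H, W, C, seed) {
  set.seed(seed)
  array(stats::rnorm(H * W * C), c(H, W, C))
}
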