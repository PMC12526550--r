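# Minimal reverse-mode autograd over HWC arrays.
#
# A "tape" records operation nodes in creation order, which is a valid
# topological order for a dynamic graph; backward() sweeps it in reverse.
# Nodes are environments: $val (array), $grad (accumulated), $parents (list
# of nodes), $backward (function(grad) -> list of parent gradients, NULL for
# parents that need no gradient). Parameter leaves persist across passes and
# keep their accumulated $grad until ag_zero_grad().

ag_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 128L)
  e$n <- 0L
  e
}

ag_node <- function(tape, val, parents = NULL, backward = NULL) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$parents <- parents
  n$backward <- backward
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[tape$n]] <- n
  }
  n
}

# Leaf node (parameter or constant); not recorded on any tape.
ag_leaf <- function(val) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$parents <- NULL
  n$backward <- NULL
  n
}

ag_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Seed gradients into `seeds` (named list of list(node=, grad=)) and sweep.
ag_backward <- function(tape, seeds) {
  for (s in seeds) ag_accum(s$node, s$grad)
  if (tape$n < 1L) return(invisible(NULL))
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (j in seq_along(gs)) {
      if (!is.null(gs[[j]])) ag_accum(ps[[j]], gs[[j]])
    }
    nd$grad <- NULL # free as we go
  }
  invisible(NULL)
}

## ---- elementwise ops -------------------------------------------------------

ag_add <- function(tape, a, b) {
  ag_node(tape, a$val + b$val, list(a, b), function(g) list(g, g))
}

ag_mul <- function(tape, a, b) {
  av <- a$val; bv <- b$val
  ag_node(tape, av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_scale <- function(tape, a, s) {
  ag_node(tape, a$val * s, list(a), function(g) list(g * s))
}

ag_relu <- function(tape, a) {
  m <- a$val > 0
  ag_node(tape, a$val * m, list(a), function(g) list(g * m))
}

ag_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$val))
  ag_node(tape, s, list(a), function(g) list(g * s * (1 - s)))
}

ag_silu <- function(tape, a) {
  v <- a$val
  s <- 1 / (1 + exp(-v))
  ag_node(tape, v * s, list(a), function(g) list(g * s * (1 + v * (1 - s))))
}

## ---- shape ops -------------------------------------------------------------

# Nearest-neighbour 2x upsampling of an (H, W, C) array.
ag_upsample2 <- function(tape, a) {
  v <- a$val
  d <- dim(v)
  ih <- rep(seq_len(d[1]), each = 2)
  iw <- rep(seq_len(d[2]), each = 2)
  out <- v[ih, iw, , drop = FALSE]
  ag_node(tape, out, list(a), function(g) {
    # sum each 2x2 block
    g1 <- g[seq(1, 2 * d[1], by = 2), , , drop = FALSE] +
      g[seq(2, 2 * d[1], by = 2), , , drop = FALSE]
    list(g1[, seq(1, 2 * d[2], by = 2), , drop = FALSE] +
           g1[, seq(2, 2 * d[2], by = 2), , drop = FALSE])
  })
}

ag_concat_c <- function(tape, a, b) {
  da <- dim(a$val)
  db <- dim(b$val)
  out <- array(c(a$val, b$val), dim = c(da[1], da[2], da[3] + db[3]))
  ag_node(tape, out, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), drop = FALSE],
         g[, , da[3] + seq_len(db[3]), drop = FALSE])
  })
}

# Channel permutation (used by channel shuffle); perm indexes input channels.
ag_permute_c <- function(tape, a, perm) {
  inv <- order(perm)
  ag_node(tape, a$val[, , perm, drop = FALSE], list(a),
          function(g) list(g[, , inv, drop = FALSE]))
}

## ---- normalisation & softmax ----------------------------------------------

# Softmax over the H*W spatial positions of each channel.
ag_softmax_spatial <- function(tape, a) {
  v <- a$val
  d <- dim(v)
  m <- matrix(v, d[1] * d[2], d[3])
  m <- sweep(m, 2, apply(m, 2, max), "-")
  e <- exp(m)
  s <- sweep(e, 2, colSums(e), "/")
  out <- array(s, d)
  ag_node(tape, out, list(a), function(g) {
    gm <- matrix(g, d[1] * d[2], d[3])
    dot <- colSums(gm * s)
    list(array(s * sweep(gm, 2, dot, "-"), d))
  })
}

# Layer normalisation across the channel axis at each spatial position,
# with learnable per-channel affine (gamma, beta leaves).
ag_layernorm_c <- function(tape, a, gamma, beta, eps = 1e-5) {
  v <- a$val
  d <- dim(v)
  C <- d[3]
  m <- matrix(v, d[1] * d[2], C) # rows = positions
  mu <- rowMeans(m)
  xc <- m - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gam <- gamma$val
  out <- array(sweep(xhat, 2, gam, "*") + rep(beta$val, each = d[1] * d[2]), d)
  ag_node(tape, out, list(a, gamma, beta), function(g) {
    gm <- matrix(g, d[1] * d[2], C)
    ggamma <- colSums(gm * xhat)
    gbeta <- colSums(gm)
    gxhat <- sweep(gm, 2, gam, "*")
    # standard LN backward over the channel axis
    t1 <- gxhat
    t2 <- rowMeans(gxhat)
    t3 <- xhat * rowMeans(gxhat * xhat)
    gx <- inv * (t1 - t2 - t3)
    list(array(gx, d), ggamma, gbeta)
  })
}

# Batch normalisation over spatial positions, per channel. `layer` is an
# environment with $gamma, $beta (leaves), $rmean, $rvar (numeric vectors),
# $momentum. With training = TRUE the per-sample spatial statistics are used
# (batch-of-one regime) and running stats updated; otherwise running stats.
ag_batchnorm_c <- function(tape, a, layer, training = FALSE, eps = 1e-5) {
  v <- a$val
  d <- dim(v)
  C <- d[3]
  m <- matrix(v, d[1] * d[2], C)
  gam <- layer$gamma$val
  if (training && d[1] * d[2] > 1) {
    mu <- colMeans(m)
    va <- colMeans(sweep(m, 2, mu)^2)
    layer$rmean <- (1 - layer$momentum) * layer$rmean + layer$momentum * mu
    layer$rvar <- (1 - layer$momentum) * layer$rvar + layer$momentum * va
    inv <- 1 / sqrt(va + eps)
    xhat <- sweep(sweep(m, 2, mu), 2, inv, "*")
    out <- array(sweep(xhat, 2, gam, "*") +
                   rep(layer$beta$val, each = d[1] * d[2]), d)
    n <- d[1] * d[2]
    ag_node(tape, out, list(a, layer$gamma, layer$beta), function(g) {
      gm <- matrix(g, n, C)
      ggamma <- colSums(gm * xhat)
      gbeta <- colSums(gm)
      gxhat <- sweep(gm, 2, gam, "*")
      gx <- sweep(gxhat, 2, colMeans(gxhat)) -
        xhat * rep(colMeans(gxhat * xhat), each = n)
      gx <- sweep(gx, 2, inv, "*")
      list(array(gx, d), ggamma, gbeta)
    })
  } else {
    inv <- 1 / sqrt(layer$rvar + eps)
    scale <- gam * inv
    shift <- layer$beta$val - layer$rmean * scale
    out <- array(sweep(sweep(m, 2, scale, "*"), 2, shift, "+"), d)
    xhat <- sweep(sweep(m, 2, layer$rmean), 2, inv, "*")
    n <- d[1] * d[2]
    ag_node(tape, out, list(a, layer$gamma, layer$beta), function(g) {
      gm <- matrix(g, n, C)
      list(array(sweep(gm, 2, scale, "*"), d),
           colSums(gm * xhat), colSums(gm))
    })
  }
}

## ---- convolution -----------------------------------------------------------

# Convolution layer parameters: weight leaf holds a (k*k*Cin) x Cout matrix.
conv_params <- function(cin, cout, k, gain = 2) {
  fan_in <- k * k * cin
  w <- matrix(stats::rnorm(fan_in * cout, sd = sqrt(gain / fan_in)),
              fan_in, cout)
  list(w = ag_leaf(w), b = ag_leaf(numeric(cout)), k = k,
       cin = cin, cout = cout)
}

ag_conv <- function(tape, x, p, stride = 1L, pad = (p$k - 1L) %/% 2L,
                    act = FALSE) {
  xv <- x$val
  acti <- as.integer(act)
  out <- conv2d_fw(xv, p$w$val, p$b$val, p$k, stride, pad, acti)
  ag_node(tape, out, list(x, p$w, p$b), function(g) {
    r <- conv2d_bw(xv, g, p$w$val, p$b$val, p$k, stride, pad, acti)
    list(r$gx, r$gw, as.numeric(r$gb))
  })
}

## ---- parameter handling ----------------------------------------------------

# Recursively collect ag_leaf parameter nodes from a nested structure.
# Environments with numeric $val are parameter leaves; batch-norm layer
# environments expose their affine leaves via $gamma/$beta.
collect_params <- function(x) {
  out <- list()
  walk <- function(v) {
    if (is.environment(v)) {
      if (!is.null(v$val) && is.numeric(v$val)) {
        out[[length(out) + 1L]] <<- v
      } else if (!is.null(v$gamma)) {
        walk(v$gamma)
        walk(v$beta)
      }
    } else if (is.list(v)) {
      for (el in v) walk(el)
    }
  }
  walk(x)
  out
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Adam with decoupled weight decay. `state` persists across steps.
adam_step <- function(params, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad
    key <- as.character(i)
    if (is.null(state$m[[key]])) {
      state$m[[key]] <- g * 0
      state$v[[key]] <- g * 0
    }
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    mhat <- state$m[[key]] / (1 - beta1^state$t)
    vhat <- state$v[[key]] / (1 - beta2^state$t)
    upd <- mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && length(dim(p$val)) == 2) upd <- upd + weight_decay * p$val
    p$val <- p$val - lr * upd
  }
  invisible(NULL)
}

adam_state <- function() {
  e <- new.env(parent = emptyenv())
  e$t <- 0L
  e$m <- list()
  e$v <- list()
  e
}
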