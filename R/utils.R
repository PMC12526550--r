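# Small shared helpers.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. Seeds derived from user seeds are kept inside
# 32-bit integer range.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 7919) %% 2147483647)
}

# Nearest-neighbour resize of an (H, W, C) array to (h, w).
resize_image <- function(img, h, w = h) {
  d <- dim(img)
  ri <- pmin(d[1], pmax(1L, round((seq_len(h) - 0.5) * d[1] / h + 0.5)))
  ci <- pmin(d[2], pmax(1L, round((seq_len(w) - 0.5) * d[2] / w + 0.5)))
  img[ri, ci, , drop = FALSE]
}
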