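# Independent straight-line oracles used to cross-check the vectorised
# implementations.  Everything here is deliberately written with explicit
# loops and no shared code with the package internals.

# Matrix product via triple loop.
oracle_matmul <- function(a, b) {
  out <- matrix(0, nrow(a), ncol(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(ncol(b)))
      for (k in seq_len(ncol(a)))
        out[i, j] <- out[i, j] + a[i, k] * b[k, j]
  out
}

# Full attention block computed position-by-position with loops.
# Follows the row-major flattening convention: flat index
# k = (h-1)*W + w for position (h, w).
oracle_gattn <- function(x, params, scaling = FALSE) {
  h <- dim(x)[1]; w <- dim(x)[2]; cc <- dim(x)[3]
  cp <- ncol(params$linear1$w)
  hw <- h * w
  xf <- matrix(0, hw, cc)
  for (hh in seq_len(h)) for (ww in seq_len(w))
    xf[(hh - 1) * w + ww, ] <- x[hh, ww, ]
  lin <- function(m, wgt, b) {
    out <- oracle_matmul(m, wgt)
    for (i in seq_len(nrow(out))) out[i, ] <- out[i, ] + b
    out
  }
  z <- lin(xf, params$linear1$w, params$linear1$b)
  p <- lin(z, params$linear2$w, params$linear2$b)
  m1 <- p[, 1:cp, drop = FALSE]
  m2 <- p[, cp + (1:cp), drop = FALSE]
  m3 <- p[, 2 * cp + (1:cp), drop = FALSE]
  mi <- matrix(0, hw, hw)
  for (i in seq_len(hw)) for (j in seq_len(hw))
    mi[i, j] <- sum(m1[i, ] * m2[j, ])
  if (scaling) mi <- mi / sqrt(cp)
  mr <- oracle_matmul(mi, m3)
  hid <- lin(mr, params$mlp1$w, params$mlp1$b)
  hid[hid < 0] <- 0
  amat <- lin(hid, params$mlp2$w, params$mlp2$b)
  ar <- numeric(hw)
  for (i in seq_len(hw)) ar[i] <- mean(amat[i, ])
  out <- array(0, dim = dim(x))
  for (hh in seq_len(h)) for (ww in seq_len(w)) {
    k <- (hh - 1) * w + ww
    out[hh, ww, ] <- (ar[k] + 1) * x[hh, ww, ]
  }
  list(output = out, MI = mi, MR = mr, ar = ar)
}

# Zero-padded 2-D convolution with loops (stride/dilation aware).
oracle_conv <- function(x, w, b, stride = 1, dilation = 1) {
  kh <- dim(w)[1]; kw <- dim(w)[2]; cin <- dim(w)[3]; cout <- dim(w)[4]
  pad <- dilation * (kh - 1) %/% 2
  h <- dim(x)[1]; wd <- dim(x)[2]
  ho <- (h + 2 * pad - (dilation * (kh - 1) + 1)) %/% stride + 1
  wo <- (wd + 2 * pad - (dilation * (kw - 1) + 1)) %/% stride + 1
  y <- array(0, dim = c(ho, wo, cout))
  for (co in seq_len(cout)) for (i in seq_len(ho)) for (j in seq_len(wo)) {
    acc <- if (is.null(b)) 0 else b[co]
    for (ci in seq_len(cin)) for (a in seq_len(kh)) for (d in seq_len(kw)) {
      hi <- (i - 1) * stride - pad + (a - 1) * dilation + 1
      wi <- (j - 1) * stride - pad + (d - 1) * dilation + 1
      if (hi >= 1 && hi <= h && wi >= 1 && wi <= wd)
        acc <- acc + x[hi, wi, ci] * w[a, d, ci, co]
    }
    y[i, j, co] <- acc
  }
  y
}

# ---- fixture builders ----------------------------------------------------

rand_feature <- function(h, w, c, seed = 1) {
  set.seed(seed)
  array(rnorm(h * w * c), dim = c(h, w, c))
}

zero_gattn_params <- function(channels, config) {
  p <- gattn_init(channels, config)
  p <- rapply(p, function(a) a * 0, how = "replace")
  class(p) <- "gattn_params"
  p
}

# A tiny spec used across the model tests.
tiny_spec <- function(attn = NULL, stages = c(1L, 1L), base_width = 4L,
                      family = "resnet") {
  segmodel_spec(
    backbone_spec(family, stages = stages, base_width = base_width,
                  attn_insertions = attn,
                  attn_config = gattn_config(embed_dim = 4L)),
    aspp_rates = c(1L, 2L, 3L), num_classes = 3L, decoder_channels = 8L)
}

# Small synthetic tiles without a full mosaic (uniform class patches).
toy_tiles <- function(n, size = 16L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    cls <- (i - 1L) %% 3L
    img <- array(runif(size * size * 3, cls * 0.3, cls * 0.3 + 0.2),
                 dim = c(size, size, 3L))
    list(image = img, mask = matrix(cls, size, size))
  })
}

toy_tileset <- function(n_train = 6L, n_val = 3L, size = 16L, seed = 1L) {
  tiles <- toy_tiles(n_train + n_val, size, seed)
  split <- rep(c("train", "val"), c(n_train, n_val))
  for (i in seq_along(tiles)) tiles[[i]]$split <- split[i]
  structure(list(
    tiles = tiles,
    manifest = data.frame(id = sprintf("tile_%05d", seq_along(tiles)),
                          split = split, x = 0L, y = 0L, seed = seed),
    crop_size = size, config = NULL), class = "tileset")
}
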