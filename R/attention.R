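# Global attention block.
#
# A single-head query-key-value attention unit for convolutional feature
# maps.  The input H x W x C map is flattened to (H*W) x C, projected to a
# low-dimensional embedding of width C' (so the (H*W)^2 affinity stays
# affordable at any C), split into query/key/value matrices, aggregated by
# the global pairwise affinity, recalibrated by a two-layer MLP, squeezed
# over channels by average pooling, and finally applied residually:
#
#   x_out = (AR + 1) * x
#
# so a zero-initialised block is an exact identity.  Spatial flattening is
# row-major over the image: flat index k (0-based) maps to
# (h, w) = (k %/% W, k %% W).

#' Configuration for the global attention block
#'
#' @param embed_dim width C' of the low-dimensional embedding the input
#'   channels are projected to before the affinity is computed. Default 64.
#' @param mlp_hidden hidden width of the recalibration MLP; defaults to
#'   `embed_dim` (the channel count is not reduced inside the MLP).
#' @param affinity_scaling if `TRUE`, divide the raw affinity by
#'   `sqrt(embed_dim)`. Off by default: the block applies the raw
#'   query-key product; the flag exists for numerical headroom on large
#'   inputs.
#' @param init initialisation scheme: `"fan_uniform"` (default; fan-based
#'   uniform draws for all four layers) or `"identity_start"` (the same,
#'   but the second MLP layer starts at zero so the whole block is an
#'   exact identity at initialisation and the attention signal grows from
#'   a safe start — useful when inserting the block into a network trained
#'   from scratch).
#' @param seed optional integer seed used by [gattn_init()].
#' @return an object of class `gattn_config`.
#' @export
gattn_config <- function(embed_dim = 64L, mlp_hidden = embed_dim,
                         affinity_scaling = FALSE,
                         init = c("fan_uniform", "identity_start"),
                         seed = NULL) {
  embed_dim <- as.integer(embed_dim)
  mlp_hidden <- as.integer(mlp_hidden)
  init <- match.arg(init)
  stopifnot(embed_dim >= 1L, mlp_hidden >= 1L)
  structure(list(embed_dim = embed_dim, mlp_hidden = mlp_hidden,
                 affinity_scaling = isTRUE(affinity_scaling),
                 init = init, seed = seed),
            class = "gattn_config")
}

#' Initialise global attention block parameters
#'
#' Four biased linear layers: `linear1` (C -> C'), `linear2` (C' -> 3C',
#' chunked into query/key/value), and the two MLP layers
#' (C' -> mlp_hidden -> C').  Fan-based uniform initialisation.
#'
#' @param channels input channel count C.
#' @param config a [gattn_config()].
#' @return named list of parameter arrays, class `gattn_params`.
#' @export
gattn_init <- function(channels, config = gattn_config()) {
  stopifnot(channels >= 1L)
  if (!is.null(config$seed)) set.seed(config$seed)
  cp <- config$embed_dim
  mlp2 <- init_linear(config$mlp_hidden, cp)
  if (identical(config$init, "identity_start")) {
    mlp2$w[] <- 0
    mlp2$b[] <- 0
  }
  structure(list(
    linear1 = init_linear(channels, cp),
    linear2 = init_linear(cp, 3L * cp),
    mlp1    = init_linear(cp, config$mlp_hidden),
    mlp2    = mlp2
  ), class = "gattn_params", channels = channels)
}

# Row-major (h-major, then w) spatial flattening and its inverse.
flatten_hw <- function(x) {
  d <- dim(x)
  m <- matrix(aperm(x, c(2L, 1L, 3L)), nrow = d[1] * d[2], ncol = d[3])
  m
}

unflatten_hw <- function(m, h, w) {
  aperm(array(m, dim = c(w, h, ncol(m))), c(2L, 1L, 3L))
}

check_feature <- function(x) {
  if (length(dim(x)) != 3L)
    stop("feature map must be an H x W x C array")
  if (any(!is.finite(x))) stop("feature map contains non-finite values")
  invisible(x)
}

#' Project a feature map into the attention embedding
#'
#' Flattens the `H x W x C` input row-major to `(H*W) x C` and applies the
#' first linear layer, shrinking the channel dimension to C'.
#'
#' @param x feature array `H x W x C`.
#' @param params a [gattn_init()] parameter set.
#' @return matrix `(H*W) x C'`; row k is spatial position
#'   `(k %/% W, k %% W)` (0-based).
#' @export
gattn_project <- function(x, params) {
  check_feature(x)
  if (dim(x)[3] != nrow(params$linear1$w))
    stop("input has ", dim(x)[3], " channels but linear1 expects ",
         nrow(params$linear1$w))
  xf <- flatten_hw(x)
  sweep(xf %*% params$linear1$w, 2L, params$linear1$b, "+")
}

#' Chunk the second projection into query/key/value matrices
#'
#' Applies `linear2` (C' -> 3C') and partitions the output columns
#' contiguously: `[1, C']` -> M1 (query), `(C', 2C']` -> M2 (key),
#' `(2C', 3C']` -> M3 (value).
#'
#' @param z `(H*W) x C'` matrix from [gattn_project()].
#' @inheritParams gattn_project
#' @return list with matrices `M1`, `M2`, `M3`, each `(H*W) x C'`.
#' @export
gattn_qkv <- function(z, params) {
  cp <- ncol(z)
  if (nrow(params$linear2$w) != cp || ncol(params$linear2$w) != 3L * cp)
    stop("linear2 must map C' to 3*C'")
  p <- sweep(z %*% params$linear2$w, 2L, params$linear2$b, "+")
  list(M1 = p[, seq_len(cp), drop = FALSE],
       M2 = p[, cp + seq_len(cp), drop = FALSE],
       M3 = p[, 2L * cp + seq_len(cp), drop = FALSE])
}

#' Global pairwise affinity between spatial positions
#'
#' `MI = M1 %*% t(M2)`: entry (i, j) is the dot-product similarity between
#' positions i and j of the embedded feature map, giving every output
#' position a global receptive field.  No softmax or other normalisation is
#' applied; with `scaling = TRUE` entries are divided by `sqrt(C')`.
#'
#' @param m1,m2 query and key matrices, `(H*W) x C'`.
#' @param scaling logical, see [gattn_config()]`$affinity_scaling`.
#' @return `(H*W) x (H*W)` affinity matrix.
#' @export
gattn_affinity <- function(m1, m2, scaling = FALSE) {
  stopifnot(identical(dim(m1), dim(m2)))
  mi <- tcrossprod(m1, m2)
  if (isTRUE(scaling)) mi <- mi / sqrt(ncol(m1))
  mi
}

#' Aggregate values by the global affinity
#'
#' @param mi `(H*W) x (H*W)` affinity from [gattn_affinity()].
#' @param m3 value matrix `(H*W) x C'`.
#' @return `MR = MI %*% M3`, an `(H*W) x C'` matrix in which every row
#'   draws on all spatial positions of the input.
#' @export
gattn_aggregate <- function(mi, m3) {
  stopifnot(ncol(mi) == nrow(m3), nrow(mi) == nrow(m3))
  mi %*% m3
}

#' Recalibrate the aggregated features with a two-layer MLP
#'
#' Linear -> ReLU -> linear (no nonlinearity after the second layer, and no
#' channel reduction), then the row-major flattening is inverted to give
#' the attention map `A` of shape `H x W x C'`.
#'
#' @param mr `(H*W) x C'` matrix from [gattn_aggregate()].
#' @inheritParams gattn_project
#' @param h,w spatial size of the originating feature map.
#' @return attention map array `H x W x C'`.
#' @export
gattn_recalibrate <- function(mr, params, h, w) {
  stopifnot(nrow(mr) == h * w)
  hid <- pmax(sweep(mr %*% params$mlp1$w, 2L, params$mlp1$b, "+"), 0)
  a <- sweep(hid %*% params$mlp2$w, 2L, params$mlp2$b, "+")
  unflatten_hw(a, h, w)
}

#' Squeeze the attention map channels by average pooling
#'
#' @param a attention map `H x W x C'`.
#' @return refined attention map `AR` of shape `H x W x 1`, the per-pixel
#'   channel mean.
#' @export
gattn_squeeze <- function(a) {
  stopifnot(length(dim(a)) == 3L)
  d <- dim(a)
  ar <- rowMeans(matrix(a, nrow = d[1] * d[2], ncol = d[3]))
  array(ar, dim = c(d[1], d[2], 1L))
}

#' Apply a refined attention map residually
#'
#' `x_out[h, w, c] = (AR[h, w, 1] + 1) * x[h, w, c]`, the refined map being
#' broadcast along channels.  `AR = 0` leaves the input untouched.
#'
#' @param x feature array `H x W x C`.
#' @param ar refined attention map `H x W x 1`.
#' @return re-weighted feature array, same shape as `x`.
#' @export
gattn_apply <- function(x, ar) {
  dx <- dim(x); da <- dim(ar)
  if (da[1] != dx[1] || da[2] != dx[2])
    stop("attention map is ", da[1], "x", da[2],
         " but feature map is ", dx[1], "x", dx[2])
  # channel is the trailing dimension, so column-major recycling of the
  # H*W map broadcasts it along channels
  x * array(c(ar) + 1, dim = dx)
}

#' Full forward pass of the global attention block
#'
#' Chains projection, query/key/value chunking, global affinity,
#' aggregation, MLP recalibration, channel squeeze and residual
#' application.  The output has exactly the shape of the input.
#'
#' @inheritParams gattn_project
#' @param config the [gattn_config()] the parameters were built with.
#' @return list with `output` (`H x W x C`) and `trace`, a list exposing
#'   every intermediate (`Z`, `M1`, `M2`, `M3`, `MI`, `MR`, `A`, `AR`).
#' @export
gattn_forward <- function(x, params, config = gattn_config(
                            embed_dim = ncol(params$linear1$w))) {
  d <- dim(x)
  z <- gattn_project(x, params)
  qkv <- gattn_qkv(z, params)
  mi <- gattn_affinity(qkv$M1, qkv$M2, scaling = config$affinity_scaling)
  mr <- gattn_aggregate(mi, qkv$M3)
  a <- gattn_recalibrate(mr, params, d[1], d[2])
  ar <- gattn_squeeze(a)
  out <- gattn_apply(x, ar)
  list(output = out,
       trace = list(Z = z, M1 = qkv$M1, M2 = qkv$M2, M3 = qkv$M3,
                    MI = mi, MR = mr, A = a, AR = ar))
}

#' Trainable parameter count of a global attention block
#'
#' Counts weights and biases of the four linear layers:
#' `(C*C' + C') + (C'*3C' + 3C') + (C'*mlp + mlp) + (mlp*C' + C')`.
#'
#' @param channels input channel count C.
#' @param config a [gattn_config()].
#' @return integer parameter count.
#' @export
gattn_param_count <- function(channels, config = gattn_config()) {
  stopifnot(channels >= 1L)
  cp <- config$embed_dim; mh <- config$mlp_hidden
  (channels * cp + cp) + (cp * 3L * cp + 3L * cp) +
    (cp * mh + mh) + (mh * cp + cp)
}

# ---- training support ----------------------------------------------------

# Forward pass that additionally retains everything the backward pass
# needs (flattened input, MLP pre-activation).
gattn_forward_train <- function(x, params, config) {
  d <- dim(x)
  xf <- flatten_hw(x)
  z <- sweep(xf %*% params$linear1$w, 2L, params$linear1$b, "+")
  qkv <- gattn_qkv(z, params)
  mi <- gattn_affinity(qkv$M1, qkv$M2, scaling = config$affinity_scaling)
  mr <- gattn_aggregate(mi, qkv$M3)
  pre <- sweep(mr %*% params$mlp1$w, 2L, params$mlp1$b, "+")
  hid <- pmax(pre, 0)
  amat <- sweep(hid %*% params$mlp2$w, 2L, params$mlp2$b, "+")
  ar <- rowMeans(amat)
  out <- unflatten_hw(xf * (ar + 1), d[1], d[2])
  list(y = out,
       cache = list(xf = xf, z = z, M1 = qkv$M1, M2 = qkv$M2, M3 = qkv$M3,
                    mi = mi, mr = mr, pre = pre, hid = hid, ar = ar,
                    dimx = d, params = params, config = config))
}

# Backward pass: returns gradient w.r.t. the input feature map and every
# parameter of the block.
gattn_backward <- function(gy, cache) {
  p <- cache$params
  d <- cache$dimx
  gyf <- flatten_hw(gy)
  gxf <- gyf * (cache$ar + 1)
  gar <- rowSums(gyf * cache$xf)
  # channel average-pool spreads the per-pixel gradient uniformly
  cp <- ncol(cache$z)
  gamat <- matrix(gar / cp, nrow = length(gar), ncol = cp)
  ghid <- tcrossprod(gamat, p$mlp2$w)
  gw_mlp2 <- crossprod(cache$hid, gamat)
  gb_mlp2 <- colSums(gamat)
  gpre <- ghid * (cache$pre > 0)
  gw_mlp1 <- crossprod(cache$mr, gpre)
  gb_mlp1 <- colSums(gpre)
  gmr <- tcrossprod(gpre, p$mlp1$w)
  gmi <- tcrossprod(gmr, cache$M3)
  gM3 <- crossprod(cache$mi, gmr)
  scale <- if (isTRUE(cache$config$affinity_scaling)) 1 / sqrt(cp) else 1
  gM1 <- (gmi %*% cache$M2) * scale
  gM2 <- (crossprod(gmi, cache$M1)) * scale
  gp2 <- cbind(gM1, gM2, gM3)
  gz <- tcrossprod(gp2, p$linear2$w)
  gw_l2 <- crossprod(cache$z, gp2)
  gb_l2 <- colSums(gp2)
  gxf <- gxf + tcrossprod(gz, p$linear1$w)
  gw_l1 <- crossprod(cache$xf, gz)
  gb_l1 <- colSums(gz)
  list(gx = unflatten_hw(gxf, d[1], d[2]),
       grads = list(linear1 = list(w = gw_l1, b = gb_l1),
                    linear2 = list(w = gw_l2, b = gb_l2),
                    mlp1 = list(w = gw_mlp1, b = gb_mlp1),
                    mlp2 = list(w = gw_mlp2, b = gb_mlp2)))
}
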