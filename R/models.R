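# Compact encoder-decoder segmentation models.
#
# The encoder is a small strided-convolution backbone (plain "vgg"-style
# blocks, residual "resnet"-style blocks, or bottleneck "mobilenet"-style
# blocks) with optional global attention blocks inserted per-block: the
# attention branch is computed from the block input and re-weights the
# block's main-path output before the residual addition.  The decoder is an
# atrous spatial pyramid pooling (ASPP) head: three parallel atrous
# convolutions at distinct rates plus a pointwise branch, concatenated,
# projected, and classified; logits are bilinearly upsampled to label
# resolution.

#' Specification of a convolution layer for receptive-field analysis
#'
#' @param kernel positive odd kernel size.
#' @param stride positive integer stride.
#' @param rate atrous (dilation) rate; 1 is a standard convolution.
#' @return a `layer_spec` list.
#' @export
layer_spec <- function(kernel, stride = 1L, rate = 1L) {
  stopifnot(kernel >= 1L, kernel %% 2L == 1L, stride >= 1L, rate >= 1L)
  structure(list(kernel = as.integer(kernel), stride = as.integer(stride),
                 rate = as.integer(rate)), class = "layer_spec")
}

#' Receptive field of a stack of (atrous) convolutions
#'
#' Side length in input pixels of the patch that influences one output
#' pixel:
#' `RF = 1 + sum_i (k_i - 1) * r_i * prod_{j<i} s_j`.
#' Two stacked 3x3 convolutions give 5; dilating the second to rate 2
#' gives 7.
#'
#' @param layers list of [layer_spec()] objects, outermost (closest to the
#'   input) first.
#' @return integer receptive-field side length.
#' @export
receptive_field <- function(layers) {
  if (length(layers) == 0L) stop("empty layer list")
  rf <- 1L
  jump <- 1L
  for (l in layers) {
    rf <- rf + (l$kernel - 1L) * l$rate * jump
    jump <- jump * l$stride
  }
  rf
}

#' Backbone specification
#'
#' A stem convolution (stride 2) followed by stages; each stage opens with
#' a stride-2 transition convolution and continues with stride-1 blocks in
#' the family's style.  Attention blocks can be inserted at any
#' (stage, block) position; by default the final block of the last two
#' stages, where the spatial grid is smallest and the (H*W)^2 affinity is
#' cheapest.
#'
#' @param family one of `"resnet"` (two 3x3 convolutions with an identity
#'   skip), `"vgg"` (a single 3x3 convolution), `"mobilenet"` (pointwise
#'   expand, 3x3, pointwise project with an identity skip).
#' @param stages integer vector of block counts per stage.
#' @param base_width channel count of the first stage (doubled each stage).
#' @param width_multiplier multiplier on all stage widths.
#' @param attn_insertions list of `c(stage, block)` pairs, or `NULL` for
#'   none, or `"default"` for the final block of the last two stages.
#' @param attn_config a [gattn_config()] for inserted blocks.
#' @return a `backbone_spec` object.
#' @export
backbone_spec <- function(family = c("resnet", "vgg", "mobilenet"),
                          stages = c(1L, 1L),
                          base_width = 8L,
                          width_multiplier = 1,
                          attn_insertions = NULL,
                          attn_config = gattn_config(embed_dim = 16L)) {
  family <- match.arg(family)
  stages <- as.integer(stages)
  stopifnot(length(stages) >= 1L, all(stages >= 1L), base_width >= 1L,
            width_multiplier > 0)
  widths <- as.integer(round(base_width * 2^(seq_along(stages) - 1L) *
                               width_multiplier))
  if (identical(attn_insertions, "default")) {
    last <- seq_along(stages)
    last <- last[last > length(stages) - 2L]
    attn_insertions <- lapply(last, function(s) c(s, stages[s]))
  }
  if (!is.null(attn_insertions)) {
    for (pos in attn_insertions) {
      if (length(pos) != 2L || pos[1] < 1L || pos[1] > length(stages) ||
          pos[2] < 1L || pos[2] > stages[pos[1]])
        stop("invalid attention insertion position (",
             paste(pos, collapse = ", "), ")")
    }
  }
  structure(list(family = family, stages = stages, widths = widths,
                 attn_insertions = attn_insertions,
                 attn_config = attn_config),
            class = "backbone_spec")
}

#' Segmentation model specification
#'
#' @param backbone a [backbone_spec()].
#' @param aspp_rates exactly three distinct positive atrous rates for the
#'   pyramid branches.
#' @param num_classes K, number of segmentation classes (>= 2).
#' @param decoder_channels channel width of the ASPP branches and
#'   projection.
#' @return a `segmodel_spec` object; `$output_stride` is the encoder
#'   downsampling factor implied by the stem and stage strides.
#' @export
segmodel_spec <- function(backbone = backbone_spec(),
                          aspp_rates = c(6L, 12L, 18L),
                          num_classes = 3L,
                          decoder_channels = 32L) {
  aspp_rates <- as.integer(aspp_rates)
  if (length(aspp_rates) != 3L || anyDuplicated(aspp_rates) ||
      any(aspp_rates < 1L))
    stop("aspp_rates must be three distinct positive integers")
  stopifnot(num_classes >= 2L, decoder_channels >= 1L)
  structure(list(backbone = backbone, aspp_rates = aspp_rates,
                 num_classes = as.integer(num_classes),
                 decoder_channels = as.integer(decoder_channels),
                 output_stride = 2L^(1L + length(backbone$stages))),
            class = "segmodel_spec")
}

has_attn <- function(bspec, stage, block) {
  if (is.null(bspec$attn_insertions)) return(FALSE)
  any(vapply(bspec$attn_insertions,
             function(p) p[1] == stage && p[2] == block, logical(1)))
}

init_block <- function(family, width) {
  switch(family,
         resnet = list(conv1 = init_conv(3L, 3L, width, width),
                       conv2 = init_conv(3L, 3L, width, width)),
         vgg = list(conv1 = init_conv(3L, 3L, width, width)),
         mobilenet = list(conv1 = init_conv(1L, 1L, width, 2L * width),
                          conv2 = init_conv(3L, 3L, 2L * width, 2L * width),
                          conv3 = init_conv(1L, 1L, 2L * width, width)))
}

#' Build a segmentation model
#'
#' Instantiates all parameters of the encoder, the inserted attention
#' blocks and the ASPP decoder with seeded fan-based uniform
#' initialisation.
#'
#' @param spec a [segmodel_spec()].
#' @param seed integer seed; the same spec and seed give identical
#'   parameters.
#' @return a `segmodel` object (spec plus nested parameter list).
#' @export
build_segmodel <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "segmodel_spec"))
  set.seed(seed)
  bs <- spec$backbone
  backbone <- list(stem = init_conv(3L, 3L, 3L, bs$widths[1]))
  for (s in seq_along(bs$stages)) {
    cin <- if (s == 1L) bs$widths[1] else bs$widths[s - 1L]
    stage <- list(trans = init_conv(3L, 3L, cin, bs$widths[s]))
    blocks <- list()
    for (b in seq_len(bs$stages[s])) {
      blk <- init_block(bs$family, bs$widths[s])
      if (has_attn(bs, s, b))
        blk$attn <- gattn_init(bs$widths[s], bs$attn_config)
      blocks[[b]] <- blk
    }
    names(blocks) <- paste0("block", seq_along(blocks))
    stage$blocks <- blocks
    backbone[[paste0("stage", s)]] <- stage
  }
  cenc <- bs$widths[length(bs$widths)]
  dc <- spec$decoder_channels
  decoder <- list(
    aspp0 = init_conv(1L, 1L, cenc, dc),
    aspp1 = init_conv(3L, 3L, cenc, dc),
    aspp2 = init_conv(3L, 3L, cenc, dc),
    aspp3 = init_conv(3L, 3L, cenc, dc),
    project = init_conv(1L, 1L, 4L * dc, dc),
    classifier = init_conv(1L, 1L, dc, spec$num_classes))
  structure(list(spec = spec,
                 params = list(backbone = backbone, decoder = decoder)),
            class = "segmodel")
}

# ---- forward / backward --------------------------------------------------

block_forward <- function(x, blk, family, attn_config, keep = FALSE) {
  cache <- list(family = family, attn = !is.null(blk$attn))
  if (cache$attn) {
    at <- gattn_forward_train(x, blk$attn, attn_config)
    cache$attn_cache <- at$cache
    arp1 <- (at$cache$ar + 1)
  }
  if (family == "resnet") {
    c1 <- conv_forward(x, blk$conv1$w, blk$conv1$b)
    r1 <- relu_forward(c1$y)
    c2 <- conv_forward(r1$y, blk$conv2$w, blk$conv2$b)
    main <- c2$y
    cache$c1 <- c1$cache; cache$m1 <- r1$mask; cache$c2 <- c2$cache
  } else if (family == "vgg") {
    c1 <- conv_forward(x, blk$conv1$w, blk$conv1$b)
    main <- c1$y
    cache$c1 <- c1$cache
  } else {
    c1 <- conv_forward(x, blk$conv1$w, blk$conv1$b)
    r1 <- relu_forward(c1$y)
    c2 <- conv_forward(r1$y, blk$conv2$w, blk$conv2$b)
    r2 <- relu_forward(c2$y)
    c3 <- conv_forward(r2$y, blk$conv3$w, blk$conv3$b)
    main <- c3$y
    cache$c1 <- c1$cache; cache$m1 <- r1$mask
    cache$c2 <- c2$cache; cache$m2 <- r2$mask
    cache$c3 <- c3$cache
  }
  if (cache$attn) {
    d <- dim(main)
    cache$main_pre_attn <- main
    main <- main * array(unflatten_hw(matrix(arp1), d[1], d[2]), dim = d)
  }
  if (family == "vgg") {
    r <- relu_forward(main)
    y <- r$y
    cache$mout <- r$mask
  } else {
    s <- x + main
    r <- relu_forward(s)
    y <- r$y
    cache$mout <- r$mask
  }
  list(y = y, cache = cache)
}

block_backward <- function(gy, blk, cache, attn_config) {
  g <- relu_backward(gy, cache$mout)
  grads <- list()
  gx_skip <- if (cache$family == "vgg") 0 else g
  gmain <- g
  if (cache$attn) {
    at <- cache$attn_cache
    d <- dim(gmain)
    arp1_arr <- array(unflatten_hw(matrix(at$ar + 1), d[1], d[2]), dim = d)
    # gradient into the attention map AR via the product with the main path
    main_pre <- if (!is.null(cache$main_pre_attn)) cache$main_pre_attn else
      stop("attention block backward requires cached pre-attention output")
    gmain_scaled <- gmain * arp1_arr
    gar_map <- apply(gmain * main_pre, c(1L, 2L), sum)
    gmain <- gmain_scaled
  }
  if (cache$family == "resnet") {
    b2 <- conv_backward(gmain, cache$c2)
    grads$conv2 <- list(w = b2$gw, b = b2$gb)
    g1 <- relu_backward(b2$gx, cache$m1)
    b1 <- conv_backward(g1, cache$c1)
    grads$conv1 <- list(w = b1$gw, b = b1$gb)
    gx <- b1$gx
  } else if (cache$family == "vgg") {
    b1 <- conv_backward(gmain, cache$c1)
    grads$conv1 <- list(w = b1$gw, b = b1$gb)
    gx <- b1$gx
  } else {
    b3 <- conv_backward(gmain, cache$c3)
    grads$conv3 <- list(w = b3$gw, b = b3$gb)
    g2 <- relu_backward(b3$gx, cache$m2)
    b2 <- conv_backward(g2, cache$c2)
    grads$conv2 <- list(w = b2$gw, b = b2$gb)
    g1 <- relu_backward(b2$gx, cache$m1)
    b1 <- conv_backward(g1, cache$c1)
    grads$conv1 <- list(w = b1$gw, b = b1$gb)
    gx <- b1$gx
  }
  if (cache$attn) {
    # route the AR gradient through the attention branch; its input is the
    # block input, so the returned gx adds to the main-path input gradient
    ab <- gattn_backward_ar(gar_map, cache$attn_cache)
    grads$attn <- ab$grads
    gx <- gx + ab$gx
  }
  if (!identical(gx_skip, 0)) gx <- gx + gx_skip
  list(gx = gx, grads = grads)
}

# Backward through the attention branch when only the refined map AR (not
# the re-weighted output) received a gradient.  gar is an H x W matrix.
gattn_backward_ar <- function(gar, cache) {
  p <- cache$params
  d <- cache$dimx
  cp <- ncol(cache$z)
  garf <- c(t(gar))  # row-major flatten to match the trace convention
  gamat <- matrix(garf / cp, nrow = length(garf), ncol = cp)
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
  gxf <- tcrossprod(gz, p$linear1$w)
  gw_l1 <- crossprod(cache$xf, gz)
  gb_l1 <- colSums(gz)
  list(gx = unflatten_hw(gxf, d[1], d[2]),
       grads = list(linear1 = list(w = gw_l1, b = gb_l1),
                    linear2 = list(w = gw_l2, b = gb_l2),
                    mlp1 = list(w = gw_mlp1, b = gb_mlp1),
                    mlp2 = list(w = gw_mlp2, b = gb_mlp2)))
}

segmodel_forward <- function(model, image, keep = FALSE) {
  spec <- model$spec
  bs <- spec$backbone
  p <- model$params
  caches <- list()
  image <- (image - 0.5) * 2  # centre [0,1] inputs to [-1,1]
  st <- conv_forward(image, p$backbone$stem$w, p$backbone$stem$b,
                     stride = 2L)
  r <- relu_forward(st$y)
  caches$stem <- st$cache; caches$stem_mask <- r$mask
  x <- r$y
  caches$stages <- list()
  for (s in seq_along(bs$stages)) {
    sp <- p$backbone[[paste0("stage", s)]]
    tr <- conv_forward(x, sp$trans$w, sp$trans$b, stride = 2L)
    rt <- relu_forward(tr$y)
    scache <- list(trans = tr$cache, trans_mask = rt$mask, blocks = list())
    x <- rt$y
    for (b in seq_len(bs$stages[s])) {
      bf <- block_forward(x, sp$blocks[[b]], bs$family, bs$attn_config,
                          keep = TRUE)
      scache$blocks[[b]] <- bf$cache
      x <- bf$y
    }
    caches$stages[[s]] <- scache
  }
  # ASPP decoder
  d <- p$decoder
  rates <- spec$aspp_rates
  a0 <- conv_forward(x, d$aspp0$w, d$aspp0$b)
  a1 <- conv_forward(x, d$aspp1$w, d$aspp1$b, dilation = rates[1])
  a2 <- conv_forward(x, d$aspp2$w, d$aspp2$b, dilation = rates[2])
  a3 <- conv_forward(x, d$aspp3$w, d$aspp3$b, dilation = rates[3])
  cat_ <- array(c(a0$y, a1$y, a2$y, a3$y),
                dim = c(dim(a0$y)[1], dim(a0$y)[2], 4L * dim(a0$y)[3]))
  rcat <- relu_forward(cat_)
  pr <- conv_forward(rcat$y, d$project$w, d$project$b)
  rp <- relu_forward(pr$y)
  cl <- conv_forward(rp$y, d$classifier$w, d$classifier$b)
  logits <- bilinear_resize(cl$y, dim(image)[1], dim(image)[2])
  caches$aspp <- list(a0 = a0$cache, a1 = a1$cache, a2 = a2$cache,
                      a3 = a3$cache, cat_mask = rcat$mask,
                      project = pr$cache, project_mask = rp$mask,
                      classifier = cl$cache,
                      coarse_dim = dim(cl$y), full_dim = dim(image))
  list(logits = logits, cache = if (keep) caches else NULL)
}

segmodel_backward <- function(glogits, model, caches) {
  spec <- model$spec
  bs <- spec$backbone
  ac <- caches$aspp
  g <- bilinear_resize_grad(glogits, ac$coarse_dim[1], ac$coarse_dim[2])
  grads <- list(backbone = list(), decoder = list())
  bcl <- conv_backward(g, ac$classifier)
  grads$decoder$classifier <- list(w = bcl$gw, b = bcl$gb)
  gp <- relu_backward(bcl$gx, ac$project_mask)
  bpr <- conv_backward(gp, ac$project)
  grads$decoder$project <- list(w = bpr$gw, b = bpr$gb)
  gcat <- relu_backward(bpr$gx, ac$cat_mask)
  dc <- dim(gcat)[3] %/% 4L
  sl <- function(i) gcat[, , (i - 1L) * dc + seq_len(dc), drop = FALSE]
  b0 <- conv_backward(sl(1L), ac$a0)
  b1 <- conv_backward(sl(2L), ac$a1)
  b2 <- conv_backward(sl(3L), ac$a2)
  b3 <- conv_backward(sl(4L), ac$a3)
  grads$decoder$aspp0 <- list(w = b0$gw, b = b0$gb)
  grads$decoder$aspp1 <- list(w = b1$gw, b = b1$gb)
  grads$decoder$aspp2 <- list(w = b2$gw, b = b2$gb)
  grads$decoder$aspp3 <- list(w = b3$gw, b = b3$gb)
  gx <- b0$gx + b1$gx + b2$gx + b3$gx
  for (s in rev(seq_along(bs$stages))) {
    sp <- model$params$backbone[[paste0("stage", s)]]
    scache <- caches$stages[[s]]
    sgrads <- list(blocks = vector("list", bs$stages[s]))
    for (b in rev(seq_len(bs$stages[s]))) {
      bb <- block_backward(gx, sp$blocks[[b]], scache$blocks[[b]],
                           bs$attn_config)
      sgrads$blocks[[b]] <- bb$grads
      gx <- bb$gx
    }
    names(sgrads$blocks) <- paste0("block", seq_along(sgrads$blocks))
    gt <- relu_backward(gx, scache$trans_mask)
    bt <- conv_backward(gt, scache$trans)
    sgrads$trans <- list(w = bt$gw, b = bt$gb)
    gx <- bt$gx
    grads$backbone[[paste0("stage", s)]] <- sgrads
  }
  gs <- relu_backward(gx, caches$stem_mask)
  bst <- conv_backward(gs, caches$stem)
  grads$backbone$stem <- list(w = bst$gw, b = bst$gb)
  grads$backbone <- grads$backbone[names(model$params$backbone)]
  grads
}

#' Run a segmentation model on an RGB image
#'
#' @param model a [build_segmodel()] model.
#' @param image `H x W x 3` array with values in `[0, 1]`.
#' @return logit array `H x W x K` at label resolution (coarse logits are
#'   bilinearly upsampled).
#' @export
forward_segment <- function(model, image) {
  stopifnot(inherits(model, "segmodel"))
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("expected an H x W x 3 RGB image")
  segmodel_forward(model, image)$logits
}
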