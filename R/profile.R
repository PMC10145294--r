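# Parameter accounting, FLOP estimation and checkpoint I/O.

# Flatten a nested parameter list to a flat named list of numeric arrays,
# names joined with ".": e.g. "backbone.stage1.blocks.1.attn.linear1.w".
flatten_params <- function(x, prefix = character()) {
  if (is.numeric(x)) {
    out <- list(x)
    names(out) <- paste(prefix, collapse = ".")
    return(out)
  }
  nm <- names(x)
  if (is.null(nm)) nm <- as.character(seq_along(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, flatten_params(x[[i]], c(prefix, nm[i])))
  out
}

# Write a flat named list of values back into the nested structure.
assign_flat <- function(params, flat) {
  for (nm in names(flat)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    params[[path]] <- flat[[nm]]
  }
  params
}

#' Count trainable parameters of a segmentation model
#'
#' @param model a `segmodel`.
#' @return total number of trainable scalars (weights and biases,
#'   including any inserted attention blocks).
#' @export
model_param_count <- function(model) {
  stopifnot(inherits(model, "segmodel"))
  sum(vapply(flatten_params(model$params), length, numeric(1)))
}

# Layer-by-layer layout of a model spec at a given input size; used by the
# FLOP estimator and the profiler.
segmodel_layout <- function(spec, input_size = c(64L, 64L)) {
  bs <- spec$backbone
  h <- input_size[1]; w <- input_size[2]
  rows <- list()
  add <- function(name, type, kh, kw, cin, cout, hin, win, stride = 1L,
                  rate = 1L) {
    pad <- conv_pad(kh, rate)
    ho <- conv_out_size(hin, kh, stride, rate, pad)
    wo <- conv_out_size(win, kw, stride, rate, pad)
    rows[[length(rows) + 1L]] <<- list(name = name, type = type, kh = kh,
                                       kw = kw, cin = cin, cout = cout,
                                       h = ho, w = wo, stride = stride,
                                       rate = rate)
    c(ho, wo)
  }
  hw <- add("stem", "conv", 3L, 3L, 3L, bs$widths[1], h, w, stride = 2L)
  for (s in seq_along(bs$stages)) {
    cin <- if (s == 1L) bs$widths[1] else bs$widths[s - 1L]
    cw <- bs$widths[s]
    hw <- add(paste0("stage", s, ".trans"), "conv", 3L, 3L, cin, cw,
              hw[1], hw[2], stride = 2L)
    for (b in seq_len(bs$stages[s])) {
      pre <- paste0("stage", s, ".block", b)
      if (bs$family == "resnet") {
        add(paste0(pre, ".conv1"), "conv", 3L, 3L, cw, cw, hw[1], hw[2])
        add(paste0(pre, ".conv2"), "conv", 3L, 3L, cw, cw, hw[1], hw[2])
      } else if (bs$family == "vgg") {
        add(paste0(pre, ".conv1"), "conv", 3L, 3L, cw, cw, hw[1], hw[2])
      } else {
        add(paste0(pre, ".conv1"), "conv", 1L, 1L, cw, 2L * cw, hw[1], hw[2])
        add(paste0(pre, ".conv2"), "conv", 3L, 3L, 2L * cw, 2L * cw,
            hw[1], hw[2])
        add(paste0(pre, ".conv3"), "conv", 1L, 1L, 2L * cw, cw, hw[1], hw[2])
      }
      if (has_attn(bs, s, b))
        rows[[length(rows) + 1L]] <- list(name = paste0(pre, ".attn"),
                                          type = "attn", kh = NA, kw = NA,
                                          cin = cw, cout = cw,
                                          h = hw[1], w = hw[2],
                                          stride = 1L, rate = 1L)
    }
  }
  cenc <- bs$widths[length(bs$widths)]
  dc <- spec$decoder_channels
  add("aspp0", "conv", 1L, 1L, cenc, dc, hw[1], hw[2])
  for (i in 1:3)
    add(paste0("aspp", i), "conv", 3L, 3L, cenc, dc, hw[1], hw[2],
        rate = spec$aspp_rates[i])
  add("project", "conv", 1L, 1L, 4L * dc, dc, hw[1], hw[2])
  add("classifier", "conv", 1L, 1L, dc, spec$num_classes, hw[1], hw[2])
  rows
}

#' Estimate the forward cost of a model spec in GFLOPs
#'
#' Multiply-accumulate based estimate (2 FLOPs per MAC) summed over all
#' convolutions and the attention blocks' linear layers and matrix
#' products; the global affinity of an attention block on an `h x w`
#' grid contributes `2 * (h*w)^2 * C'` FLOPs, and its aggregation the
#' same again.
#'
#' @param spec a [segmodel_spec()].
#' @param input_size integer `c(H, W)` the estimate refers to.
#' @return estimated GFLOPs (double).
#' @export
model_flops_estimate <- function(spec, input_size = c(224L, 224L)) {
  cfg <- spec$backbone$attn_config
  fl <- 0
  for (r in segmodel_layout(spec, input_size)) {
    if (r$type == "conv") {
      fl <- fl + 2 * r$kh * r$kw * r$cin * r$cout * r$h * r$w
    } else {
      hw <- r$h * r$w
      cp <- cfg$embed_dim; mh <- cfg$mlp_hidden
      fl <- fl + 2 * hw * r$cin * cp +        # projection
        2 * hw * cp * 3 * cp +                # query/key/value
        2 * hw^2 * cp +                       # affinity
        2 * hw^2 * cp +                       # aggregation
        2 * hw * cp * mh + 2 * hw * mh * cp   # MLP
    }
  }
  fl / 1e9
}

#' Profile a model spec
#'
#' @param spec a [segmodel_spec()].
#' @param input_size integer `c(H, W)`.
#' @return data.frame with parameter count, estimated GFLOPs at the given
#'   input size, encoder output stride, and the analytic receptive field
#'   after each encoder stage.
#' @export
profile_segmodel <- function(spec, input_size = c(224L, 224L)) {
  model <- build_segmodel(spec, seed = 1L)
  layers <- list(layer_spec(3L, stride = 2L))
  rf <- integer(0)
  for (s in seq_along(spec$backbone$stages)) {
    layers <- c(layers, list(layer_spec(3L, stride = 2L)))
    n_convs <- switch(spec$backbone$family, resnet = 2L, vgg = 1L,
                      mobilenet = 1L)  # 3x3 convs per block
    for (b in seq_len(spec$backbone$stages[s]))
      layers <- c(layers, replicate(n_convs, layer_spec(3L),
                                    simplify = FALSE))
    rf[s] <- receptive_field(layers)
  }
  data.frame(
    parameters = model_param_count(model),
    gflops = model_flops_estimate(spec, input_size),
    output_stride = spec$output_stride,
    stage = paste0("stage", seq_along(rf), ":rf=", rf) |>
      paste(collapse = " "),
    stringsAsFactors = FALSE)
}

# ---- checkpoints ---------------------------------------------------------

#' Save / load model checkpoints
#'
#' A checkpoint is a flat name-to-array mapping of every parameter.
#' [load_pretrained()] copies entries whose name and shape match into the
#' model and reports what was loaded and skipped; attention-block
#' parameters live under `.attn.` keys, so backbone-only checkpoints load
#' cleanly into attention-augmented models (the attention parameters stay
#' freshly initialised).
#'
#' @param model a `segmodel`.
#' @param path file path for the checkpoint.
#' @return `save_checkpoint` returns `path` invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(flatten_params(model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param checkpoint a path to a saved checkpoint or a named list of
#'   arrays.
#' @param strict if `TRUE`, any name or shape mismatch in either direction
#'   is an error.
#' @return `load_pretrained` returns a list with the updated `model` and
#'   character vectors `loaded` and `skipped`.
#' @export
load_pretrained <- function(model, checkpoint, strict = FALSE) {
  stopifnot(inherits(model, "segmodel"))
  ck <- if (is.character(checkpoint)) readRDS(checkpoint) else checkpoint
  own <- flatten_params(model$params)
  loaded <- character(0); skipped <- character(0)
  accepted <- list()
  for (nm in names(own)) {
    if (!is.null(ck[[nm]]) &&
        identical(dim2(ck[[nm]]), dim2(own[[nm]]))) {
      accepted[[nm]] <- ck[[nm]]
      loaded <- c(loaded, nm)
    } else {
      skipped <- c(skipped, nm)
    }
  }
  extra <- setdiff(names(ck), names(own))
  if (strict && (length(skipped) || length(extra)))
    stop("strict load failed; missing/mismatched: ",
         paste(utils::head(c(skipped, extra), 5L), collapse = ", "))
  model$params <- assign_flat(model$params, accepted)
  list(model = model, loaded = loaded, skipped = skipped)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)
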