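# Training orchestration: two-phase transfer-learning schedule
# (frozen backbone, then full fine-tuning), exponential learning-rate
# decay, optional channel-wise knowledge distillation from a frozen
# teacher, and per-epoch validation-mIoU tracking.

#' Training configuration
#'
#' The two-phase schedule freezes the backbone for the first
#' `freeze_epochs` epochs (only the decoder learns, larger batches), then
#' unfreezes the whole network (smaller batches).  The learning rate
#' starts at `lr0` and is multiplied by `lr_decay` every epoch.
#'
#' @param total_epochs total number of epochs (default 40).
#' @param freeze_epochs number of initial epochs with a frozen backbone
#'   (default 20); 0 disables the frozen phase.
#' @param lr0 initial learning rate (default 5e-4).
#' @param lr_decay per-epoch multiplicative decay (default 0.92).
#' @param batch_frozen batch size during the frozen phase (default 16).
#' @param batch_unfrozen batch size after unfreezing (default 4).
#' @param seed RNG seed controlling initialisation, shuffling and
#'   augmentation.
#' @param optimizer `"rmsprop"` (momentum-free adaptive updates) or
#'   `"sgd"`.
#' @param attn_lr_scale multiplier on the learning rate of attention-block
#'   parameters (default 1).  The attention branch multiplies features by
#'   a map produced from a chain of three learned matrix products, so its
#'   output scale reacts much more sharply to weight changes than a
#'   convolution's; a scale below 1 keeps it from destabilising short
#'   from-scratch runs.
#' @return a `train_config` object.
#' @export
train_config <- function(total_epochs = 40L, freeze_epochs = 20L,
                         lr0 = 5e-4, lr_decay = 0.92,
                         batch_frozen = 16L, batch_unfrozen = 4L,
                         seed = 1L, optimizer = c("rmsprop", "sgd"),
                         attn_lr_scale = 1) {
  optimizer <- match.arg(optimizer)
  stopifnot(total_epochs >= 1L, freeze_epochs >= 0L,
            freeze_epochs <= total_epochs, lr0 > 0,
            lr_decay > 0, lr_decay <= 1,
            batch_frozen >= 1L, batch_unfrozen >= 1L, attn_lr_scale > 0)
  structure(list(total_epochs = as.integer(total_epochs),
                 freeze_epochs = as.integer(freeze_epochs),
                 lr0 = lr0, lr_decay = lr_decay,
                 batch_frozen = as.integer(batch_frozen),
                 batch_unfrozen = as.integer(batch_unfrozen),
                 seed = as.integer(seed), optimizer = optimizer,
                 attn_lr_scale = attn_lr_scale),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' `lr0 * lr_decay^epoch` (epoch 0-based), a strictly decreasing sequence
#' for `lr_decay < 1`.
#'
#' @param epoch 0-based epoch index.
#' @param config a [train_config()].
#' @return learning rate.
#' @export
lr_at_epoch <- function(epoch, config = train_config()) {
  stopifnot(epoch >= 0)
  config$lr0 * config$lr_decay^epoch
}

#' Phase and batch size at a given epoch
#'
#' @inheritParams lr_at_epoch
#' @return list with `phase` (`"frozen"` or `"unfrozen"`) and
#'   `batch_size`.
#' @export
phase_of_epoch <- function(epoch, config = train_config()) {
  stopifnot(epoch >= 0)
  if (epoch < config$freeze_epochs)
    list(phase = "frozen", batch_size = config$batch_frozen)
  else
    list(phase = "unfrozen", batch_size = config$batch_unfrozen)
}

# ---- optimiser -----------------------------------------------------------

opt_init <- function() list(v = list())

# RMSprop (or plain SGD) over a flat named gradient list; `trainable`
# restricts which parameters move.
opt_update <- function(pflat, gflat, state, lr, optimizer, trainable,
                       attn_lr_scale = 1) {
  base_lr <- lr
  for (nm in trainable) {
    g <- gflat[[nm]]
    if (is.null(g)) next
    lr <- if (grepl(".attn.", nm, fixed = TRUE))
      base_lr * attn_lr_scale else base_lr
    if (optimizer == "rmsprop") {
      v <- state$v[[nm]]
      if (is.null(v)) v <- array(0, dim = dim2(g))
      v <- 0.9 * v + 0.1 * g^2
      state$v[[nm]] <- v
      pflat[[nm]] <- pflat[[nm]] - lr * g / (sqrt(v) + 1e-8)
    } else {
      pflat[[nm]] <- pflat[[nm]] - lr * g
    }
  }
  list(pflat = pflat, state = state)
}

# Sum two flat gradient lists (matching by name).
gflat_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

gflat_scale <- function(a, s) lapply(a, function(g) g * s)

# ---- single training step ------------------------------------------------

# Forward/backward over one batch of tiles; returns mean losses and the
# mean flat gradient.
batch_gradients <- function(model, tiles, teacher = NULL,
                            dconfig = NULL, teacher_logits = NULL,
                            class_weights = NULL) {
  gacc <- NULL
  ce_sum <- 0; kd_sum <- 0
  for (i in seq_along(tiles)) {
    t <- tiles[[i]]
    fw <- segmodel_forward(model, t$image, keep = TRUE)
    ce <- ce_loss_impl(fw$logits, t$mask, ignore_value = 255L,
                       weights = class_weights)
    glog <- ce$grad
    kd <- 0
    if ((!is.null(teacher) || !is.null(teacher_logits)) &&
        !is.null(dconfig) && dconfig$alpha > 0) {
      tlog <- if (!is.null(teacher_logits)) teacher_logits[[i]] else
        forward_segment(teacher, t$image)
      if (dim(tlog)[3] != dim(fw$logits)[3])
        stop("teacher and student class counts differ")
      kd <- kd_loss(tlog, fw$logits, dconfig$temperature)
      glog <- glog + dconfig$alpha *
        kd_loss_grad(tlog, fw$logits, dconfig$temperature)
    }
    grads <- segmodel_backward(glog, model, fw$cache)
    gacc <- gflat_add(gacc, flatten_params(grads))
    ce_sum <- ce_sum + ce$loss; kd_sum <- kd_sum + kd
  }
  n <- length(tiles)
  list(gflat = gflat_scale(gacc, 1 / n), ce = ce_sum / n, kd = kd_sum / n)
}

#' One knowledge-distillation training step
#'
#' Runs the frozen teacher and the student on a batch of tiles, combines
#' the cross-entropy and channel-wise distillation losses, and applies one
#' optimiser step to the student only.  The teacher is never modified.
#'
#' @param teacher trained `segmodel` (inference only).
#' @param student `segmodel` being trained.
#' @param tiles list of tiles (`image`, `mask`).
#' @param dconfig a [distill_config()].
#' @param lr learning rate for this step.
#' @param opt_state optimiser state from a previous call, or `NULL`.
#' @param optimizer `"rmsprop"` or `"sgd"`.
#' @return list with the updated `student`, `opt_state`, and `loss` (a
#'   `loss_breakdown`).
#' @export
distill_step <- function(teacher, student, tiles,
                         dconfig = distill_config(), lr = 5e-4,
                         opt_state = NULL, optimizer = "rmsprop") {
  bg <- batch_gradients(student, tiles, teacher = teacher,
                        dconfig = dconfig)
  pflat <- flatten_params(student$params)
  if (is.null(opt_state)) opt_state <- opt_init()
  up <- opt_update(pflat, bg$gflat, opt_state, lr, optimizer,
                   trainable = names(pflat))
  student$params <- assign_flat(student$params, up$pflat)
  list(student = student, opt_state = up$state,
       loss = total_loss(bg$ce, bg$kd, dconfig))
}

# ---- full training loop --------------------------------------------------

#' Train a segmentation model on a tile set
#'
#' Full two-phase schedule with exponential learning-rate decay, seeded
#' shuffling, light augmentation (random horizontal flips and colour
#' jitter), optional knowledge distillation from a frozen teacher, and
#' per-epoch validation mIoU.  The returned model is the one with the
#' highest validation mIoU (ties broken by the earlier epoch).
#'
#' @param spec a [segmodel_spec()] (a fresh model is built) or an existing
#'   `segmodel` to continue training.
#' @param tileset a [make_tileset()] tile set with train and val splits.
#' @param config a [train_config()].
#' @param dconfig optional [distill_config()]; requires `teacher`.
#' @param teacher optional trained `segmodel` used as the distillation
#'   teacher; its parameters are never modified.
#' @param augment logical; apply random flips/jitter to training tiles.
#' @param jitter colour-jitter amplitude used when `augment` is on.
#' @param class_weights `NULL` (unweighted CE), `"balanced"`
#'   (inverse-frequency weights computed from the training tiles,
#'   normalised to mean 1), or a numeric vector of K weights.
#' @param metrics_csv optional path; per-epoch metrics are appended as
#'   CSV.
#' @param verbose print one line per epoch.
#' @return list with `model` (best-validation parameters), `final_model`,
#'   and `metrics` (one row per epoch: epoch, phase, lr, train_ce,
#'   train_kd, train_total, val_miou).
#' @export
train_segmodel <- function(spec, tileset, config = train_config(),
                           dconfig = NULL, teacher = NULL,
                           augment = TRUE, jitter = 0.05,
                           class_weights = NULL,
                           metrics_csv = NULL, verbose = FALSE) {
  if (!is.null(dconfig) && is.null(teacher))
    stop("distillation requires a teacher model")
  train_tiles <- tileset_split(tileset, "train")
  val_tiles <- tileset_split(tileset, "val")
  if (length(train_tiles) == 0L) stop("tile set has no training tiles")
  model <- if (inherits(spec, "segmodel")) spec else
    build_segmodel(spec, seed = config$seed)
  k <- model$spec$num_classes
  if (any(vapply(train_tiles, function(t) max(t$mask), 0) >= k))
    stop("tile labels exceed the model's class count")
  if (!is.null(teacher) && teacher$spec$num_classes != k)
    stop("teacher and student class counts differ")
  if (identical(class_weights, "balanced")) {
    counts <- rep(0, k)
    for (t in train_tiles) {
      tb <- tabulate(t$mask + 1L, nbins = k)
      counts <- counts + tb
    }
    w <- ifelse(counts > 0, 1 / pmax(counts, 1), 0)
    class_weights <- w / mean(w[counts > 0])
  }

  # with augmentation off the frozen teacher sees each tile unchanged every
  # epoch, so its logits can be computed once
  tlogit_cache <- NULL
  if (!is.null(teacher) && !augment && !is.null(dconfig) &&
      dconfig$alpha > 0)
    tlogit_cache <- lapply(train_tiles, function(t)
      forward_segment(teacher, t$image))

  set.seed(config$seed)
  opt_state <- opt_init()
  pnames <- names(flatten_params(model$params))
  decoder_names <- grep("^decoder\\.", pnames, value = TRUE)
  metrics <- NULL
  best <- list(miou = -Inf, epoch = NA_integer_, params = model$params)

  for (e in seq_len(config$total_epochs) - 1L) {
    ph <- phase_of_epoch(e, config)
    lr <- lr_at_epoch(e, config)
    trainable <- if (ph$phase == "frozen") decoder_names else pnames
    idx <- sample(length(train_tiles))
    ce_e <- 0; kd_e <- 0; nb <- 0L
    for (start in seq(1L, length(idx), by = ph$batch_size)) {
      take <- idx[start:min(start + ph$batch_size - 1L, length(idx))]
      tiles <- train_tiles[take]
      if (augment)
        tiles <- lapply(tiles, function(t)
          augment_tile(t, flip = stats::runif(1) < 0.5, jitter = jitter))
      bg <- batch_gradients(model, tiles, teacher = teacher,
                            dconfig = dconfig,
                            teacher_logits = if (!is.null(tlogit_cache))
                              tlogit_cache[take],
                            class_weights = class_weights)
      if (ph$phase == "frozen")
        bg$gflat[setdiff(pnames, decoder_names)] <- NULL
      pflat <- flatten_params(model$params)
      up <- opt_update(pflat, bg$gflat, opt_state, lr, config$optimizer,
                       trainable, attn_lr_scale = config$attn_lr_scale)
      opt_state <- up$state
      model$params <- assign_flat(model$params, up$pflat)
      ce_e <- ce_e + bg$ce; kd_e <- kd_e + bg$kd; nb <- nb + 1L
    }
    vm <- if (length(val_tiles))
      evaluate_tiles(model, val_tiles, num_classes = k)$miou else NA_real_
    alpha <- if (is.null(dconfig)) 0 else dconfig$alpha
    row <- data.frame(epoch = e, phase = ph$phase, lr = lr,
                      train_ce = ce_e / nb, train_kd = kd_e / nb,
                      train_total = (ce_e + alpha * kd_e) / nb,
                      val_miou = vm)
    metrics <- rbind(metrics, row)
    if (!is.na(vm) && vm > best$miou) {
      best <- list(miou = vm, epoch = e, params = model$params)
    }
    if (verbose)
      message(sprintf("epoch %2d [%s] lr=%.2e ce=%.4f kd=%.4f val_miou=%.4f",
                      e, ph$phase, lr, row$train_ce, row$train_kd, vm))
  }
  if (!is.null(metrics_csv))
    utils::write.csv(metrics, metrics_csv, row.names = FALSE)
  best_model <- model
  if (!is.infinite(best$miou)) best_model$params <- best$params
  list(model = best_model, final_model = model, metrics = metrics,
       best_epoch = best$epoch)
}
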