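# Training objectives: per-pixel cross-entropy, and channel-wise knowledge
# distillation with a temperature softmax.
#
# The two losses deliberately normalise over different axes.  The CE loss
# uses the conventional per-pixel softmax over the K classes.  The KD loss
# is channel-wise: each output channel is turned into a probability
# distribution over its H*W spatial positions with a temperature-T softmax,
# and the student's spatial distribution is pulled towards the teacher's
# with a KL divergence, scaled by T^2/C to compensate the 1/T^2 gradient
# shrinkage the temperature introduces.

#' Distillation configuration
#'
#' @param temperature softmax temperature T > 0; values above 1 soften the
#'   spatial distributions so inter-position similarity structure carries
#'   gradient signal. Default 4.
#' @param alpha weight of the KD term in the total loss
#'   `total = ce + alpha * kd`. Default 3.
#' @return a `distill_config` object.
#' @export
distill_config <- function(temperature = 4, alpha = 3) {
  stopifnot(temperature > 0, alpha >= 0)
  structure(list(temperature = temperature, alpha = alpha),
            class = "distill_config")
}

#' Temperature softmax over a channel's spatial positions
#'
#' `theta_i = exp(y_i / T) / sum_j exp(y_j / T)`, computed with
#' max-subtraction for numerical stability.
#'
#' @param y numeric vector of logits (one channel, flattened over space).
#' @param temperature T > 0.
#' @return probability vector summing to 1.
#' @export
channel_softmax <- function(y, temperature = 1) {
  if (temperature <= 0) stop("temperature must be positive")
  stopifnot(all(is.finite(y)))
  z <- y / temperature
  e <- exp(z - max(z))
  e / sum(e)
}

# Column-wise temperature softmax of an (H*W) x C logit matrix.
softmax_cols <- function(m, temperature) {
  z <- m / temperature
  z <- sweep(z, 2L, apply(z, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

#' Channel-wise knowledge-distillation loss
#'
#' `(T^2 / C) * sum_c KL(theta(Y_teacher[,,c] / T) || theta(Y_student[,,c] / T))`
#' where `theta` is the temperature softmax over the H*W spatial positions
#' of channel c.  Probabilities are floored at 1e-12 inside the logarithm.
#' The teacher distribution is a constant w.r.t. the student.
#'
#' @param teacher,student logit arrays `H x W x C` (identical shapes).
#' @param temperature softmax temperature T > 0.
#' @return nonnegative scalar loss; 0 iff the per-channel spatial
#'   distributions coincide.
#' @export
kd_loss <- function(teacher, student, temperature = 4) {
  if (!identical(dim(teacher), dim(student)))
    stop("teacher and student logit shapes differ")
  if (temperature <= 0) stop("temperature must be positive")
  d <- dim(teacher)
  k <- d[3]
  tm <- matrix(teacher, ncol = k)
  sm <- matrix(student, ncol = k)
  pt <- softmax_cols(tm, temperature)
  ps <- softmax_cols(sm, temperature)
  kl <- sum(pt * (log(pmax(pt, 1e-12)) - log(pmax(ps, 1e-12))))
  max(temperature^2 / k * kl, 0)
}

# Gradient of kd_loss w.r.t. the student logits.
kd_loss_grad <- function(teacher, student, temperature = 4) {
  d <- dim(teacher)
  k <- d[3]
  pt <- softmax_cols(matrix(teacher, ncol = k), temperature)
  ps <- softmax_cols(matrix(student, ncol = k), temperature)
  array((temperature / k) * (ps - pt), dim = d)
}

#' Per-pixel cross-entropy loss for segmentation logits
#'
#' Mean over scored pixels of the negative log-probability of the true
#' class under the per-pixel class softmax.  Pixels labelled
#' `ignore_value` are excluded.  Optional per-class weights turn the mean
#' into a weighted mean (weight of each pixel = weight of its true
#' class), the standard remedy for rare classes in segmentation.
#'
#' @param logits array `H x W x K`.
#' @param labels integer matrix `H x W` with values in `0:(K-1)` or
#'   `ignore_value`.
#' @param ignore_value label treated as unscored (default 255).
#' @param weights optional numeric vector of K per-class weights.
#' @return nonnegative scalar loss.
#' @export
ce_loss <- function(logits, labels, ignore_value = 255L, weights = NULL) {
  ce_loss_impl(logits, labels, ignore_value, weights)$loss
}

ce_loss_impl <- function(logits, labels, ignore_value, weights = NULL) {
  d <- dim(logits)
  if (!identical(dim(labels), d[1:2]))
    stop("labels must match the logit spatial dimensions")
  k <- d[3]
  lab <- as.integer(labels)
  scored <- lab != ignore_value
  if (any(scored & (lab < 0L | lab >= k)))
    stop("label out of range [0, K)")
  lm <- matrix(logits, ncol = k)            # pixels x classes
  mx <- lm[, 1L]
  for (j in seq_len(k)[-1L]) mx <- pmax(mx, lm[, j])
  e <- exp(lm - mx)
  p <- e / rowSums(e)
  n <- sum(scored)
  if (n == 0L) return(list(loss = 0, grad = array(0, dim = d)))
  idx <- cbind(which(scored), lab[scored] + 1L)
  if (is.null(weights)) {
    pixw <- rep(1, n)
  } else {
    stopifnot(length(weights) == k, all(weights >= 0))
    pixw <- weights[lab[scored] + 1L]
  }
  wsum <- sum(pixw)
  loss <- -sum(pixw * log(pmax(p[idx], 1e-12))) / wsum
  onehot <- matrix(0, nrow = nrow(lm), ncol = k)
  onehot[idx] <- 1
  g <- p - onehot
  g[!scored, ] <- 0
  g[scored, ] <- g[scored, , drop = FALSE] * (pixw / wsum)
  list(loss = loss, grad = array(g, dim = d))
}

#' Combine cross-entropy and distillation losses
#'
#' @param ce cross-entropy loss value.
#' @param kd distillation loss value.
#' @param config a [distill_config()].
#' @return a `loss_breakdown` list with `ce`, `kd`, `alpha` and
#'   `total = ce + alpha * kd`.
#' @export
total_loss <- function(ce, kd, config = distill_config()) {
  structure(list(ce = ce, kd = kd, alpha = config$alpha,
                 total = ce + config$alpha * kd),
            class = "loss_breakdown")
}
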