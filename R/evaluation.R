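# Segmentation evaluation: confusion-matrix accumulation and mean
# intersection over union.

#' Accumulate a confusion matrix from prediction and truth masks
#'
#' `counts[t, p]` is the number of pixels with ground-truth class t and
#' predicted class p (both 0-based classes; row/column 1 is class 0).
#' Matrices from different tiles/batches add: `cm_total = cm1 + cm2`.
#'
#' @param pred,truth integer matrices of equal shape with values in
#'   `0:(K-1)` or `ignore_value`.
#' @param num_classes K.
#' @param ignore_value pixels with this truth value are not scored
#'   (default 255).
#' @return `K x K` integer matrix of class `confusion_matrix`.
#' @export
accumulate_confusion <- function(pred, truth, num_classes,
                                 ignore_value = 255L) {
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and truth shapes differ")
  p <- as.integer(pred); t <- as.integer(truth)
  keep <- t != ignore_value & p != ignore_value
  p <- p[keep]; t <- t[keep]
  if (any(p < 0L | p >= num_classes) || any(t < 0L | t >= num_classes))
    stop("class index out of range [0, ", num_classes, ")")
  cm <- matrix(0L, num_classes, num_classes)
  tab <- table(factor(t, levels = 0:(num_classes - 1L)),
               factor(p, levels = 0:(num_classes - 1L)))
  cm[] <- as.integer(tab)
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Mean intersection over union
#'
#' Per-class IoU is `counts[c, c] / (row_c + col_c - counts[c, c])`
#' (true positives over the union of prediction and truth).  Classes with
#' an empty union (absent from both prediction and truth) are excluded
#' from the mean rather than scored, so tiles lacking a class are not
#' penalised; `include_background = FALSE` additionally drops class 0.
#'
#' @param cm a `K x K` confusion matrix (rows = truth, columns =
#'   prediction).
#' @param include_background include class 0 in the mean (default TRUE).
#' @return mIoU in `[0, 1]`.
#' @export
miou <- function(cm, include_background = TRUE) {
  ious <- class_iou(cm)
  if (!include_background && length(ious) > 1L) ious <- ious[-1L]
  ious <- ious[!is.na(ious)]
  if (length(ious) == 0L) stop("confusion matrix has no scored class")
  mean(ious)
}

#' @rdname miou
#' @return `class_iou` returns the per-class IoU vector, `NA` for classes
#'   with an empty union.
#' @export
class_iou <- function(cm) {
  cm <- unclass(cm)
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  if (sum(cm) == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  union <- rowSums(cm) + colSums(cm) - tp
  ifelse(union > 0, tp / union, NA_real_)
}

#' Pixel accuracy from a confusion matrix
#'
#' @inheritParams miou
#' @return fraction of scored pixels predicted correctly.
#' @export
pixel_accuracy <- function(cm) {
  cm <- unclass(cm)
  if (sum(cm) == 0) stop("empty confusion matrix")
  sum(diag(cm)) / sum(cm)
}

# Class prediction from a logit map: per-pixel argmax over K (0-based).
logits_to_mask <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, ncol = d[3])
  matrix(max.col(m, ties.method = "first") - 1L, d[1], d[2])
}

#' Evaluate a model over the tiles of one split
#'
#' @param model a `segmodel`.
#' @param tiles list of tiles (`image`, `mask`).
#' @param num_classes K.
#' @param include_background passed to [miou()].
#' @return list with `confusion`, `per_class_iou`, `miou`,
#'   `pixel_accuracy`.
#' @export
evaluate_tiles <- function(model, tiles, num_classes = 3L,
                           include_background = TRUE) {
  cm <- matrix(0L, num_classes, num_classes)
  for (t in tiles) {
    pred <- logits_to_mask(forward_segment(model, t$image))
    cm <- cm + accumulate_confusion(pred, t$mask, num_classes)
  }
  cm <- structure(cm, class = c("confusion_matrix", "matrix"))
  list(confusion = cm, per_class_iou = class_iou(cm),
       miou = miou(cm, include_background),
       pixel_accuracy = pixel_accuracy(cm))
}
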