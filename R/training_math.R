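#' Inverse-power class weights
#'
#' Computes the per-class loss weights \eqn{w_i = 1 / p_i^{x}} from the
#' proportional share \eqn{p_i} of each class in the training data. The
#' exponent \eqn{x} interpolates between no weighting (\eqn{x = 0}, all
#' weights 1) and full inverse-frequency weighting (\eqn{x = 1}); classes
#' absent from the training data (\eqn{p_i = 0}) get weight 0 and are thereby
#' excluded from the loss.
#'
#' @param p numeric vector of class proportions (non-negative, summing to 1).
#' @param x weighting exponent, a scalar >= 0.
#' @return a `class_weight_table` data frame with columns `p`, `w` and
#'   `absent`, and the exponent stored as attribute `x`.
#' @export
compute_class_weights <- function(p, x) {
  stopifnot_scalar(x, "x")
  if (x < 0) stop("weight exponent 'x' must be >= 0", call. = FALSE)
  if (any(p < 0)) stop("class proportions must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6)
    stop(sprintf("class proportions must sum to 1 (got %.8f)", sum(p)),
         call. = FALSE)
  w <- ifelse(p > 0, p^(-x), 0)
  structure(data.frame(p = as.numeric(p), w = w, absent = p == 0),
            x = x, class = c("class_weight_table", "data.frame"))
}

#' Weighted categorical cross-entropy
#'
#' Mean over pixels of \eqn{w_{c} \cdot (-\log \hat p_{c})}, where \eqn{c} is
#' the true class of the pixel and \eqn{\hat p_c} the predicted probability
#' for it, clipped below at 1e-7 before the logarithm. With all weights 1 this
#' reduces to the unweighted categorical cross-entropy.
#'
#' @param pred_probs predicted per-pixel class distribution: an N x K matrix
#'   or H x W x K array with rows summing to 1.
#' @param truth one-hot ground truth of the same shape.
#' @param weights a [compute_class_weights()] table (or bare numeric vector)
#'   of length K.
#' @return scalar loss, non-negative; 0 iff the prediction equals the truth.
#' @export
weighted_cce <- function(pred_probs, truth, weights) {
  w <- if (inherits(weights, "class_weight_table")) weights$w
       else as.numeric(weights)
  pm <- if (length(dim(pred_probs)) == 3L)
    matrix(pred_probs, prod(dim(pred_probs)[1:2]), dim(pred_probs)[3])
  else as.matrix(pred_probs)
  tm <- if (length(dim(truth)) == 3L)
    matrix(truth, prod(dim(truth)[1:2]), dim(truth)[3]) else as.matrix(truth)
  if (!all(dim(pm) == dim(tm)) || ncol(pm) != length(w))
    stop("prediction, truth and weights shapes are inconsistent",
         call. = FALSE)
  pc <- rowSums(pm * tm)
  wc <- as.vector(tm %*% w)
  mean(wc * -log(pmax(pc, 1e-7)))
}

#' Mean intersection over union of two class-id masks
#'
#' For each class \eqn{i}, \eqn{O_i} is the intersection (true positives) of
#' the predicted and true pixel sets and \eqn{U_i} their union
#' (TP + FP + FN); mIoU is the mean of \eqn{O_i / U_i} over the classes with
#' a non-empty union (classes absent from both masks are excluded).
#'
#' @param truth,pred co-registered integer masks with values in
#'   `[0, n_classes)`.
#' @param n_classes number of classes.
#' @return mIoU in `[0, 1]`.
#' @seealso [miou_from_cm()] for the same metric computed from a confusion
#'   matrix (an independent code path used for cross-checks).
#' @export
miou <- function(truth, pred, n_classes) {
  if (!all(dim(truth) == dim(pred)))
    stop("masks are not co-registered", call. = FALSE)
  check_mask_range(truth, n_classes)
  check_mask_range(pred, n_classes)
  ious <- vapply(seq_len(n_classes) - 1L, function(i) {
    ti <- truth == i; pi <- pred == i
    u <- sum(ti | pi)
    if (u == 0) NA_real_ else sum(ti & pi) / u
  }, numeric(1))
  if (all(is.na(ious)))
    stop("no class present in either mask", call. = FALSE)
  mean(ious, na.rm = TRUE)
}

#' mIoU from a confusion matrix
#' @param cm confusion matrix (rows = truth, columns = prediction).
#' @return mIoU in `[0, 1]`.
#' @export
miou_from_cm <- function(cm) {
  tp <- diag(cm)
  u <- rowSums(cm) + colSums(cm) - tp
  keep <- u > 0
  if (!any(keep)) stop("empty confusion matrix", call. = FALSE)
  mean(tp[keep] / u[keep])
}

check_mask_range <- function(mask, n_classes) {
  v <- as.vector(mask)
  if (any(v < 0L | v >= n_classes | v != round(v)))
    stop(sprintf("mask values must be integers in [0, %d)", n_classes),
         call. = FALSE)
  invisible(TRUE)
}
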