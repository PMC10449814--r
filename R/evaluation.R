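#' Confusion matrix of two class-id masks
#'
#' Entry (i, j) counts the pixels with true class i and predicted class j
#' (rows = truth, columns = prediction; a plotted matrix may transpose this).
#'
#' @param truth,pred co-registered integer masks with values in
#'   `[0, n_classes)`.
#' @param n_classes number of classes.
#' @return `n_classes` x `n_classes` integer matrix, dimnames set to the
#'   class indices.
#' @export
confusion_matrix <- function(truth, pred, n_classes) {
  if (!all(dim(truth) == dim(pred)))
    stop("masks are not co-registered", call. = FALSE)
  check_mask_range(truth, n_classes)
  check_mask_range(pred, n_classes)
  idx <- as.vector(truth) * n_classes + as.vector(pred) + 1L
  cm <- matrix(tabulate(idx, nbins = n_classes^2), n_classes, n_classes,
               byrow = TRUE)
  dimnames(cm) <- list(truth = seq_len(n_classes) - 1L,
                       prediction = seq_len(n_classes) - 1L)
  cm
}

#' Per-class precision, recall and F1
#'
#' \eqn{P_i = cm_{ii} / \sum_j cm_{ji}} (column sum),
#' \eqn{R_i = cm_{ii} / \sum_j cm_{ij}} (row sum),
#' \eqn{F1_i = 2 P_i R_i / (P_i + R_i)}. Any 0/0 is defined as 0 and flagged
#' in the `degenerate` column.
#'
#' @param cm confusion matrix (rows = truth, columns = prediction).
#' @return data frame with columns `class`, `precision`, `recall`, `f1`,
#'   `degenerate`.
#' @export
per_class_prf <- function(cm) {
  tp <- diag(cm)
  colsum <- colSums(cm)
  rowsum <- rowSums(cm)
  safe_div <- function(a, b) ifelse(b > 0, a / ifelse(b > 0, b, 1), 0)
  p <- safe_div(tp, colsum)
  r <- safe_div(tp, rowsum)
  f1 <- safe_div(2 * p * r, p + r)
  data.frame(class = seq_len(nrow(cm)) - 1L, precision = p, recall = r,
             f1 = f1, degenerate = colsum == 0 | rowsum == 0,
             row.names = NULL)
}

#' Summary accuracy metrics from a confusion matrix
#'
#' Mean F1 (unweighted over the report set of classes), overall accuracy
#' (trace / total), Cohen's kappa with chance agreement
#' \eqn{p_e = \sum_i rowsum_i \cdot colsum_i / total^2}, and mIoU. Mean F1
#' averages over all classes by default; set `exclude_class` to drop the
#' background class from the mean.
#'
#' @param cm confusion matrix (rows = truth, columns = prediction).
#' @param exclude_class optional class index (0-based) excluded from mean F1.
#' @return a `metrics_report` list: `per_class`, `mean_f1`,
#'   `overall_accuracy`, `kappa`, `miou`.
#' @export
summary_metrics <- function(cm, exclude_class = NULL) {
  total <- sum(cm)
  if (total == 0) stop("confusion matrix has no counts", call. = FALSE)
  prf <- per_class_prf(cm)
  keep <- rep(TRUE, nrow(prf))
  if (!is.null(exclude_class)) keep[prf$class %in% exclude_class] <- FALSE
  oa <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- if (pe < 1) (oa - pe) / (1 - pe) else 1
  structure(list(per_class = prf, mean_f1 = mean(prf$f1[keep]),
                 overall_accuracy = oa, kappa = kappa,
                 miou = miou_from_cm(cm)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> mean F1 %.3f | OA %.3f | kappa %.3f | mIoU %.3f\n",
    x$mean_f1, x$overall_accuracy, x$kappa, x$miou))
  invisible(x)
}

#' Export a metrics report as CSV (per-class rows plus summary rows)
#' @param report a `metrics_report`.
#' @param path output file.
#' @export
write_metrics_report <- function(report, path) {
  pc <- report$per_class
  pc$metric <- "class"
  summary_rows <- data.frame(
    class = NA_integer_, precision = NA_real_, recall = NA_real_,
    f1 = c(report$mean_f1, report$overall_accuracy, report$kappa,
           report$miou),
    degenerate = FALSE,
    metric = c("mean_f1", "overall_accuracy", "kappa", "miou"))
  write.csv(rbind(pc, summary_rows), path, row.names = FALSE)
  invisible(path)
}

#' Paired t-test on per-class F1 vectors of two model configurations
#'
#' @param f1_a,f1_b equal-length paired per-class F1 vectors (n >= 3).
#' @return list with `t`, `p_value`, `df` (= n - 1), `mean_diff`.
#' @export
paired_f1_test <- function(f1_a, f1_b) {
  if (length(f1_a) != length(f1_b))
    stop("paired vectors must have equal length", call. = FALSE)
  if (length(f1_a) < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- f1_a - f1_b
  if (sd(d) <= 1e-12 * max(1, abs(mean(d))))
    stop("differences have zero variance; paired t-test is degenerate",
         call. = FALSE)
  tt <- tryCatch(t.test(f1_a, f1_b, paired = TRUE), error = function(e)
    stop("differences have zero variance; paired t-test is degenerate",
         call. = FALSE))
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d))
}
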