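#' Binary DE call per gene
#'
#' A gene is called DE when it passed the screening stage (adjusted
#' p-value at most `alpha`) and its final-model deviance R-squared is at
#' least `rsq_threshold` (boundary-equal genes are kept). Genes with `NA`
#' R-squared (screened out or non-convergent) are never called.
#'
#' @param results a result table from [run_trajectory_de()].
#' @param alpha screening significance level (default 0.05).
#' @param rsq_threshold R-squared gate (default 0.6).
#' @return logical vector, one call per gene.
#' @export
classify_genes <- function(results, alpha = 0.05, rsq_threshold = 0.6) {
  !is.na(results$adjusted_p) & results$adjusted_p <= alpha &
    !is.na(results$r_squared) & results$r_squared >= rsq_threshold
}

#' Confusion metrics for a set of calls
#'
#' @param calls logical calls per gene.
#' @param truth logical ground-truth DE labels, same length.
#' @return one-row data.frame with TP/FP/TN/FN counts, TPR, FPR, accuracy
#'   and F1 (0 when precision + recall is 0; TPR is `NA` when the truth
#'   has no positives).
#' @export
confusion_metrics <- function(calls, truth) {
  stopifnot(length(calls) == length(truth))
  calls <- as.logical(calls); truth <- as.logical(truth)
  tp <- sum(calls & truth); fp <- sum(calls & !truth)
  fn <- sum(!calls & truth); tn <- sum(!calls & !truth)
  tpr <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  fpr <- if (fp + tn == 0) NA_real_ else fp / (fp + tn)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (is.na(tpr)) 0 else tpr
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  data.frame(TP = tp, FP = fp, TN = tn, FN = fn, TPR = tpr, FPR = fpr,
             accuracy = (tp + tn) / length(calls), F1 = f1)
}

#' ROC over the R-squared threshold grid
#'
#' Sweeps the R-squared gate from 0.10 to 0.95 in steps of 0.05 (18
#' points), classifying genes at each threshold and computing confusion
#' metrics against the truth. TPR and FPR are non-increasing along the
#' grid since stricter gates can only remove calls.
#'
#' @param results a result table from [run_trajectory_de()].
#' @param truth logical ground-truth labels, one per gene.
#' @param alpha screening significance level used in the calls.
#' @return data.frame with one row per threshold.
#' @export
roc_over_rsq <- function(results, truth, alpha = 0.05) {
  grid <- seq(0.10, 0.95, by = 0.05)
  out <- do.call(rbind, lapply(grid, function(thr) {
    cm <- confusion_metrics(classify_genes(results, alpha, thr), truth)
    cbind(data.frame(rsq_threshold = thr), cm)
  }))
  rownames(out) <- NULL
  out
}

#' Ranking p-values under the filtered-gene convention
#'
#' For rank-based comparisons across methods, genes that fail the
#' screening stage or the R-squared gate are assigned a p-value of 1;
#' genes passing both keep their screening p-value. This makes filtered
#' genes sort last without discarding them.
#'
#' @param results a result table from [run_trajectory_de()].
#' @param rsq_threshold R-squared gate (default 0.6; boundary-equal genes
#'   keep their p-value).
#' @param alpha screening significance level (default 0.05).
#' @return data.frame with `gene` and exported `p_value`.
#' @export
export_ranking <- function(results, rsq_threshold = 0.6, alpha = 0.05) {
  pass <- classify_genes(results, alpha, rsq_threshold)
  p <- ifelse(pass, results$p_value, 1)
  data.frame(gene = results$gene, p_value = p, stringsAsFactors = FALSE)
}
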