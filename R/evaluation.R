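# Evaluation metrics: ROC AUC (Mann-Whitney), balanced accuracy,
# sensitivity/specificity/FPR; per-structure and pooled reporting.

#' Area under the ROC curve
#'
#' Mann-Whitney rank statistic; tied scores contribute 1/2.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (logical or 0/1).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.logical(labels)
  if (length(unique(y)) < 2) stop("labels are single-class")
  r <- rank(scores)
  n1 <- sum(y); n0 <- sum(!y)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold-based classification metrics
#'
#' A score `>= threshold` is a positive call (ties positive).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param threshold Decision cutoff.
#' @return An `eval_metrics` list: `auc`, `ba`, `sensitivity`,
#'   `specificity`, `fpr`, `n_pos`, `n_neg`, `threshold`.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  y <- as.logical(labels)
  if (length(unique(y)) < 2) stop("labels are single-class")
  call <- scores >= threshold
  sens <- mean(call[y])
  spec <- mean(!call[!y])
  structure(
    list(auc = roc_auc(scores, y), ba = (sens + spec) / 2,
         sensitivity = sens, specificity = spec, fpr = 1 - spec,
         n_pos = sum(y), n_neg = sum(!y), threshold = threshold),
    class = "eval_metrics"
  )
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "AUC %.3f | BA %.3f | sens %.3f | spec %.3f | FPR %.3f (n+ %d, n- %d)\n",
    x$auc, x$ba, x$sensitivity, x$specificity, x$fpr, x$n_pos, x$n_neg))
  invisible(x)
}

#' Evaluate predictions over a corpus
#'
#' Produces a per-structure metrics table and residue-pooled metrics.
#' Structures whose surface labels are single-class get `NA` rows and are
#' excluded from per-structure averaging (but their residues still enter
#' the pooled metrics).
#'
#' @param predictions List of `prediction_result` tables.
#' @param labelings List of matching `epitope_labeling`s (same order and
#'   structure keys).
#' @param threshold Cutoff for the confusion metrics; defaults to each
#'   prediction's own threshold attribute.
#' @return List with `per_structure` (data.table) and `pooled`
#'   (`eval_metrics`).
#' @export
evaluate_corpus <- function(predictions, labelings, threshold = NULL) {
  if (length(predictions) != length(labelings)) {
    stop("predictions/labelings length mismatch")
  }
  rows <- list(); sc_all <- list(); lb_all <- list()
  for (q in seq_along(predictions)) {
    pred <- predictions[[q]]
    lab <- labelings[[q]]
    pk <- attr(pred, "structure_key")
    if (!is.null(pk) && !identical(unname(pk),
                                   unname(lab$structure_key))) {
      stop(sprintf("structure key mismatch at entry %d", q))
    }
    th <- if (is.null(threshold)) attr(pred, "threshold") else threshold
    surf <- which(pred$is_surface)
    sc <- pred$adjusted_score[surf]
    lb <- lab$labels[surf]
    sc_all[[q]] <- sc; lb_all[[q]] <- lb
    key <- paste(pk[1], pk[2], sep = "_")
    if (length(unique(lb)) < 2) {
      rows[[q]] <- data.table(structure = key, auc = NA_real_,
                              ba = NA_real_, sensitivity = NA_real_,
                              specificity = NA_real_, fpr = NA_real_,
                              n_pos = sum(lb), n_neg = sum(!lb))
    } else {
      m <- confusion_metrics(sc, lb, th)
      rows[[q]] <- data.table(structure = key, auc = m$auc, ba = m$ba,
                              sensitivity = m$sensitivity,
                              specificity = m$specificity, fpr = m$fpr,
                              n_pos = m$n_pos, n_neg = m$n_neg)
    }
  }
  th0 <- if (is.null(threshold)) attr(predictions[[1]], "threshold") else
    threshold
  pooled <- confusion_metrics(unlist(sc_all), unlist(lb_all), th0)
  list(per_structure = rbindlist(rows), pooled = pooled)
}
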