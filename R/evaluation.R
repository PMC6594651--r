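# Threshold metrics (sensitivity, specificity, precision, accuracy, F1) and
# threshold-free curves (trapezoidal ROC AUC, step-wise PR AUPR).

#' Confusion counts at a threshold
#'
#' A pair is called positive iff `score >= threshold` (boundary counts as
#' positive, one fixed convention).
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels, same length, non-empty.
#' @param threshold Finite classification threshold.
#' @return A `confusion_counts` list: `tp`, `fp`, `tn`, `fn`, `p` (= tp+fn),
#'   `n` (= tn+fp).
#' @export
confusion <- function(scores, labels, threshold) {
  if (length(scores) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(scores) == length(labels), is.finite(threshold))
  assert_binary_labels(labels)
  calls <- scores >= threshold
  tp <- sum(calls & labels == 1)
  fp <- sum(calls & labels == 0)
  tn <- sum(!calls & labels == 0)
  fn <- sum(!calls & labels == 1)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 p = tp + fn, n = tn + fp),
            class = "confusion_counts")
}

#' Threshold classification metrics from confusion counts
#'
#' Computes sensitivity `TP/P`, specificity `TN/N`, precision
#' `TP/(TP+FP)`, accuracy `(TP+TN)/(P+N)`, and two F1 variants:
#' `f1_standard = 2*Sen*Pre/(Sen+Pre)` (the conventional harmonic mean,
#' the headline value) and `f1_paper = Sen*Pre/(Sen+Pre)` (the same ratio
#' without the factor 2, as some sources print it; it maxes at 0.5 and
#' always equals `f1_standard / 2`). Metrics whose denominator is zero are
#' reported as `NA` with the reason in the `undefined` attribute — never
#' as 0.
#'
#' @param counts A [confusion()] result, or numeric scores (then `labels`
#'   and `threshold` are required).
#' @param labels,threshold Used when `counts` is a score vector.
#' @return One-row tibble with columns `sen`, `spe`, `pre`, `acc`,
#'   `f1_standard`, `f1_paper`; attribute `undefined` names any metric
#'   that could not be computed and why.
#' @export
dti_metrics <- function(counts, labels = NULL, threshold = NULL) {
  if (!inherits(counts, "confusion_counts")) {
    counts <- confusion(counts, labels, threshold)
  }
  undefined <- character()
  sen <- if (counts$p > 0) counts$tp / counts$p else {
    undefined["sen"] <- "no positive pairs (P = 0)"; NA_real_
  }
  spe <- if (counts$n > 0) counts$tn / counts$n else {
    undefined["spe"] <- "no negative pairs (N = 0)"; NA_real_
  }
  pre <- if (counts$tp + counts$fp > 0) counts$tp / (counts$tp + counts$fp) else {
    undefined["pre"] <- "no positive calls (TP + FP = 0)"; NA_real_
  }
  acc <- (counts$tp + counts$tn) / (counts$p + counts$n)
  f1s <- if (!is.na(sen) && !is.na(pre) && sen + pre > 0) {
    2 * sen * pre / (sen + pre)
  } else {
    undefined["f1_standard"] <- "sensitivity/precision undefined or both zero"
    NA_real_
  }
  out <- tibble::tibble(sen = sen, spe = spe, pre = pre, acc = acc,
                        f1_standard = f1s, f1_paper = f1s / 2)
  attr(out, "undefined") <- undefined
  out
}

#' Area under the ROC curve (trapezoidal)
#'
#' Trapezoidal integration of the ROC curve over the unique-score
#' operating points; exactly the normalised Mann-Whitney U statistic with
#' ties counted 1/2, and invariant to strictly monotone score transforms.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in [0, 1].
#' @export
auc_roc <- function(scores, labels) {
  assert_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  p <- sum(labels == 1)
  n <- sum(labels == 0)
  if (p == 0 || n == 0) stop("both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  keep <- !duplicated(s, fromLast = TRUE)   # last index within each tie group
  tpr <- c(0, cumsum(y)[keep] / p)
  fpr <- c(0, cumsum(1 - y)[keep] / n)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Area under the precision-recall curve (step-wise)
#'
#' Step-wise interpolation over the achievable operating points at unique
#' score cutoffs: `sum (R_i - R_{i-1}) * P_i`, precision held constant
#' between points (no optimistic linear interpolation).
#'
#' @inheritParams auc_roc
#' @return AUPR in [0, 1].
#' @export
aupr <- function(scores, labels) {
  assert_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  p <- sum(labels == 1)
  if (p == 0 || sum(labels == 0) == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  keep <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(y)[keep]
  pos_calls <- which(keep)
  recall <- tp / p
  precision <- tp / pos_calls
  sum(diff(c(0, recall)) * precision)
}

#' Evaluate predictions at a threshold
#'
#' Convenience wrapper: metrics plus AUC and AUPR for a prediction table.
#'
#' @param predictions Tibble with `score` and `label` columns (e.g. from
#'   [predict_dti()]).
#' @param threshold Classification threshold.
#' @return One-row tibble: `n_pairs`, the [dti_metrics()] columns, `auc`,
#'   `aupr`.
#' @export
evaluate_predictions <- function(predictions, threshold) {
  stopifnot(all(c("score", "label") %in% names(predictions)))
  m <- dti_metrics(predictions$score, predictions$label, threshold)
  both <- length(unique(predictions$label)) == 2
  out <- dplyr::bind_cols(
    tibble::tibble(n_pairs = nrow(predictions)), m,
    tibble::tibble(
      auc = if (both) auc_roc(predictions$score, predictions$label) else NA_real_,
      aupr = if (both) aupr(predictions$score, predictions$label) else NA_real_))
  attr(out, "undefined") <- attr(m, "undefined")
  out
}

#' Evaluate predictions across novelty subsets
#'
#' Applies [evaluate_predictions()] to the four novelty partitions of a
#' test set relative to the training pairs (all / unseen compound / unseen
#' protein / both unseen).
#'
#' @param predictions Prediction tibble for the test pairs (with `drug_id`,
#'   `protein_id`, `score`, `label`).
#' @param train An [interaction_dataset()] defining "seen" entities.
#' @param threshold Classification threshold.
#' @return Tibble, one row per subset, with a `subset` column.
#' @export
evaluate_by_novelty <- function(predictions, train, threshold) {
  new_drug <- !(predictions$drug_id %in% train$pairs$drug_id)
  new_prot <- !(predictions$protein_id %in% train$pairs$protein_id)
  subsets <- list(all = rep(TRUE, nrow(predictions)),
                  unseen_compound = new_drug,
                  unseen_protein = new_prot,
                  unseen_both = new_drug & new_prot)
  dplyr::bind_rows(lapply(names(subsets), function(nm) {
    sub <- predictions[subsets[[nm]], , drop = FALSE]
    if (nrow(sub) == 0) {
      return(tibble::tibble(subset = nm, n_pairs = 0L))
    }
    dplyr::bind_cols(tibble::tibble(subset = nm),
                     evaluate_predictions(sub, threshold))
  }))
}
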