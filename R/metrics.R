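#' Confusion counts at a 0.5 threshold
#'
#' @param scores Class-1 (patient) probabilities in `[0, 1]`.
#' @param labels True labels, 0/1; patient is the positive class.
#' @param threshold Decision threshold (default 0.5; scores at the
#'   threshold predict positive).
#' @return A list with `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels),
            all(scores >= 0 & scores <= 1))
  pred <- scores >= threshold
  pos <- labels == 1L
  list(tp = sum(pred & pos), fn = sum(!pred & pos),
       fp = sum(pred & !pos), tn = sum(!pred & !pos))
}

#' The seven classification metrics from confusion counts and scores
#'
#' Accuracy, precision, recall, F1, sensitivity and specificity come from
#' the confusion counts (patient = positive class; precision/recall are 0
#' when their denominator is 0). Sensitivity equals positive-class recall
#' by definition, so the two fields carry the same value. AUC is the rank
#' statistic (Mann-Whitney) with half credit for tied scores.
#'
#' @inheritParams confusion_counts
#' @return A list with `metrics` (named numeric vector of the seven
#'   metrics) and `counts`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  cc <- confusion_counts(scores, labels, threshold)
  m <- metrics_from_counts(cc)
  if (length(unique(labels)) < 2L) {
    warning("AUC undefined: labels contain a single class")
    m["auc"] <- NA_real_
  } else {
    m["auc"] <- auc_rank(scores, labels)
  }
  list(metrics = m, counts = cc)
}

#' Metrics determined by confusion counts alone (all but AUC)
#'
#' @param cc A list with `tp`, `fn`, `fp`, `tn`.
#' @return Named numeric vector with `auc` left `NA`.
#' @export
metrics_from_counts <- function(cc) {
  total <- cc$tp + cc$fn + cc$fp + cc$tn
  prec <- if (cc$tp + cc$fp == 0) 0 else cc$tp / (cc$tp + cc$fp)
  rec <- if (cc$tp + cc$fn == 0) 0 else cc$tp / (cc$tp + cc$fn)
  spec <- if (cc$tn + cc$fp == 0) 0 else cc$tn / (cc$tn + cc$fp)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(accuracy = (cc$tp + cc$tn) / total, precision = prec, recall = rec,
    f1 = f1, sensitivity = rec, specificity = spec, auc = NA_real_)
}

#' Rank-statistic AUC with 0.5 credit for ties
#'
#' @inheritParams confusion_counts
#' @return The area under the ROC curve.
#' @export
auc_rank <- function(scores, labels) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: labels contain one class")
  r <- rank(scores) # midranks share tie credit equally
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
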