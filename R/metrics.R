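# Evaluation metrics: sensitivity/specificity, rank-based auROC, Matthews
# correlation coefficient, and a two-sided Mann-Whitney comparison.

#' Sensitivity and specificity from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`;
#' an undefined ratio (zero denominator) is reported as `NA`.
#'
#' @param TP,FN,TN,FP Non-negative confusion-matrix counts.
#' @return A list with `sensitivity` and `specificity`.
#' @export
sensitivity_specificity <- function(TP, FN, TN, FP) {
  list(
    sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_
  )
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) auROC: the probability that a random positive
#' outscores a random negative, with ties counted 1/2. Equivalent to the
#' trapezoidal area under the threshold-swept ROC curve.
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param labels Binary labels: a factor with the positive class
#'   `"allergic"`, or a logical/0-1 vector.
#' @return auROC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.factor(labels)) labels == "allergic" else as.logical(labels)
  if (length(scores) != length(pos)) abort("scores and labels must align")
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; if any factor of
#' the denominator is zero the MCC is reported as 0 (the convention for a
#' degenerate confusion matrix).
#'
#' @param TP,FP,TN,FN Non-negative confusion-matrix counts.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(TP, FP, TN, FN) {
  TP <- as.numeric(TP); FP <- as.numeric(FP)
  TN <- as.numeric(TN); FN <- as.numeric(FN)
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (den == 0) return(0)
  (TP * TN - FP * FN) / sqrt(den)
}

confusion_counts <- function(predicted, truth) {
  pos <- truth == "allergic"
  pred_pos <- predicted == "allergic"
  list(TP = sum(pred_pos & pos), FP = sum(pred_pos & !pos),
       TN = sum(!pred_pos & !pos), FN = sum(!pred_pos & pos))
}

#' Two-sided Mann-Whitney comparison of two metric samples
#'
#' Exact rank-sum p-value when there are no ties and both samples are
#' small, otherwise the tie-corrected normal approximation. All-identical
#' pooled values give p = 1.
#'
#' @param a,b Non-empty numeric vectors (e.g. per-repeat auROC values).
#' @return Two-sided p-value in `(0, 1]`.
#' @export
mann_whitney_compare <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) abort("both samples must be non-empty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) return(1)
  has_ties <- anyDuplicated(pooled) > 0L
  exact <- !has_ties && length(a) < 50L && length(b) < 50L
  suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = !exact)$p.value
  )
}
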