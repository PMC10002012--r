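# Two-class evaluation battery: confusion matrix, per-class precision /
# recall / F1 / specificity combined by support-weighted (default) or macro
# averaging, Cohen's kappa, and the rank-based (Mann-Whitney) ROC AUC with
# midrank tie handling. Per-class metrics with a zero denominator are 0
# (with a diagnostic message), matching mainstream metric libraries.

checkLabels <- function(y, name) {
  if (length(y) == 0L) stop(name, " must be non-empty", call. = FALSE)
  y <- as.integer(y)
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop(name, " must contain only labels 0 and 1", call. = FALSE)
  y
}

#' Confusion matrix for two-class predictions
#'
#' @param yTrue,yPred integer label vectors in `{0, 1}`, equal length.
#' @return 2x2 integer matrix, rows = true class, columns = predicted class,
#'   dimnames `"0"`/`"1"`.
#' @examples
#' confusionCounts(c(0, 0, 1, 1), c(0, 1, 1, 1))
#' @export
confusionCounts <- function(yTrue, yPred) {
  yTrue <- checkLabels(yTrue, "yTrue"); yPred <- checkLabels(yPred, "yPred")
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length", call. = FALSE)
  cm <- matrix(0L, 2L, 2L, dimnames = list(true = c("0", "1"),
                                           predicted = c("0", "1")))
  for (i in 0:1) for (j in 0:1)
    cm[i + 1L, j + 1L] <- sum(yTrue == i & yPred == j)
  cm
}

# TP/FP/FN/TN of class `cls` (one-vs-rest) from a 2x2 confusion matrix.
classCounts <- function(cm, cls) {
  k <- cls + 1L
  tp <- cm[k, k]
  fp <- sum(cm[-k, k])
  fn <- sum(cm[k, -k])
  tn <- sum(cm) - tp - fp - fn
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

safeRatio <- function(num, den, what, cls) {
  if (den == 0) {
    message(sprintf("zero denominator for %s of class %d; reporting 0",
                    what, cls))
    return(0)
  }
  num / den
}

#' Precision, recall, F1 and specificity from a confusion matrix
#'
#' Per class: `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`,
#' `specificity = TN/(FP+TN)`; combined across the two classes by
#' support-weighted mean (weights = true class frequencies, the default) or
#' unweighted (macro) mean.
#'
#' @param cm 2x2 confusion matrix from [confusionCounts()].
#' @param averaging `"weighted"` or `"macro"`.
#' @return named numeric: `precision`, `recall`, `f1`, `specificity`.
#' @export
classMetrics <- function(cm, averaging = c("weighted", "macro")) {
  averaging <- match.arg(averaging)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  per <- vapply(0:1, function(cls) {
    cc <- classCounts(cm, cls)
    precision <- safeRatio(cc[["tp"]], cc[["tp"]] + cc[["fp"]], "precision", cls)
    recall <- safeRatio(cc[["tp"]], cc[["tp"]] + cc[["fn"]], "recall", cls)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    specificity <- safeRatio(cc[["tn"]], cc[["fp"]] + cc[["tn"]], "specificity", cls)
    c(precision = precision, recall = recall, f1 = f1,
      specificity = specificity)
  }, numeric(4))
  w <- if (averaging == "weighted") rowSums(cm) / total else c(0.5, 0.5)
  drop(per %*% w)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(P0 - Pe) / (1 - Pe)`: `P0` is the observed
#' agreement (diagonal fraction) and `Pe` the agreement expected from the
#' row/column marginals. Any predictor statistically independent of the
#' truth — a constant predictor in particular — scores 0. When `Pe = 1`
#' (both marginals degenerate) kappa is reported as 0 with a warning.
#'
#' @param cm 2x2 confusion matrix.
#' @return scalar in `[-1, 1]`.
#' @export
cohensKappa <- function(cm) {
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  p0 <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    warning("chance agreement Pe = 1; kappa undefined, reporting 0",
            call. = FALSE)
    return(0)
  }
  (p0 - pe) / (1 - pe)
}

#' ROC AUC by the rank (Mann-Whitney) estimator with midrank ties
#'
#' Equals the probability that a random positive outscores a random
#' negative, ties counted one half — equivalently the trapezoidal area under
#' the ROC curve. Invariant under strictly monotone transforms of the
#' scores; identical scores for everyone give exactly 0.5.
#'
#' @param yTrue labels in `{0, 1}`; both classes must be present.
#' @param scores positive-class scores.
#' @return scalar in `[0, 1]`.
#' @export
rocAuc <- function(yTrue, scores) {
  yTrue <- checkLabels(yTrue, "yTrue")
  if (length(yTrue) != length(scores))
    stop("yTrue and scores must have equal length", call. = FALSE)
  n1 <- sum(yTrue == 1L); n0 <- sum(yTrue == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("ROC AUC requires both classes to be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[yTrue == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Assemble the full metric battery into a MetricReport
#'
#' @param yTrue,yPred labels in `{0, 1}`.
#' @param scores positive-class scores (for ROC AUC); may be `NULL`, which
#'   records `NA`.
#' @param loss scalar loss of the arm (e.g. test-set categorical
#'   cross-entropy); `NA` when not applicable.
#' @param averaging `"weighted"` or `"macro"`.
#' @return a [MetricReport].
#' @export
evaluatePredictions <- function(yTrue, yPred, scores = NULL, loss = NA_real_,
                                averaging = c("weighted", "macro")) {
  averaging <- match.arg(averaging)
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length", call. = FALSE)
  cm <- confusionCounts(yTrue, yPred)
  prfs <- classMetrics(cm, averaging)
  auc <- if (is.null(scores)) NA_real_ else rocAuc(yTrue, scores)
  new("MetricReport", loss = as.numeric(loss),
      accuracy = sum(diag(cm)) / sum(cm),
      precision = prfs[["precision"]], recall = prfs[["recall"]],
      f1 = prfs[["f1"]], specificity = prfs[["specificity"]],
      kappa = cohensKappa(cm), rocAuc = auc, averaging = averaging)
}
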