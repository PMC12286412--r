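## Imbalance-aware evaluation metrics, the PR random baseline and t-based
## confidence intervals.

#' Six-metric evaluation set for imbalanced binary classification
#'
#' Computes, from continuous scores and binary labels: ROC-AUC (by the rank
#' statistic, equivalent to the pairwise concordance probability), PR-AUC
#' (step integration of the precision-recall curve), G-mean
#' (sqrt(sensitivity * specificity)), accuracy, Type I error (false-positive
#' rate: predicted injury, none occurred) and Type II error (false-negative
#' rate: predicted safe, injury occurred). Threshold-based metrics use
#' `threshold` on the scores; the two AUCs are threshold-free. If only one
#' class is present the AUCs are `NaN` and the threshold metrics are still
#' computed.
#'
#' @param scores numeric vector of predicted positive-class scores.
#' @param labels binary 0/1 vector aligned to `scores`.
#' @param threshold classification threshold on the scores.
#' @return named numeric vector with elements `roc_auc`, `pr_auc`, `gmean`,
#'   `accuracy`, `type1_error`, `type2_error`.
#' @export
computeMetrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  pos <- labels == 1L
  nP <- sum(pos); nN <- sum(!pos)

  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & pos);  fn <- sum(pred == 0L & pos)
  tn <- sum(pred == 0L & !pos); fp <- sum(pred == 1L & !pos)
  type1 <- if (fp + tn > 0) fp / (fp + tn) else NaN
  type2 <- if (fn + tp > 0) fn / (fn + tp) else NaN
  gmean <- sqrt((1 - type2) * (1 - type1))
  acc <- (tp + tn) / length(labels)

  if (nP > 0 && nN > 0) {
    r <- rank(scores, ties.method = "average")
    roc <- (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
    pr <- .prAUC(scores, labels)
  } else {
    roc <- NaN
    pr <- NaN
  }
  c(roc_auc = roc, pr_auc = pr, gmean = gmean, accuracy = acc,
    type1_error = type1, type2_error = type2)
}

## Precision-recall step integration: walk thresholds in decreasing score
## order, sum precision * delta-recall.
.prAUC <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  nP <- sum(lab)
  tp <- cumsum(lab)
  fp <- cumsum(1L - lab)
  ## collapse tied scores to their last cumulative counts
  keep <- c(sc[-1L] != sc[-length(sc)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  precision <- tp / (tp + fp)
  recall <- tp / nP
  dr <- diff(c(0, recall))
  sum(precision * dr)
}

#' Random-classifier baseline of the precision-recall curve
#'
#' The PR-AUC of a random classifier equals the positive-class prevalence:
#' the floor against which an observed PR-AUC is judged on an imbalanced
#' test set.
#'
#' @param labels binary 0/1 vector.
#' @return prevalence (numeric scalar in (0, 1]).
#' @export
prBaseline <- function(labels) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  if (sum(labels) == 0L) stop("no positive labels: PR baseline undefined")
  mean(labels)
}

#' t-based confidence interval for a metric distribution
#'
#' mean +/- t((1 + level) / 2, n - 1) * sd / sqrt(n), the Student-t interval
#' used to summarize repeated evaluation runs.
#'
#' @param values numeric vector, n >= 2.
#' @param level confidence level in (0, 1).
#' @return named numeric vector `(low, mean, high)`.
#' @export
confidenceIntervalT <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values for a t interval")
  m <- mean(values)
  half <- stats::qt((1 + level) / 2, df = n - 1) * stats::sd(values) / sqrt(n)
  c(low = m - half, mean = m, high = m + half)
}
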