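#' Area under the ROC curve (rank estimator)
#'
#' Tie-aware Mann-Whitney estimator: the probability that a random positive
#' scores above a random negative, counting ties as one half, computed via
#' average ranks. Preferred over trapezoidal ROC integration because KNN
#' vote fractions produce heavy ties.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector of the same length; both classes required.
#' @return AUC in `[0, 1]`.
#' @examples
#' rocAUC(c(0.9, 0.4, 0.35, 0.8), c(1, 0, 1, 0))  # 0.75
#' @export
rocAUC <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC needs both classes present in 'labels'")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion metrics with explicit counts
#'
#' Accuracy, false-positive rate FP/N- and false-negative rate FN/N+ for
#' binary predictions, each rate carried with its numerator/denominator so
#' small-cohort results stay auditable (e.g. `"0.40 (4/10)"`). A rate whose
#' denominator is zero is reported as `NA` and flagged.
#'
#' @param pred,truth 0/1 vectors of equal length.
#' @return list with `n`, `accuracy`, `fpr`, `fnr`, the count pairs
#'   `fp`/`negatives` and `fn`/`positives`, and formatted strings
#'   `fpr_label`, `fnr_label`.
#' @export
confusionMetrics <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("'pred' and 'truth' must have equal length")
  pred <- as.integer(pred); truth <- as.integer(truth)
  stopifnot(all(pred %in% 0:1), all(truth %in% 0:1))
  n <- length(truth)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  npos <- sum(truth == 1L); nneg <- sum(truth == 0L)
  fpr <- if (nneg > 0L) fp / nneg else NA_real_
  fnr <- if (npos > 0L) fn / npos else NA_real_
  fmt <- function(rate, num, den)
    if (is.na(rate)) sprintf("undefined (0 in denominator)")
    else sprintf("%.2f (%d/%d)", rate, num, den)
  list(n = n, accuracy = 1 - (fp + fn) / n,
       fpr = fpr, fnr = fnr,
       fp = fp, negatives = nneg, fn = fn, positives = npos,
       fpr_label = fmt(fpr, fp, nneg), fnr_label = fmt(fnr, fn, npos))
}

#' Mean and standard error over repeated runs
#'
#' @param values numeric vector of at least 2 values (e.g. per-repeat AUCs).
#' @return named vector `c(mean, se)` with `se = sd / sqrt(n)`.
#' @export
repeatSummary <- function(values) {
  if (length(values) < 2L)
    stop("need at least 2 values to estimate a standard error")
  c(mean = mean(values), se = stats::sd(values) / sqrt(length(values)))
}

#' Evaluate scores against true labels at a cutoff
#'
#' Combines [rocAUC()] and [confusionMetrics()] into one report.
#'
#' @param scores probability scores.
#' @param truth 0/1 labels.
#' @param cutoff decision threshold, see [classifyWithCutoff()].
#' @return list with `auc`, `cutoff_used`, and the confusion metrics.
#' @export
evaluateScores <- function(scores, truth, cutoff = 0.5) {
  cm <- confusionMetrics(classifyWithCutoff(scores, cutoff), truth)
  c(list(auc = rocAUC(scores, truth), cutoff_used = cutoff), cm)
}
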