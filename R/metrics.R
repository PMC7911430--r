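#' Truncate a percentage to two decimals
#'
#' Reported rates are truncated (floored), not rounded, to two decimal
#' places: 329/360 = 91.3888...% is reported as 91.38. Internal values stay
#' at full precision; truncation is a reporting convention.
#'
#' @param x numeric percentage(s).
#' @return `x` truncated to 2 decimals.
#' @export
truncatePercent <- function(x) floor(x * 100) / 100

#' Binary classification accuracy
#'
#' `100 * (TP + TN) / (TP + TN + FP + FN)`, reported truncated to two
#' decimals (set `raw = TRUE` for full precision).
#'
#' @param cm a [ConfusionMatrix2-class].
#' @param raw return full precision instead of the truncated report value.
#' @return Accuracy in percent.
#' @examples
#' accuracy(ConfusionMatrix2(tp = 140, fp = 12, fn = 19, tn = 189))  # 91.38
#' @export
accuracy <- function(cm, raw = FALSE) {
  stopifnot(is(cm, "ConfusionMatrix2"))
  total <- cm@tp + cm@fp + cm@fn + cm@tn
  if (total <= 0) stop("accuracy: empty confusion matrix")
  a <- 100 * (cm@tp + cm@tn) / total
  if (raw) a else truncatePercent(a)
}

#' True recognition rate (precision)
#'
#' `100 * TP / (TP + FP)`: of the sounds recognized as cattle voice, the
#' fraction that really were. Truncated to two decimals unless `raw`.
#'
#' @inheritParams accuracy
#' @return Rate in percent.
#' @export
trueRecognitionRate <- function(cm, raw = FALSE) {
  stopifnot(is(cm, "ConfusionMatrix2"))
  den <- cm@tp + cm@fp
  if (den <= 0) stop("trueRecognitionRate: undefined (TP + FP = 0)")
  r <- 100 * cm@tp / den
  if (raw) r else truncatePercent(r)
}

#' False recognition rate (negative predictive value)
#'
#' `100 * TN / (TN + FN)`: of the sounds recognized as non-cattle, the
#' fraction that really were. Truncated to two decimals unless `raw`.
#'
#' @inheritParams accuracy
#' @return Rate in percent.
#' @export
falseRecognitionRate <- function(cm, raw = FALSE) {
  stopifnot(is(cm, "ConfusionMatrix2"))
  den <- cm@tn + cm@fn
  if (den <= 0) stop("falseRecognitionRate: undefined (TN + FN = 0)")
  r <- 100 * cm@tn / den
  if (raw) r else truncatePercent(r)
}

#' K-class confusion matrix from labels and predictions
#'
#' Rows are true classes, columns predicted classes (0-based labels
#' `0..K-1`). Per-class accuracy is the diagonal over the row total;
#' overall accuracy the trace over the grand total.
#'
#' @param labels,predictions integer vectors of equal length with values in
#'   `0..K-1`.
#' @param K number of classes.
#' @param classLabels optional dimnames (default `behaviorClassLabels()`
#'   when K = 4).
#' @return List with `counts` (K x K matrix), `perClassAccuracy` (percent,
#'   full precision) and `overallAccuracy` (percent, full precision).
#' @export
confusionFromPredictions <- function(labels, predictions, K,
                                     classLabels = NULL) {
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  if (length(labels) != length(predictions))
    stop("confusionFromPredictions: length mismatch")
  if (any(labels < 0L | labels >= K) || any(predictions < 0L | predictions >= K))
    stop("confusionFromPredictions: label out of range 0..K-1")
  if (is.null(classLabels))
    classLabels <- if (K == 4) behaviorClassLabels() else as.character(0:(K - 1))
  counts <- matrix(0L, K, K, dimnames = list(true = classLabels,
                                             predicted = classLabels))
  for (i in seq_along(labels))
    counts[labels[i] + 1L, predictions[i] + 1L] <-
      counts[labels[i] + 1L, predictions[i] + 1L] + 1L
  rowTot <- rowSums(counts)
  perClass <- ifelse(rowTot > 0, 100 * diag(counts) / rowTot, NA_real_)
  list(counts = counts, perClassAccuracy = perClass,
       overallAccuracy = 100 * sum(diag(counts)) / sum(counts))
}

#' Binary confusion matrix from labels and predictions
#'
#' Collapses 0/1 labels (1 = positive, i.e. cattle voice) into the
#' [ConfusionMatrix2-class] layout.
#'
#' @param labels,predictions 0/1 integer vectors.
#' @return A [ConfusionMatrix2-class].
#' @export
binaryConfusion <- function(labels, predictions) {
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  stopifnot(length(labels) == length(predictions),
            all(labels %in% 0:1), all(predictions %in% 0:1))
  ConfusionMatrix2(tp = sum(predictions == 1L & labels == 1L),
                   fp = sum(predictions == 1L & labels == 0L),
                   fn = sum(predictions == 0L & labels == 1L),
                   tn = sum(predictions == 0L & labels == 0L))
}

#' Evaluation report for a binary confusion matrix
#'
#' The three reported rates (truncated to 2 decimals) plus the raw counts,
#' as a list ready for JSON export or as an aligned text table.
#'
#' @param cm a [ConfusionMatrix2-class].
#' @param format `"list"` or `"text"`.
#' @return List of counts and rates, or a character vector of table lines.
#' @export
evaluationReport <- function(cm, format = c("list", "text")) {
  format <- match.arg(format)
  orNA <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  rep <- list(truePositive = cm@tp, falsePositive = cm@fp,
              trueNegative = cm@tn, falseNegative = cm@fn,
              trueRecognitionRate = orNA(trueRecognitionRate(cm)),
              falseRecognitionRate = orNA(falseRecognitionRate(cm)),
              accuracy = accuracy(cm))
  if (format == "list") return(rep)
  c(sprintf("%-26s %10g", "True positive", rep$truePositive),
    sprintf("%-26s %10g", "False positive", rep$falsePositive),
    sprintf("%-26s %10g", "True negative", rep$trueNegative),
    sprintf("%-26s %10g", "False negative", rep$falseNegative),
    sprintf("%-26s %10.2f", "True recognition rate (%)",
            rep$trueRecognitionRate),
    sprintf("%-26s %10.2f", "False recognition rate (%)",
            rep$falseRecognitionRate),
    sprintf("%-26s %10.2f", "Accuracy (%)", rep$accuracy))
}
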