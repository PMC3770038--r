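#' Binary classification metrics from a confusion matrix
#'
#' Precision, recall (TPR), TNR, F-measure, G-mean and accuracy from
#' the four confusion-matrix counts. Conventions for degenerate cases:
#' precision is 0 when nothing is predicted positive, and the
#' F-measure is 0 when precision and recall are both 0.
#'
#' @param TP,FN,FP,TN non-negative integer counts; both classes must be
#'   represented (TP + FN >= 1 and TN + FP >= 1).
#' @return named list with `precision`, `recall`, `tnr`, `fMeasure`,
#'   `gMean`, `acc`.
#' @examples
#' binaryMetrics(TP = 8, FN = 2, FP = 4, TN = 16)
#' @export
binaryMetrics <- function(TP, FN, FP, TN) {
  counts <- c(TP, FN, FP, TN)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (TP + FN < 1) stop("no positive examples")
  if (TN + FP < 1) stop("no negative examples")
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  recall <- TP / (TP + FN)
  tnr <- TN / (TN + FP)
  fMeasure <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, tnr = tnr,
       fMeasure = fMeasure, gMean = sqrt(recall * tnr),
       acc = (TP + TN) / sum(counts))
}

# Geometric mean in log space with an exact zero short-circuit, so
# products over many classes (C up to the 20s) cannot underflow.
.geomMean <- function(x) {
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

#' Imbalance-aware multiclass metrics
#'
#' Computes, from true and predicted class codes: per-class accuracies
#' Acc_i (within-class recall), one-vs-rest precisions and F-measures;
#' the weighted accuracy Acc = sum_i Acc_i * P_i (identical to the
#' plain fraction correct); the F-score, the arithmetic mean of the
#' per-class F-measures; and the G-mean, the geometric mean of the
#' Acc_i, which collapses to 0 as soon as any single class is entirely
#' misclassified — the signature that makes it sensitive to imbalance
#' where plain accuracy is not.
#'
#' A class never predicted gets precision (and hence F-measure) 0,
#' deliberately penalizing classifiers that ignore minority classes.
#'
#' @param yTrue integer class codes in 1..C; every class must appear.
#' @param yPred integer class codes in 1..C.
#' @param C number of classes (default: maximum code observed).
#' @return a [MetricsReport-class].
#' @examples
#' r <- multiclassMetrics(c(1, 1, 1, 2, 2, 3), c(1, 1, 2, 2, 2, 3))
#' r
#' @export
multiclassMetrics <- function(yTrue, yPred, C = max(yTrue, yPred)) {
  yTrue <- as.integer(yTrue); yPred <- as.integer(yPred)
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length")
  C <- as.integer(C)
  if (!all(seq_len(C) %in% yTrue))
    stop("every class in 1..C must appear in yTrue")
  if (any(yPred < 1L | yPred > C)) stop("predictions outside 1..C")

  conf <- table(factor(yTrue, levels = seq_len(C)),
                factor(yPred, levels = seq_len(C)))
  nPerClass <- rowSums(conf)
  acc_i <- diag(conf) / nPerClass
  prec_i <- vapply(seq_len(C), function(i) {
    predicted <- sum(conf[, i])
    if (predicted > 0) conf[i, i] / predicted else 0
  }, 0)
  f_i <- ifelse(prec_i + acc_i > 0,
                2 * prec_i * acc_i / (prec_i + acc_i), 0)
  P_i <- nPerClass / sum(nPerClass)

  methods::new("MetricsReport",
               perClassAccuracy = unname(acc_i),
               perClassPrecision = unname(prec_i),
               perClassFMeasure = unname(f_i),
               classProportions = unname(P_i),
               acc = sum(acc_i * P_i),
               fScore = mean(f_i),
               gMean = .geomMean(unname(acc_i)))
}

#' Aggregate metric values of a report
#' @param x a [MetricsReport-class].
#' @return named numeric vector with `acc`, `fScore`, `gMean`.
#' @export
metricValues <- function(x) {
  stopifnot(methods::is(x, "MetricsReport"))
  c(acc = x@acc, fScore = x@fScore, gMean = x@gMean)
}

#' Per-class accuracies of a report
#' @param x a [MetricsReport-class].
#' @export
perClassAccuracy <- function(x) {
  stopifnot(methods::is(x, "MetricsReport"))
  x@perClassAccuracy
}

#' Per-class one-vs-rest F-measures of a report
#' @param x a [MetricsReport-class].
#' @export
perClassFMeasure <- function(x) {
  stopifnot(methods::is(x, "MetricsReport"))
  x@perClassFMeasure
}

setMethod("show", "MetricsReport", function(object) {
  C <- length(object@perClassAccuracy)
  cat("MetricsReport (", C, " classes)\n", sep = "")
  cat(sprintf("  Acc = %.4f  F-score = %.4f  G-mean = %.4f\n",
              object@acc, object@fScore, object@gMean))
  cat("  per-class accuracy:",
      paste(sprintf("%.3f", object@perClassAccuracy), collapse = " "), "\n")
})
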