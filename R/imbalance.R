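#' Decision-threshold adjustment for an imbalanced binary task
#'
#' theta = (m+ - m-)/(m+ + m- + 2), computed from the training counts
#' of the positive and negative class. When the positive class is the
#' minority, theta is negative, so subtracting it from the raw SVM
#' margin moves the decision boundary toward the majority class.
#' Antisymmetric in its arguments and always strictly inside (-1, 1).
#'
#' @param mPlus,mMinus class training counts, both >= 1.
#' @return a [ThresholdCorrection-class].
#' @examples
#' computeThreshold(10, 50)  # theta = -40/62
#' @export
computeThreshold <- function(mPlus, mMinus) {
  mPlus <- as.integer(mPlus); mMinus <- as.integer(mMinus)
  if (is.na(mPlus) || is.na(mMinus) || mPlus < 1L || mMinus < 1L)
    stop("both class counts must be integers >= 1")
  methods::new("ThresholdCorrection",
               theta = (mPlus - mMinus) / (mPlus + mMinus + 2),
               mPlus = mPlus, mMinus = mMinus)
}

#' Threshold value of a correction
#' @param x a [ThresholdCorrection-class].
#' @export
thetaValue <- function(x) {
  stopifnot(methods::is(x, "ThresholdCorrection"))
  x@theta
}

setMethod("show", "ThresholdCorrection", function(object) {
  cat("ThresholdCorrection: theta =", format(object@theta, digits = 6),
      " (m+ =", object@mPlus, ", m- =", object@mMinus, ")\n")
})

#' Apply a decision threshold to raw SVM margins
#'
#' The corrected decision value is `raw - theta`; the predicted binary
#' label is +1 when it is positive, -1 otherwise.
#'
#' @param raw raw (pre-sign) SVM decision values.
#' @param theta threshold, either a number or a
#'   [ThresholdCorrection-class].
#' @return list with `corrected` (numeric) and `label` (+1/-1 integer).
#' @export
applyThreshold <- function(raw, theta) {
  if (methods::is(theta, "ThresholdCorrection")) theta <- theta@theta
  corrected <- raw - theta
  list(corrected = corrected,
       label = ifelse(corrected > 0, 1L, -1L))
}

#' Random undersampling to a balanced binary training subset
#'
#' Keeps every minority-class sample and draws, uniformly without
#' replacement, an equal number of majority-class samples. Already
#' balanced input is returned unchanged (order-stable). Uses the
#' current RNG state.
#'
#' @param sampleIndices indices identifying the training samples.
#' @param binaryLabels +1/-1 per element of `sampleIndices`.
#' @return subset of `sampleIndices` with equal class counts.
#' @export
randomUndersample <- function(sampleIndices, binaryLabels) {
  if (length(sampleIndices) != length(binaryLabels))
    stop("indices and labels must be parallel")
  pos <- binaryLabels > 0
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L) stop("both classes must be present")
  if (nPos == nNeg) return(sampleIndices)
  if (nPos < nNeg) {
    keepMaj <- sample(sampleIndices[!pos], nPos, replace = FALSE)
    out <- c(sampleIndices[pos], keepMaj)
  } else {
    keepMaj <- sample(sampleIndices[pos], nNeg, replace = FALSE)
    out <- c(sampleIndices[!pos], keepMaj)
  }
  sort(out)
}
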