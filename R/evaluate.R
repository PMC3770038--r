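#' Stratified fold assignment
#'
#' Assigns samples to folds so that every fold's class composition is
#' within one sample of the overall class proportions. When the
#' smallest class has fewer samples than `nFolds`, the fold count is
#' reduced to that size (with a warning) rather than failing.
#'
#' @param labels integer class codes.
#' @param nFolds requested fold count (>= 2).
#' @return integer fold id per sample; attribute `nFolds` gives the
#'   effective fold count. Uses the current RNG state.
#' @export
stratifiedFolds <- function(labels, nFolds = 3) {
  labels <- as.integer(labels)
  nFolds <- as.integer(nFolds)
  if (nFolds < 2) stop("at least two folds are required")
  minClass <- min(table(labels))
  if (minClass < nFolds) {
    warning("smallest class has ", minClass, " samples; reducing folds ",
            "from ", nFolds, " to ", minClass)
    nFolds <- as.integer(minClass)
    if (nFolds < 2) stop("smallest class too small for cross-validation")
  }
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  structure(fold, nFolds = nFolds)
}

#' Per-branch RBF grid search
#'
#' Selects the (cost, sigma) pair maximizing the internal
#' cross-validated binary G-mean of a plain RBF SVM on one binary
#' branch's training data. Ties are broken by the smaller cost, then
#' the smaller sigma. The default grids are C in 2^-2..2^15 and sigma
#' in 2^-6..2^5 by powers of two (216 points).
#'
#' @param x numeric samples x genes matrix (the branch's feature-space
#'   view, already standardized).
#' @param yBin +1/-1 labels.
#' @param cGrid,sigmaGrid candidate values.
#' @param nFolds internal stratified folds (default 3; reduced when a
#'   class is smaller, and replaced by training-set G-mean when a
#'   class has a single sample).
#' @return list with `cost`, `sigma` and the achieved `gMean`.
#' @export
gridSearchBranch <- function(x, yBin,
                             cGrid = 2^seq(-2, 15),
                             sigmaGrid = 2^seq(-6, 5),
                             nFolds = 3) {
  x <- as.matrix(x)
  if (!all(c(-1, 1) %in% sign(yBin))) stop("both classes must be present")
  if (length(cGrid) < 1 || length(sigmaGrid) < 1) stop("empty grid")
  yf <- factor(ifelse(yBin > 0, "pos", "neg"), levels = c("pos", "neg"))
  dimnames(x) <- NULL

  minClass <- min(sum(yBin > 0), sum(yBin < 0))
  useCV <- minClass >= 2
  fold <- if (useCV) {
    suppressWarnings(stratifiedFolds(ifelse(yBin > 0, 1L, 2L),
                                     min(nFolds, minClass)))
  } else NULL

  gmeanOf <- function(truth, pred) {
    tp <- sum(truth == "pos" & pred == "pos")
    fn <- sum(truth == "pos" & pred == "neg")
    tn <- sum(truth == "neg" & pred == "neg")
    fp <- sum(truth == "neg" & pred == "pos")
    sqrt((tp / (tp + fn)) * (tn / (tn + fp)))
  }

  best <- list(cost = NA_real_, sigma = NA_real_, gMean = -Inf)
  for (sg in sort(sigmaGrid)) {
    for (cs in sort(cGrid)) {
      g <- if (useCV) {
        preds <- rep(NA_character_, length(yf))
        for (f in seq_len(attr(fold, "nFolds"))) {
          tr <- fold != f
          fit <- e1071::svm(x[tr, , drop = FALSE], yf[tr],
                            kernel = "radial",
                            gamma = .sigmaToGamma(sg), cost = cs,
                            scale = FALSE)
          preds[!tr] <- as.character(stats::predict(fit, x[!tr, , drop = FALSE]))
        }
        gmeanOf(yf, preds)
      } else {
        fit <- e1071::svm(x, yf, kernel = "radial",
                          gamma = .sigmaToGamma(sg), cost = cs,
                          scale = FALSE)
        gmeanOf(yf, as.character(stats::predict(fit, x)))
      }
      better <- g > best$gMean + 1e-12 ||
        (abs(g - best$gMean) <= 1e-12 &&
           (cs < best$cost || (cs == best$cost && sg < best$sigma)))
      if (better) best <- list(cost = cs, sigma = sg, gMean = g)
    }
  }
  best
}

#' Repeated stratified cross-validation of the ensemble
#'
#' The experimental protocol: `nRepeats` independent stratified
#' `nFolds`-fold partitions; in each fold the ensemble is trained on
#' the training folds only (feature spaces, standardization constants
#' and any grid search all see only training samples, so there is no
#' leakage into the test fold) and evaluated on the held-out fold. One
#' metrics report is computed per repeat from that repeat's pooled
#' out-of-fold predictions, and the aggregate metrics are averaged
#' over repeats.
#'
#' @param dataset an [ExpressionDataset-class].
#' @param nFolds outer folds (default 3).
#' @param nRepeats number of random repetitions (default 10).
#' @param seed integer seed for the whole protocol.
#' @param ... passed to [trainEnsemble()] (K, D, L, correction, cost,
#'   sigma, cGrid, sigmaGrid, ...).
#' @return list with `reports` (one [MetricsReport-class] per repeat),
#'   `perRepeat` (data.frame of Acc/F-score/G-mean per repeat),
#'   `summary` (mean and SD over repeats) and `avgPerClassAccuracy`.
#' @export
repeatedStratifiedCV <- function(dataset, nFolds = 3, nRepeats = 10,
                                 seed = 1, ...) {
  stopifnot(methods::is(dataset, "ExpressionDataset"))
  set.seed(seed)
  labels <- classCodes(dataset)
  C <- nClasses(dataset)

  reports <- vector("list", nRepeats)
  for (r in seq_len(nRepeats)) {
    fold <- stratifiedFolds(labels, nFolds)
    pred <- integer(length(labels))
    for (f in seq_len(attr(fold, "nFolds"))) {
      tr <- fold != f
      model <- trainEnsemble(dataset[, tr], ...)
      pred[!tr] <- predict(model, dataset[, !tr], type = "code")
    }
    reports[[r]] <- multiclassMetrics(labels, pred, C)
  }

  perRepeat <- data.frame(repeatId = seq_len(nRepeats),
                          t(vapply(reports, metricValues, numeric(3))))
  summary <- data.frame(
    metric = c("acc", "fScore", "gMean"),
    mean = c(mean(perRepeat$acc), mean(perRepeat$fScore),
             mean(perRepeat$gMean)),
    sd = c(stats::sd(perRepeat$acc), stats::sd(perRepeat$fScore),
           stats::sd(perRepeat$gMean)))
  avgPerClass <- rowMeans(vapply(reports, perClassAccuracy, numeric(C)))
  list(reports = reports, perRepeat = perRepeat, summary = summary,
       avgPerClassAccuracy = avgPerClass)
}

#' Sensitivity sweep over the feature-subspace dimension D
#'
#' Runs [repeatedStratifiedCV()] for each candidate D and collects the
#' averaged Acc, F-score and G-mean, reproducing the
#' performance-versus-D diagnostic: too small a D starves the base
#' classifiers, too large a D (approaching K) destroys their
#' diversity, so the optimum typically sits well below K.
#'
#' @param dataset an [ExpressionDataset-class].
#' @param dValues subspace dimensions to evaluate (default 10, 20, 30,
#'   50, 80); all must be <= K.
#' @param K feature-space size.
#' @param nFolds,nRepeats,seed protocol parameters, as in
#'   [repeatedStratifiedCV()].
#' @param ... further arguments to [trainEnsemble()] (L, correction,
#'   cost, sigma, ...).
#' @return data.frame with one row per D: mean and SD of each metric.
#' @export
sweepSubspaceDimension <- function(dataset,
                                   dValues = c(10, 20, 30, 50, 80),
                                   K = 100, nFolds = 3, nRepeats = 10,
                                   seed = 1, ...) {
  if (any(dValues > K)) stop("all D values must be <= K")
  rows <- lapply(dValues, function(D) {
    cv <- repeatedStratifiedCV(dataset, nFolds = nFolds,
                               nRepeats = nRepeats, seed = seed,
                               K = K, D = D, ...)
    s <- cv$summary
    data.frame(D = D,
               acc = s$mean[s$metric == "acc"],
               accSd = s$sd[s$metric == "acc"],
               fScore = s$mean[s$metric == "fScore"],
               fScoreSd = s$sd[s$metric == "fScore"],
               gMean = s$mean[s$metric == "gMean"],
               gMeanSd = s$sd[s$metric == "gMean"])
  })
  do.call(rbind, rows)
}
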