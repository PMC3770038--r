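#' @importFrom e1071 svm
#' @importFrom stats predict
NULL

# Map the RBF width sigma (kernel exp(-|x-y|^2 / (2 sigma^2))) onto
# libsvm's gamma parametrization exp(-gamma |x-y|^2).
.sigmaToGamma <- function(sigma) 1 / (2 * sigma^2)

# Raw (pre-sign) decision values of a fitted base SVM, oriented so that
# positive values mean the positive class.
.rawMargin <- function(base, x) {
  pr <- stats::predict(base@fit, x, decision.values = TRUE)
  dv <- as.numeric(attr(pr, "decision.values"))
  if (base@flip) -dv else dv
}

# Train one base classifier on an (already standardized) subspace view.
.trainBase <- function(xsub, yBin, cost, sigma, correction) {
  n <- length(yBin)
  theta <- 0
  if (correction == "thr") {
    theta <- computeThreshold(sum(yBin > 0), sum(yBin < 0))@theta
  } else if (correction == "rus") {
    keep <- randomUndersample(seq_len(n), yBin)
    xsub <- xsub[keep, , drop = FALSE]
    yBin <- yBin[keep]
  }
  if (length(unique(yBin)) < 2)
    stop("degenerate training subset: one class only")
  yf <- factor(ifelse(yBin > 0, "pos", "neg"), levels = c("pos", "neg"))
  dimnames(xsub) <- NULL
  fit <- e1071::svm(xsub, yf, kernel = "radial",
                    gamma = .sigmaToGamma(sigma), cost = cost,
                    scale = FALSE)
  # libsvm orders classes by first appearance; positive decision values
  # refer to its first label, which need not be "pos"
  flip <- fit$levels[fit$labels[1]] != "pos"
  list(fit = fit, theta = theta, flip = flip)
}

#' Train a counter-voting OAA SVM ensemble
#'
#' For each class i the labels are binarized one-against-all (class i
#' positive), a K-gene feature space is built on the training samples
#' (correlation clustering + per-cluster SNR selection), and L base
#' RBF-kernel SVMs are trained, each on a fresh random D-gene feature
#' subspace. The chosen imbalance correction is applied inside every
#' training subset: `"thr"` stores theta = (m+ - m-)/(m+ + m- + 2) and
#' shifts the decision value at prediction time; `"rus"` redraws a
#' balanced random undersample of the majority class independently for
#' every base classifier; `"none"` trains plainly.
#'
#' Expression values are standardized per gene (mean 0, SD 1 on the
#' training data); the constants are stored in the model and reapplied
#' at prediction.
#'
#' @param dataset an [ExpressionDataset-class] of training samples;
#'   every class needs at least 2 samples.
#' @param K feature-space size per branch (default 100).
#' @param D feature-subspace dimension (default 20).
#' @param L base classifiers per branch (default 100).
#' @param correction `"thr"`, `"rus"` or `"none"`.
#' @param cost,sigma SVM penalty and RBF width, scalars or length-C
#'   vectors (one per branch). Ignored for a branch when a grid is
#'   supplied.
#' @param cGrid,sigmaGrid optional grids; when the grid has more than
#'   one point, (cost, sigma) is tuned per branch by
#'   [gridSearchBranch()] on the branch's feature-space genes and
#'   shared by all L base classifiers of that branch.
#' @param seed optional integer; makes training deterministic.
#' @param featureSpaces optional precomputed list of C
#'   [FeatureSpace-class] objects (they do not depend on the
#'   correction), e.g. to reuse across correction arms or D values.
#' @return an [EnsembleModel-class].
#' @seealso [counterVotes()], [predict,EnsembleModel-method]
#' @export
trainEnsemble <- function(dataset, K = 100, D = 20, L = 100,
                          correction = c("thr", "rus", "none"),
                          cost = 8, sigma = 4,
                          cGrid = NULL, sigmaGrid = NULL,
                          seed = NULL, featureSpaces = NULL) {
  stopifnot(methods::is(dataset, "ExpressionDataset"))
  correction <- match.arg(correction)
  K <- as.integer(K); D <- as.integer(D); L <- as.integer(L)
  if (D > K) stop("D (", D, ") exceeds K (", K, ")")
  if (L < 1) stop("L must be at least 1")
  if (!is.null(seed)) set.seed(seed)

  labels <- classCodes(dataset)
  C <- nClasses(dataset)
  if (any(table(labels) < 2))
    stop("every class needs at least 2 training samples")
  values <- exprsMatrix(dataset)
  if (K > nrow(values)) stop("K exceeds the number of genes")

  center <- rowMeans(values)
  scl <- apply(values, 1, stats::sd)
  scl[scl == 0] <- 1
  std <- (values - center) / scl

  cost <- rep_len(cost, C)
  sigma <- rep_len(sigma, C)
  tune <- !is.null(cGrid) && !is.null(sigmaGrid) &&
    length(cGrid) * length(sigmaGrid) > 1
  code <- codeEntries(makeCodeMatrix("OAA", C))

  branches <- vector("list", C)
  for (i in seq_len(C)) {
    bin <- binarizeLabels(labels, code[, i])
    yBin <- bin$y
    if (sum(yBin > 0) < 1 || sum(yBin < 0) < 1)
      stop("branch ", i, " is untrainable (a class side is empty)")
    space <- if (is.null(featureSpaces)) {
      buildFeatureSpace(std, yBin, K)
    } else {
      featureSpaces[[i]]
    }
    xSpace <- t(std[geneIndices(space), , drop = FALSE])
    if (tune) {
      tuned <- gridSearchBranch(xSpace, yBin, cGrid, sigmaGrid)
      cost[i] <- tuned$cost
      sigma[i] <- tuned$sigma
    }
    classifiers <- vector("list", L)
    for (l in seq_len(L)) {
      sub <- sampleFeatureSubspace(space, D)
      xsub <- t(std[sub@geneIndices, , drop = FALSE])
      tb <- .trainBase(xsub, yBin, cost[i], sigma[i], correction)
      classifiers[[l]] <- methods::new("BaseClassifier", subspace = sub,
                                       fit = tb$fit, theta = tb$theta,
                                       flip = tb$flip, cost = cost[i],
                                       sigma = sigma[i])
    }
    branches[[i]] <- list(space = space, classifiers = classifiers)
  }

  methods::new("EnsembleModel", branches = branches, nClasses = C,
               L = L, correction = correction,
               labelMap = labelMap(dataset), geneIds = rownames(values),
               center = center, scale = scl,
               config = list(K = K, D = D, cost = cost, sigma = sigma,
                             seed = seed),
               version = 1L)
}

# Align new data with the model's genes and standardize it with the
# training constants. Accepts an ExpressionDataset, a genes x samples
# matrix with gene ids as rownames, or a named expression vector.
.alignNewdata <- function(model, newdata) {
  if (methods::is(newdata, "ExpressionDataset"))
    newdata <- exprsMatrix(newdata)
  if (is.null(dim(newdata)))
    newdata <- matrix(newdata, ncol = 1,
                      dimnames = list(names(newdata), "sample_1"))
  if (!is.null(rownames(newdata))) {
    idx <- match(model@geneIds, rownames(newdata))
    if (anyNA(idx))
      stop("missing genes: ",
           paste(utils::head(model@geneIds[is.na(idx)], 5), collapse = ", "))
    newdata <- newdata[idx, , drop = FALSE]
  } else if (nrow(newdata) != length(model@geneIds)) {
    stop("unnamed input must have one row per model gene")
  }
  (newdata - model@center) / model@scale
}

# Counters and mean corrected margins for all branches; `std` is the
# aligned, standardized genes x samples matrix.
.ensembleScores <- function(model, std) {
  n <- ncol(std)
  C <- model@nClasses
  counters <- matrix(0, n, C)
  margins <- matrix(0, n, C)
  for (i in seq_len(C)) {
    br <- model@branches[[i]]
    for (base in br$classifiers) {
      x <- t(std[base@subspace@geneIndices, , drop = FALSE])
      dimnames(x) <- NULL
      corrected <- applyThreshold(.rawMargin(base, x), base@theta)
      counters[, i] <- counters[, i] + (corrected$label > 0)
      margins[, i] <- margins[, i] + corrected$corrected
    }
  }
  list(counters = counters / model@L, margins = margins / model@L)
}

#' Per-class counters of a counter-voting ensemble
#'
#' For each OAA branch, the proportion of its L base classifiers whose
#' corrected decision value is positive for the sample. Counters lie in
#' \[0, 1\] and are multiples of 1/L.
#'
#' @param object an [EnsembleModel-class].
#' @param newdata an [ExpressionDataset-class], a genes-by-samples
#'   matrix with gene identifiers as rownames, or a single named
#'   expression vector.
#' @param ... unused.
#' @return numeric samples x C matrix; columns named by the original
#'   class labels.
#' @rdname counterVotes
#' @export
setMethod("counterVotes", "EnsembleModel", function(object, newdata, ...) {
  std <- .alignNewdata(object, newdata)
  counters <- .ensembleScores(object, std)$counters
  dimnames(counters) <- list(colnames(std), object@labelMap)
  counters
})

#' Predict classes by counter voting
#'
#' The predicted class maximizes the branch counters. Ties are broken
#' by the larger mean corrected margin across the branch's base
#' classifiers, then by the smaller class index.
#'
#' @param object an [EnsembleModel-class].
#' @param newdata as in [counterVotes()].
#' @param type `"class"` (factor of original labels), `"code"`
#'   (integer 1..C) or `"counters"`.
#' @return predictions, one per sample.
#' @export
setMethod("predict", "EnsembleModel",
          function(object, newdata, type = c("class", "code", "counters")) {
  type <- match.arg(type)
  std <- .alignNewdata(object, newdata)
  sc <- .ensembleScores(object, std)
  if (type == "counters") {
    dimnames(sc$counters) <- list(colnames(std), object@labelMap)
    return(sc$counters)
  }
  codes <- vapply(seq_len(ncol(std)), function(s) {
    cnt <- sc$counters[s, ]
    cand <- which(cnt >= max(cnt) - 1e-12)
    if (length(cand) > 1) {
      mg <- sc$margins[s, cand]
      cand <- cand[mg >= max(mg) - 1e-12]
    }
    min(cand)
  }, 0L)
  if (type == "code") return(codes)
  factor(object@labelMap[codes], levels = object@labelMap)
})

#' @describeIn nClasses number of classes of a trained ensemble
#' @export
setMethod("nClasses", "EnsembleModel", function(x) x@nClasses)

#' @describeIn labelMap label mapping of a trained ensemble
#' @export
setMethod("labelMap", "EnsembleModel", function(x) x@labelMap)

setMethod("show", "EnsembleModel", function(object) {
  cat("EnsembleModel: ", object@nClasses, " OAA branches x ", object@L,
      " base SVMs, correction = ", object@correction, "\n",
      "  K = ", object@config$K, ", D = ", object@config$D, "\n", sep = "")
})
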