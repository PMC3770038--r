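#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' ExpressionDataset: an expression matrix with class labels
#'
#' Container for a gene-expression matrix (genes in rows, samples in
#' columns, the usual microarray orientation) together with one class
#' label per sample. Extends
#' [SummarizedExperiment::SummarizedExperiment]; the single assay is
#' named `"exprs"`, `colData` carries the integer class code (`class`,
#' recoded to 1..C) and the original label name (`className`), and the
#' code-to-name mapping is kept in `metadata()$labelMap`.
#'
#' Validity requires unique gene and sample identifiers, no missing
#' values, at least two classes, and at least one sample per class.
#'
#' @seealso [ExpressionDataset()], [readExpressionDataset()],
#'   [simulateExpressionDataset()]
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  v <- SummarizedExperiment::assay(object, "exprs")
  if (anyNA(v))
    msg <- c(msg, "expression values contain missing entries")
  if (!is.numeric(v))
    msg <- c(msg, "expression values must be numeric")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers must be present and unique")
  if (!"class" %in% colnames(SummarizedExperiment::colData(object))) {
    msg <- c(msg, "colData column 'class' is required")
  } else {
    cl <- object$class
    if (anyNA(cl)) msg <- c(msg, "class labels contain missing values")
    C <- length(unique(cl))
    if (C < 2) msg <- c(msg, "at least two classes are required")
    if (!all(sort(unique(cl)) == seq_len(C)))
      msg <- c(msg, "class codes must be contiguous integers 1..C")
  }
  if (length(msg)) msg else TRUE
})

#' FeatureSpace: the K genes selected for one binary branch
#'
#' Result of clustering all (non-constant) genes into K groups on a
#' 1 - Pearson-correlation distance and keeping the single gene with
#' the highest signal-to-noise ratio from each group. Feature subspaces
#' for the branch's base classifiers are drawn from this set.
#'
#' @slot geneIndices integer vector of K distinct gene indices into the
#'   source dataset, ordered by cluster id.
#' @slot K number of clusters (= number of selected genes).
#' @slot clusterAssignment integer vector over all genes of the source
#'   dataset; `NA` marks genes dropped as constant before clustering.
#' @slot snrScores SNR of each selected gene, parallel to `geneIndices`.
#'
#' @seealso [buildFeatureSpace()], [sampleFeatureSubspace()]
#' @export
setClass("FeatureSpace",
  representation(geneIndices = "integer", K = "integer",
                 clusterAssignment = "integer", snrScores = "numeric"))

setValidity("FeatureSpace", function(object) {
  msg <- character()
  if (length(object@geneIndices) != object@K)
    msg <- c(msg, "number of selected genes must equal K")
  if (anyDuplicated(object@geneIndices))
    msg <- c(msg, "selected gene indices must be distinct")
  if (length(object@snrScores) != object@K)
    msg <- c(msg, "snrScores must be parallel to geneIndices")
  cl <- object@clusterAssignment[object@geneIndices]
  if (!anyNA(cl) && anyDuplicated(cl))
    msg <- c(msg, "at most one selected gene per cluster")
  if (length(msg)) msg else TRUE
})

#' FeatureSubspace: a random D-gene subset of a feature space
#'
#' @slot geneIndices integer vector of D distinct gene indices, all
#'   members of the parent feature space.
#' @slot D subspace dimension.
#' @slot parentK size of the parent feature space.
#' @export
setClass("FeatureSubspace",
  representation(geneIndices = "integer", D = "integer", parentK = "integer"))

setValidity("FeatureSubspace", function(object) {
  msg <- character()
  if (length(object@geneIndices) != object@D)
    msg <- c(msg, "number of indices must equal D")
  if (anyDuplicated(object@geneIndices))
    msg <- c(msg, "indices must be distinct")
  if (object@D > object@parentK)
    msg <- c(msg, "D must not exceed the parent feature-space size K")
  if (length(msg)) msg else TRUE
})

#' CodeMatrix: a class-by-classifier coding matrix
#'
#' Rows are classes, columns binary subtasks; entries are +1 (class is
#' positive in that subtask), -1 (negative) or 0 (class does not
#' participate). One-against-all (OAA, C columns), one-against-one
#' (OAO, C(C-1)/2 columns) and exhaustive error-correcting output codes
#' (ECOC, 2^(C-1)-1 columns) are supported.
#'
#' @slot entries integer C x B matrix over \{+1, -1, 0\}.
#' @slot strategy one of `"OAA"`, `"OAO"`, `"ECOC"`.
#' @seealso [makeCodeMatrix()], [binarizeLabels()]
#' @export
setClass("CodeMatrix",
  representation(entries = "matrix", strategy = "character"))

setValidity("CodeMatrix", function(object) {
  msg <- character()
  M <- object@entries
  if (!all(M %in% c(-1L, 0L, 1L)))
    msg <- c(msg, "entries must be in {+1, -1, 0}")
  if (!all(apply(M, 2, function(col) any(col == 1) && any(col == -1))))
    msg <- c(msg, "every column needs at least one +1 and one -1")
  if (anyDuplicated(t(M)))
    msg <- c(msg, "duplicate columns are not allowed")
  if (!object@strategy %in% c("OAA", "OAO", "ECOC"))
    msg <- c(msg, "unknown strategy")
  if (length(msg)) msg else TRUE
})

#' ThresholdCorrection: an adjusted SVM decision threshold
#'
#' Holds theta = (m+ - m-)/(m+ + m- + 2) together with the class counts
#' it was computed from. The corrected decision value of a base
#' classifier is its raw margin minus theta.
#'
#' @slot theta the threshold, in (-1, 1).
#' @slot mPlus positive-class training count.
#' @slot mMinus negative-class training count.
#' @seealso [computeThreshold()], [applyThreshold()]
#' @export
setClass("ThresholdCorrection",
  representation(theta = "numeric", mPlus = "integer", mMinus = "integer"))

setValidity("ThresholdCorrection", function(object) {
  msg <- character()
  if (object@mPlus < 1L || object@mMinus < 1L)
    msg <- c(msg, "both class counts must be at least 1")
  expected <- (object@mPlus - object@mMinus) /
    (object@mPlus + object@mMinus + 2)
  if (!isTRUE(all.equal(object@theta, expected)))
    msg <- c(msg, "theta must equal (m+ - m-)/(m+ + m- + 2)")
  if (length(msg)) msg else TRUE
})

# One trained base learner: an RBF-kernel SVM on one feature subspace,
# with its correction. `flip` reorients libsvm's margin so that positive
# values always mean the branch's positive class.
setClass("BaseClassifier",
  representation(subspace = "FeatureSubspace", fit = "ANY",
                 theta = "numeric", flip = "logical",
                 cost = "numeric", sigma = "numeric"))

#' EnsembleModel: a trained counter-voting OAA SVM ensemble
#'
#' One branch per class; each branch holds its feature space and L base
#' classifiers trained on random feature subspaces, with the configured
#' imbalance correction applied inside every training subset. Per-gene
#' standardization constants fitted on the training data are stored so
#' prediction reproduces the training-time preprocessing.
#'
#' @slot branches list of length C; each element has the branch's
#'   `space` (a [FeatureSpace]) and `classifiers` (list of L base
#'   classifiers).
#' @slot nClasses number of classes C.
#' @slot L base classifiers per branch.
#' @slot correction `"thr"`, `"rus"` or `"none"`.
#' @slot labelMap character vector mapping class codes 1..C to the
#'   original label names.
#' @slot geneIds gene identifiers the model indexes into.
#' @slot center,scale per-gene standardization constants.
#' @slot config training configuration (K, D, cost, sigma, seed).
#' @slot version serialization format version.
#' @seealso [trainEnsemble()], [counterVotes()],
#'   [predict,EnsembleModel-method]
#' @export
setClass("EnsembleModel",
  representation(branches = "list", nClasses = "integer", L = "integer",
                 correction = "character", labelMap = "character",
                 geneIds = "character", center = "numeric",
                 scale = "numeric", config = "list", version = "integer"))

setValidity("EnsembleModel", function(object) {
  msg <- character()
  if (length(object@branches) != object@nClasses)
    msg <- c(msg, "one branch per class is required")
  nb <- vapply(object@branches, function(b) length(b$classifiers), 0L)
  if (any(nb != object@L))
    msg <- c(msg, "every branch must hold exactly L base classifiers")
  if (!object@correction %in% c("thr", "rus", "none"))
    msg <- c(msg, "unknown correction")
  if (length(msg)) msg else TRUE
})

#' MetricsReport: imbalance-aware multiclass classification metrics
#'
#' Per-class accuracies (recalls), one-vs-rest F-measures and class
#' proportions, plus the aggregates: weighted accuracy
#' Acc = sum_i Acc_i * P_i, F-score = mean_i F-measure_i, and
#' G-mean = (prod_i Acc_i)^(1/C).
#'
#' @slot perClassAccuracy,perClassPrecision,perClassFMeasure per-class
#'   values, length C.
#' @slot classProportions P_i, summing to 1.
#' @slot acc,fScore,gMean the aggregate metrics, all in \[0, 1\].
#' @seealso [multiclassMetrics()]
#' @export
setClass("MetricsReport",
  representation(perClassAccuracy = "numeric",
                 perClassPrecision = "numeric",
                 perClassFMeasure = "numeric",
                 classProportions = "numeric",
                 acc = "numeric", fScore = "numeric", gMean = "numeric"))

setValidity("MetricsReport", function(object) {
  msg <- character()
  vals <- c(object@perClassAccuracy, object@perClassFMeasure,
            object@acc, object@fScore, object@gMean)
  if (any(vals < -1e-12 | vals > 1 + 1e-12))
    msg <- c(msg, "all metric values must lie in [0, 1]")
  if (abs(sum(object@classProportions) - 1) > 1e-9)
    msg <- c(msg, "class proportions must sum to 1")
  if (length(msg)) msg else TRUE
})
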