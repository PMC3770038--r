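#' Configuration for the synthetic imbalanced expression generator
#'
#' Describes a multiclass dataset with planted structure: for each
#' class, `nInformativePerClass` genes whose mean is shifted by
#' `effectSize * noiseSd` in that class only; `nRedundantCopies`
#' correlated duplicates of every informative gene (the parent plus
#' small Gaussian jitter, so duplicate clusters are unambiguous); and
#' `nNoiseGenes` label-independent genes. The total gene count is
#' `nClasses * nInformativePerClass * (1 + nRedundantCopies) +
#' nNoiseGenes`.
#'
#' The defaults emulate a modest skewed microarray study: three classes
#' of 50/30/10 samples (imbalance ratio 5), 10 informative genes per
#' class with 4 redundant copies each, 350 noise genes (500 genes
#' total), a one-within-class-SD effect and unit noise.
#'
#' @param nClasses number of classes (>= 2); ignored when `classSizes`
#'   is given explicitly.
#' @param classSizes positive integer sample count per class, all >= 2
#'   so within-class SDs are defined.
#' @param nInformativePerClass informative genes planted per class.
#' @param nRedundantCopies correlated duplicates per informative gene.
#' @param nNoiseGenes label-independent genes.
#' @param effectSize mean shift of an informative gene in its target
#'   class, in units of `noiseSd`.
#' @param noiseSd within-class standard deviation of every gene.
#' @param seed integer seed making generation deterministic.
#' @return a validated `SyntheticConfig` list.
#' @seealso [simulateExpressionDataset()]
#' @export
syntheticConfig <- function(nClasses = 3L, classSizes = c(50L, 30L, 10L),
                            nInformativePerClass = 10L,
                            nRedundantCopies = 4L, nNoiseGenes = 350L,
                            effectSize = 1, noiseSd = 1, seed = 1L) {
  classSizes <- as.integer(classSizes)
  nClasses <- length(classSizes)
  if (nClasses < 2) stop("at least two classes are required")
  if (any(classSizes < 2))
    stop("every class needs at least 2 samples (per-class SD undefined)")
  if (nInformativePerClass < 1) stop("need at least one informative gene per class")
  if (nRedundantCopies < 0 || nNoiseGenes < 0) stop("counts must be non-negative")
  if (effectSize < 0) stop("effectSize must be non-negative")
  if (noiseSd <= 0) stop("noiseSd must be positive")
  structure(list(nClasses = nClasses, classSizes = classSizes,
                 nInformativePerClass = as.integer(nInformativePerClass),
                 nRedundantCopies = as.integer(nRedundantCopies),
                 nNoiseGenes = as.integer(nNoiseGenes),
                 effectSize = effectSize, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Simulate an imbalanced multiclass expression dataset
#'
#' Generates independent Gaussian genes (mean 0, SD `noiseSd`);
#' informative genes get a `effectSize * noiseSd` mean shift in their
#' target class, redundant copies are their parent gene plus Gaussian
#' jitter with SD `0.2 * noiseSd` (population correlation with the
#' parent about 0.98), and noise genes ignore the labels. Ground truth
#' is emitted in the dataset's `rowData` with columns `role`
#' (`informative`/`redundant`/`noise`), `targetClass` (NA for noise)
#' and `parent` (the parent gene id for redundant copies).
#'
#' @param config a [syntheticConfig()] object.
#' @return an [ExpressionDataset-class] with ground-truth `rowData`.
#' @examples
#' ds <- simulateExpressionDataset(syntheticConfig(classSizes = c(30, 10, 2)))
#' attr(datasetSummary(ds), "imbalanceRatio")  # 15
#' @export
simulateExpressionDataset <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  C <- config$nClasses
  n <- sum(config$classSizes)
  labels <- rep(seq_len(C), config$classSizes)
  sd0 <- config$noiseSd
  shift <- config$effectSize * sd0

  nInf <- C * config$nInformativePerClass
  nRed <- nInf * config$nRedundantCopies
  nGenes <- nInf + nRed + config$nNoiseGenes

  values <- matrix(0, nGenes, n)
  geneIds <- character(nGenes)
  role <- character(nGenes)
  targetClass <- rep(NA_integer_, nGenes)
  parent <- rep(NA_character_, nGenes)

  g <- 0L
  for (cls in seq_len(C)) {
    for (j in seq_len(config$nInformativePerClass)) {
      g <- g + 1L
      base <- stats::rnorm(n, 0, sd0) + shift * (labels == cls)
      values[g, ] <- base
      pid <- sprintf("inf_c%d_g%d", cls, j)
      geneIds[g] <- pid
      role[g] <- "informative"
      targetClass[g] <- cls
      for (r in seq_len(config$nRedundantCopies)) {
        g <- g + 1L
        values[g, ] <- base + stats::rnorm(n, 0, 0.2 * sd0)
        geneIds[g] <- sprintf("red_c%d_g%d_r%d", cls, j, r)
        role[g] <- "redundant"
        targetClass[g] <- cls
        parent[g] <- pid
      }
    }
  }
  if (config$nNoiseGenes > 0) {
    idx <- (g + 1L):nGenes
    values[idx, ] <- matrix(stats::rnorm(length(idx) * n, 0, sd0),
                            length(idx), n)
    geneIds[idx] <- sprintf("noise_%d", seq_along(idx))
    role[idx] <- "noise"
  }

  ExpressionDataset(values, geneIds = geneIds,
                    sampleIds = sprintf("sample_%d", seq_len(n)),
                    labels = sprintf("class_%d", labels),
                    rowData = data.frame(role = role,
                                         targetClass = targetClass,
                                         parent = parent))
}

#' Ground-truth gene annotation of a simulated dataset
#'
#' @param x an [ExpressionDataset-class] produced by
#'   [simulateExpressionDataset()].
#' @return data.frame with columns `gene_id`, `role`, `targetClass`,
#'   `parent`.
#' @export
geneTruth <- function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!"role" %in% colnames(rd))
    stop("dataset carries no ground-truth annotation")
  data.frame(gene_id = rownames(x), as.data.frame(rd))
}
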