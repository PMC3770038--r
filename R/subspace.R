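#' Pearson correlation between two gene profiles
#'
#' The gene-gene similarity used for redundancy clustering. Undefined
#' for constant profiles (zero denominator); such genes are filtered
#' before clustering, and this function fails loudly on them.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return correlation in \[-1, 1\].
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 2) stop("at least two samples are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation with a constant profile is undefined")
  stats::cor(x, y)
}

#' Group genes into K clusters by correlation
#'
#' Average-linkage hierarchical clustering on the distance
#' 1 - Pearson correlation, cut to exactly K clusters. Deterministic
#' for fixed input. All genes must be non-constant across the given
#' samples; constants are the caller's responsibility (see
#' [buildFeatureSpace()], which drops them first).
#'
#' @param values numeric matrix, genes in rows, (training) samples in
#'   columns.
#' @param K number of clusters, between 1 and the number of genes.
#' @return integer cluster assignment of length `nrow(values)` with
#'   values in 1..K; every cluster non-empty.
#' @export
clusterGenes <- function(values, K) {
  values <- as.matrix(values)
  K <- as.integer(K)
  if (K < 1) stop("K must be at least 1")
  if (K > nrow(values))
    stop("K (", K, ") exceeds the number of genes (", nrow(values), ")")
  sds <- apply(values, 1, stats::sd)
  if (any(sds == 0))
    stop("constant gene profile(s); filter before clustering")
  if (K == nrow(values)) return(seq_len(nrow(values)))
  cc <- stats::cor(t(values))
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  unname(stats::cutree(hc, k = K))
}

#' Signal-to-noise ratio of a gene for a binary task
#'
#' `|mu+ - mu-| / (sigma+ + sigma- + epsilon)` with population
#' (denominator n) standard deviations, the Golub-style filter score.
#' The small epsilon keeps zero-variance classes finite without
#' changing rankings. Invariant under affine maps `x -> a*x + b`
#' (a > 0) of the expression values.
#'
#' @param values numeric vector of expression values.
#' @param binaryLabels vector of +1/-1, both classes present.
#' @param epsilon denominator guard (default 1e-12).
#' @return non-negative score; zero iff the class means are equal.
#' @export
snrScore <- function(values, binaryLabels, epsilon = 1e-12) {
  pos <- binaryLabels > 0
  if (!any(pos) || all(pos)) stop("both classes must be present")
  popSd <- function(v) sqrt(mean((v - mean(v))^2))
  abs(mean(values[pos]) - mean(values[!pos])) /
    (popSd(values[pos]) + popSd(values[!pos]) + epsilon)
}

#' Build the feature space for one binary branch
#'
#' Constant genes (zero SD across the given samples) are dropped; the
#' remaining genes are clustered into K groups on 1 - Pearson
#' correlation (average linkage), and from each group the single gene
#' with the highest SNR for the binary task is kept. Ties in SNR are
#' broken by the smallest gene index. The K survivors form the feature
#' space from which random feature subspaces are drawn.
#'
#' @param values numeric matrix, genes in rows, training samples in
#'   columns.
#' @param binaryLabels +1/-1 per training sample.
#' @param K target feature-space size (number of clusters).
#' @param epsilon passed to [snrScore()].
#' @return a [FeatureSpace-class]; gene indices refer to rows of
#'   `values`.
#' @export
buildFeatureSpace <- function(values, binaryLabels, K, epsilon = 1e-12) {
  values <- as.matrix(values)
  K <- as.integer(K)
  if (length(binaryLabels) != ncol(values))
    stop("one binary label per sample is required")
  sds <- apply(values, 1, stats::sd)
  usable <- which(sds > 0)
  if (length(usable) < K)
    stop("only ", length(usable), " non-constant genes but K = ", K)

  clUsable <- clusterGenes(values[usable, , drop = FALSE], K)
  assignment <- rep(NA_integer_, nrow(values))
  assignment[usable] <- clUsable

  snr <- rep(NA_real_, nrow(values))
  snr[usable] <- apply(values[usable, , drop = FALSE], 1,
                       snrScore, binaryLabels = binaryLabels,
                       epsilon = epsilon)

  selected <- integer(K)
  for (k in seq_len(K)) {
    members <- usable[clUsable == k]
    best <- members[snr[members] == max(snr[members])]
    selected[k] <- min(best)   # deterministic tie-break
  }
  methods::new("FeatureSpace", geneIndices = selected, K = K,
               clusterAssignment = assignment,
               snrScores = snr[selected])
}

#' Draw a random feature subspace
#'
#' D distinct gene indices sampled uniformly without replacement from
#' the feature space (the random projection generating base-classifier
#' training subsets). Uses the current RNG state, so sampling is
#' deterministic under `set.seed()`.
#'
#' @param space a [FeatureSpace-class].
#' @param D subspace dimension, 1 <= D <= K.
#' @return a [FeatureSubspace-class].
#' @export
sampleFeatureSubspace <- function(space, D) {
  stopifnot(methods::is(space, "FeatureSpace"))
  D <- as.integer(D)
  if (D < 1) stop("D must be at least 1")
  if (D > space@K) stop("D (", D, ") exceeds K (", space@K, ")")
  idx <- sample(space@geneIndices, D, replace = FALSE)
  methods::new("FeatureSubspace", geneIndices = as.integer(idx),
               D = D, parentK = space@K)
}

#' Theoretical diversity between two feature subspaces
#'
#' `(K - D) / K`: the expected fraction of one subspace's genes absent
#' from an independently drawn one, the complement of the D/K
#' coselection rate. Large K relative to D guarantees ensemble
#' diversity.
#'
#' @param K feature-space size.
#' @param D subspace dimension, 0 <= D <= K.
#' @return value in \[0, 1\].
#' @export
theoreticalDiversity <- function(K, D) {
  if (D < 0 || D > K) stop("need 0 <= D <= K")
  (K - D) / K
}

#' @describeIn geneIndices selected gene indices of a feature space
#' @export
setMethod("geneIndices", "FeatureSpace", function(x) x@geneIndices)

#' @describeIn geneIndices gene indices of a feature subspace
#' @export
setMethod("geneIndices", "FeatureSubspace", function(x) x@geneIndices)

#' Per-selected-gene SNR scores
#' @param x a [FeatureSpace-class].
#' @rdname snrScores
#' @export
setMethod("snrScores", "FeatureSpace", function(x) x@snrScores)

#' Cluster assignment used to build a feature space
#' @param x a [FeatureSpace-class].
#' @return integer vector over all source genes (NA = dropped constant).
#' @rdname clusterAssignment
#' @export
setMethod("clusterAssignment", "FeatureSpace", function(x) x@clusterAssignment)

setMethod("show", "FeatureSpace", function(object) {
  cat("FeatureSpace: K =", object@K, "genes selected from",
      sum(!is.na(object@clusterAssignment)), "clustered genes\n")
})

setMethod("show", "FeatureSubspace", function(object) {
  cat("FeatureSubspace: D =", object@D, "of K =", object@parentK, "genes\n")
})
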