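#' Construct an ExpressionDataset
#'
#' @param values numeric matrix of expression values, genes in rows and
#'   samples in columns.
#' @param geneIds,sampleIds unique identifiers; taken from the matrix
#'   dimnames when omitted.
#' @param labels class label per sample. May be character, factor or
#'   integer; labels are recoded to contiguous integer codes 1..C by
#'   sorted order of the unique names, and the original names are kept
#'   in the dataset's label map.
#' @param rowData optional per-gene annotation (e.g. simulation ground
#'   truth), a `DataFrame` or data.frame with one row per gene.
#'
#' @return an [ExpressionDataset-class] object.
#' @examples
#' x <- matrix(rnorm(24), 4, 6,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
#' ds <- ExpressionDataset(x, labels = c(1, 1, 2, 2, 3, 3))
#' nClasses(ds)
#' @export
ExpressionDataset <- function(values, geneIds = rownames(values),
                              sampleIds = colnames(values), labels,
                              rowData = NULL) {
  values <- as.matrix(values)
  if (is.null(geneIds))
    stop("gene identifiers are required")
  if (is.null(sampleIds))
    stop("sample identifiers are required")
  if (length(geneIds) != nrow(values))
    stop("length of geneIds (", length(geneIds),
         ") does not match the number of genes (", nrow(values), ")")
  if (length(sampleIds) != ncol(values))
    stop("length of sampleIds (", length(sampleIds),
         ") does not match the number of samples (", ncol(values), ")")
  if (length(labels) != ncol(values))
    stop("number of labels (", length(labels),
         ") does not match the number of samples (", ncol(values), ")")
  if (anyNA(values))
    stop("expression values contain missing entries")
  if (!is.numeric(values))
    stop("non-numeric expression values")
  dimnames(values) <- list(as.character(geneIds), as.character(sampleIds))

  labelNames <- as.character(labels)
  map <- sort(unique(labelNames))
  codes <- match(labelNames, map)
  cd <- S4Vectors::DataFrame(class = codes, className = labelNames,
                             row.names = colnames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), colData = cd)
  if (!is.null(rowData))
    SummarizedExperiment::rowData(se) <- S4Vectors::DataFrame(rowData)
  S4Vectors::metadata(se)$labelMap <- map
  methods::new("ExpressionDataset", se)
}

#' Expression matrix of a dataset
#'
#' @param x an [ExpressionDataset-class].
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
exprsMatrix <- function(x) SummarizedExperiment::assay(x, "exprs")

#' Integer class codes (1..C) of the samples
#' @param x an [ExpressionDataset-class].
#' @return integer vector, one code per sample.
#' @rdname classCodes
#' @export
setMethod("classCodes", "ExpressionDataset",
          function(x) as.integer(x$class))

#' Mapping from class codes to original label names
#' @param x an [ExpressionDataset-class] or [EnsembleModel-class].
#' @return character vector; element i names class code i.
#' @rdname labelMap
#' @export
setMethod("labelMap", "ExpressionDataset",
          function(x) S4Vectors::metadata(x)$labelMap)

#' Number of classes
#' @param x an [ExpressionDataset-class] or [EnsembleModel-class].
#' @rdname nClasses
#' @export
setMethod("nClasses", "ExpressionDataset",
          function(x) length(unique(x$class)))

#' Imbalance ratio: largest class size over smallest class size
#' @param x an [ExpressionDataset-class].
#' @return numeric scalar, at least 1.
#' @rdname imbalanceRatio
#' @export
setMethod("imbalanceRatio", "ExpressionDataset", function(x) {
  n <- table(x$class)
  as.numeric(max(n) / min(n))
})

#' Summarize a dataset's class structure
#'
#' @param x an [ExpressionDataset-class].
#' @return a data.frame with one row per class (code, name, count,
#'   proportion), with the imbalance ratio, gene and sample counts
#'   attached as attributes `imbalanceRatio`, `nGenes`, `nSamples`.
#' @export
datasetSummary <- function(x) {
  stopifnot(methods::is(x, "ExpressionDataset"))
  counts <- as.integer(table(factor(x$class, levels = seq_len(nClasses(x)))))
  out <- data.frame(class = seq_len(nClasses(x)),
                    name = labelMap(x),
                    count = counts,
                    proportion = counts / sum(counts))
  attr(out, "imbalanceRatio") <- max(counts) / min(counts)
  attr(out, "nGenes") <- nrow(x)
  attr(out, "nSamples") <- ncol(x)
  out
}

setMethod("show", "ExpressionDataset", function(object) {
  counts <- table(object$class)
  cat("ExpressionDataset:", nrow(object), "genes x", ncol(object),
      "samples,", length(counts), "classes\n")
  cat("  class sizes: ", paste(as.integer(counts), collapse = ", "),
      " (imbalance ratio ",
      format(imbalanceRatio(object), digits = 4), ")\n", sep = "")
})
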