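#' Read an expression dataset from delimited-text files
#'
#' The expression matrix file must have a header row of sample
#' identifiers and, in the default genes-in-rows dialect, a first column
#' of gene identifiers (transposed for `samples-in-rows`). The labels
#' file has two columns, `sample_id` and `label`; it is matched to the
#' matrix by sample identifier, so row order need not agree.
#'
#' Labels are recoded to contiguous integer codes 1..C (sorted order of
#' unique names); the original names are kept in the dataset's label
#' map. Missing values are rejected unless `impute = TRUE`, in which
#' case they are replaced by the per-gene median.
#'
#' @param matrixPath path to the TSV/CSV expression matrix (delimiter
#'   chosen by extension: comma for `.csv`, tab otherwise).
#' @param labelsPath path to the two-column labels file.
#' @param orientation `"genes-in-rows"` (default, the common microarray
#'   convention) or `"samples-in-rows"`. Never guessed from shape.
#' @param impute replace missing expression values by the per-gene
#'   median instead of failing.
#' @return an [ExpressionDataset-class].
#' @seealso [writeExpressionDataset()]
#' @export
readExpressionDataset <- function(matrixPath, labelsPath,
                                  orientation = c("genes-in-rows",
                                                  "samples-in-rows"),
                                  impute = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(matrixPath)) stop("matrix file not found: ", matrixPath)
  if (!file.exists(labelsPath)) stop("labels file not found: ", labelsPath)
  sepOf <- function(p) if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"

  raw <- utils::read.table(matrixPath, header = TRUE, sep = sepOf(matrixPath),
                           check.names = FALSE, stringsAsFactors = FALSE,
                           row.names = 1, comment.char = "")
  values <- as.matrix(raw)
  if (!is.numeric(values)) {
    bad <- which(!vapply(raw, is.numeric, TRUE))
    stop("non-numeric expression values in column(s): ",
         paste(colnames(raw)[bad], collapse = ", "))
  }
  if (orientation == "samples-in-rows") values <- t(values)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in ", matrixPath)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in ", matrixPath)

  if (anyNA(values)) {
    if (!impute)
      stop("expression matrix contains missing values ",
           "(set impute = TRUE for per-gene median imputation)")
    for (i in which(rowSums(is.na(values)) > 0)) {
      med <- stats::median(values[i, ], na.rm = TRUE)
      if (is.na(med)) stop("gene ", rownames(values)[i], " is all-missing")
      values[i, is.na(values[i, ])] <- med
    }
  }

  lab <- utils::read.table(labelsPath, header = TRUE, sep = sepOf(labelsPath),
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  if (ncol(lab) < 2)
    stop("labels file must have columns sample_id and label")
  sampleIds <- as.character(lab[[1]])
  if (nrow(lab) != ncol(values))
    stop("label count (", nrow(lab), ") does not match sample count (",
         ncol(values), "); check the orientation flag")
  idx <- match(colnames(values), sampleIds)
  if (anyNA(idx))
    stop("sample identifiers missing from the labels file: ",
         paste(utils::head(colnames(values)[is.na(idx)], 5), collapse = ", "))
  ExpressionDataset(values, labels = lab[[2]][idx])
}

#' Write an expression dataset to delimited-text files
#'
#' Writes the genes-in-rows dialect read by [readExpressionDataset()]:
#' the matrix with gene identifiers in the first column and sample
#' identifiers in the header, and a two-column `sample_id`/`label`
#' file carrying the original label names.
#'
#' @param x an [ExpressionDataset-class].
#' @param matrixPath,labelsPath output paths (comma-delimited for
#'   `.csv`, tab otherwise).
#' @param digits significant digits for expression values (default 15,
#'   enough for a bit-faithful double round trip in practice).
#' @return invisibly, the two paths.
#' @export
writeExpressionDataset <- function(x, matrixPath, labelsPath, digits = 15) {
  stopifnot(methods::is(x, "ExpressionDataset"))
  sepOf <- function(p) if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
  v <- exprsMatrix(x)
  df <- data.frame(gene_id = rownames(v),
                   signif(v, digits), check.names = FALSE)
  utils::write.table(df, matrixPath, sep = sepOf(matrixPath),
                     quote = FALSE, row.names = FALSE)
  lab <- data.frame(sample_id = colnames(v),
                    label = labelMap(x)[classCodes(x)])
  utils::write.table(lab, labelsPath, sep = sepOf(labelsPath),
                     quote = FALSE, row.names = FALSE)
  invisible(c(matrixPath, labelsPath))
}
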