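#' @rdname geneIndices
#' @export
setGeneric("geneIndices", function(x) standardGeneric("geneIndices"))

#' @rdname snrScores
#' @export
setGeneric("snrScores", function(x) standardGeneric("snrScores"))

#' @rdname clusterAssignment
#' @export
setGeneric("clusterAssignment",
           function(x) standardGeneric("clusterAssignment"))

#' @rdname classCodes
#' @export
setGeneric("classCodes", function(x) standardGeneric("classCodes"))

#' @rdname labelMap
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' @rdname nClasses
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))

#' @rdname imbalanceRatio
#' @export
setGeneric("imbalanceRatio", function(x) standardGeneric("imbalanceRatio"))

#' @rdname codeEntries
#' @export
setGeneric("codeEntries", function(x) standardGeneric("codeEntries"))

#' @rdname counterVotes
#' @export
setGeneric("counterVotes",
           function(object, newdata, ...) standardGeneric("counterVotes"))
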