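#' @rdname ExpressionMatrix-class
#' @param x an object.
#' @export
setGeneric("featureClass", function(x) standardGeneric("featureClass"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("isLog2", function(x) standardGeneric("isLog2"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname ExpressionMatrix-class
setMethod("featureClass", "ExpressionMatrix", function(x) x@featureClass)

#' @rdname ExpressionMatrix-class
setMethod("isLog2", "ExpressionMatrix", function(x) x@isLog2)

#' @rdname ExpressionMatrix-class
setMethod("sampleGroups", "ExpressionMatrix",
          function(x) stats::setNames(as.character(x$group), colnames(x)))

#' @rdname TripartiteNetwork-class
#' @param x an object.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname TripartiteNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname TripartiteNetwork-class
setMethod("networkNodes", "TripartiteNetwork", function(x) x@nodes)

#' @rdname TripartiteNetwork-class
setMethod("networkEdges", "TripartiteNetwork", function(x) x@edges)

#' @rdname RWRProfile-class
#' @param x an object.
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))

#' @rdname RWRProfile-class
setMethod("probabilities", "RWRProfile", function(x) x@probabilities)
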