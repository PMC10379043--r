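#' @rdname MolecularGraph-accessors
#' @export
setGeneric("graphName", function(x) standardGeneric("graphName"))

#' @rdname MolecularGraph-accessors
#' @export
setGeneric("numVertices", function(x) standardGeneric("numVertices"))

#' @rdname MolecularGraph-accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname MolecularGraph-accessors
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' @rdname MolecularGraph-accessors
#' @export
setGeneric("degreeVector", function(x) standardGeneric("degreeVector"))

#' @rdname asIgraph
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname degreeEntropy
#' @export
setGeneric("degreeEntropy", function(x, k = 2) standardGeneric("degreeEntropy"))

#' @rdname functionalEntropy
#' @export
setGeneric("functionalEntropy", function(x, phi) standardGeneric("functionalEntropy"))

#' @rdname indexSuite
#' @export
setGeneric("indexSuite", function(x, k = 2) standardGeneric("indexSuite"))

#' @rdname canonicalCode
#' @export
setGeneric("canonicalCode", function(x) standardGeneric("canonicalCode"))

#' @rdname FitResult-accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @rdname FitResult-accessors
#' @export
setGeneric("residualSE", function(x) standardGeneric("residualSE"))

#' @rdname FitResult-accessors
#' @export
setGeneric("fStatistic", function(x) standardGeneric("fStatistic"))

#' @rdname FitResult-accessors
#' @export
setGeneric("fSignificance", function(x) standardGeneric("fSignificance"))

#' @rdname FitResult-accessors
#' @export
setGeneric("sampleSize", function(x) standardGeneric("sampleSize"))
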