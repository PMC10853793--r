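#' @rdname TwoClassExperiment-class
#' @param x,object a \code{TwoClassExperiment}.
#' @export
setGeneric("sampleClasses", function(x) standardGeneric("sampleClasses"))

#' @rdname TwoClassExperiment-class
#' @export
setGeneric("caseSamples", function(x) standardGeneric("caseSamples"))

#' @rdname TwoClassExperiment-class
#' @export
setGeneric("controlSamples", function(x) standardGeneric("controlSamples"))

#' @rdname GeneSet-class
#' @param x,object a \code{GeneSet} or \code{GeneSetCollection}.
#' @export
setGeneric("setId", function(x) standardGeneric("setId"))

#' @rdname GeneSet-class
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname GeneSetCollection-class
#' @param x a \code{GeneSetCollection}.
#' @export
setGeneric("setIds", function(x) standardGeneric("setIds"))

#' @rdname CoexpressionNetwork-class
#' @param x a \code{CoexpressionNetwork}.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname CoexpressionNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname CoexpressionNetwork-class
#' @export
setGeneric("excludedNodes", function(x) standardGeneric("excludedNodes"))

#' @rdname CoexpressionNetwork-class
#' @export
setGeneric("corThreshold", function(x) standardGeneric("corThreshold"))

#' @rdname GsceResult-class
#' @param x a \code{GsceResult}.
#' @export
setGeneric("degTable", function(x) standardGeneric("degTable"))

#' @rdname GsceResult-class
#' @export
setGeneric("network", function(x) standardGeneric("network"))

#' @rdname GsceResult-class
#' @export
setGeneric("listResults", function(x) standardGeneric("listResults"))

#' @rdname GsceResult-class
#' @export
setGeneric("geneResults", function(x) standardGeneric("geneResults"))

#' @rdname GsceResult-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
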