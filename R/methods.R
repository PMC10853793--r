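#' @rdname TwoClassExperiment-class
#' @export
setMethod("sampleClasses", "TwoClassExperiment", function(x) {
    cls <- as.character(colData(x)$class)
    names(cls) <- colnames(x)
    cls
})

#' @rdname TwoClassExperiment-class
#' @export
setMethod("caseSamples", "TwoClassExperiment", function(x) {
    colnames(x)[sampleClasses(x) == "case"]
})

#' @rdname TwoClassExperiment-class
#' @export
setMethod("controlSamples", "TwoClassExperiment", function(x) {
    colnames(x)[sampleClasses(x) == "control"]
})

setMethod("show", "TwoClassExperiment", function(object) {
    cls <- sampleClasses(object)
    cat("TwoClassExperiment with", nrow(object), "genes,",
        sum(cls == "control"), "control and",
        sum(cls == "case"), "case samples\n")
})

## expression matrix restricted to one class, genes x samples
.classMatrix <- function(x, class) {
    assay(x, 1L)[, sampleClasses(x) == class, drop = FALSE]
}

#' @rdname GeneSet-class
#' @export
setMethod("setId", "GeneSet", function(x) x@setId)

#' @rdname GeneSet-class
#' @export
setMethod("members", "GeneSet", function(x) x@members)

#' @rdname GeneSet-class
#' @export
setMethod("length", "GeneSet", function(x) length(x@members))

setMethod("show", "GeneSet", function(object) {
    cat("GeneSet", object@setId, "with", length(object@members), "members\n")
})

#' @rdname GeneSetCollection-class
#' @export
setMethod("setIds", "GeneSetCollection", function(x) {
    vapply(x@sets, slot, character(1), "setId")
})

#' @rdname GeneSetCollection-class
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @rdname GeneSetCollection-class
#' @export
setMethod("names", "GeneSetCollection", function(x) setIds(x))

#' @rdname GeneSetCollection-class
#' @param i index or set id.
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) {
    if (is.character(i)) {
        k <- match(i, setIds(x))
        if (is.na(k)) stop("no gene set with id '", i, "'")
        i <- k
    }
    x@sets[[i]]
})

#' @rdname GeneSetCollection-class
#' @param j,drop,... ignored.
#' @export
setMethod("[", "GeneSetCollection", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) {
        k <- match(i, setIds(x))
        if (anyNA(k))
            stop("no gene set with id '", i[which(is.na(k))[1L]], "'")
        i <- k
    }
    GeneSetCollection(x@sets[i])
})

setMethod("show", "GeneSetCollection", function(object) {
    n <- length(object)
    cat("GeneSetCollection of", n, "gene sets\n")
    if (n) {
        sizes <- vapply(object@sets, length, integer(1))
        cat("  set sizes:", min(sizes), "-", max(sizes), "\n")
    }
})

#' @rdname CoexpressionNetwork-class
#' @export
setMethod("networkNodes", "CoexpressionNetwork", function(x) x@nodes)

#' @rdname CoexpressionNetwork-class
#' @export
setMethod("networkEdges", "CoexpressionNetwork", function(x) x@edges)

#' @rdname CoexpressionNetwork-class
#' @export
setMethod("excludedNodes", "CoexpressionNetwork", function(x) x@excludedNodes)

#' @rdname CoexpressionNetwork-class
#' @export
setMethod("corThreshold", "CoexpressionNetwork", function(x) x@threshold)

setMethod("show", "CoexpressionNetwork", function(object) {
    cat("CoexpressionNetwork: ", length(object@nodes), " nodes, ",
        nrow(object@edges), " edges (|r| >= ", object@threshold, "); ",
        length(object@excludedNodes), " zero-variance gene(s) excluded\n",
        sep = "")
})

#' @rdname GsceResult-class
#' @export
setMethod("degTable", "GsceResult", function(x) x@degTable)

#' @rdname GsceResult-class
#' @export
setMethod("network", "GsceResult", function(x) x@network)

#' @rdname GsceResult-class
#' @export
setMethod("listResults", "GsceResult", function(x) x@listResults)

#' @rdname GsceResult-class
#' @export
setMethod("geneResults", "GsceResult", function(x) x@geneResults)

#' @rdname GsceResult-class
#' @export
setMethod("provenance", "GsceResult", function(x) x@provenance)

setMethod("show", "GsceResult", function(object) {
    nd <- sum(object@degTable$is_deg)
    nsig <- sum(object@listResults$significant, na.rm = TRUE)
    cat("GsceResult\n")
    cat("  DEGs:", nd, "of", nrow(object@degTable), "genes\n")
    show(object@network)
    cat("  list-level: ", nsig, " of ", nrow(object@listResults),
        " gene sets significant at q <= ",
        object@provenance$fdr_level, "\n", sep = "")
    cat("  gene-level rows:", nrow(object@geneResults), "\n")
})
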