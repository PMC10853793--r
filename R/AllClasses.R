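#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

.CLASS_LEVELS <- c("control", "case")

#' Two-class expression experiment
#'
#' A \linkS4class{SummarizedExperiment} whose columns carry a mandatory
#' \code{class} label, either \code{"control"} or \code{"case"}.  The single
#' assay holds log2-scale expression values (genes in rows, samples in
#' columns).  All downstream steps -- differential expression between the two
#' classes and coexpression-network construction on the case samples -- start
#' from this container.
#'
#' @slot ... inherited from \linkS4class{SummarizedExperiment}; the column
#'   data must contain a \code{class} column.
#'
#' @seealso [TwoClassExperiment()] for construction from a matrix,
#'   [readExpression()] for construction from files.
#' @exportClass TwoClassExperiment
setClass("TwoClassExperiment", contains = "SummarizedExperiment")

setValidity("TwoClassExperiment", function(object) {
    msg <- NULL
    cd <- colData(object)
    if (!"class" %in% colnames(cd))
        msg <- c(msg, "colData must contain a 'class' column")
    else {
        cls <- as.character(cd$class)
        bad <- setdiff(unique(cls), .CLASS_LEVELS)
        if (length(bad))
            msg <- c(msg, paste0("invalid sample class(es): ",
                                 paste(bad, collapse = ", ")))
        if (anyNA(cls))
            msg <- c(msg, "every sample must have a class")
    }
    if (length(SummarizedExperiment::assays(object)) < 1L)
        msg <- c(msg, "an expression assay is required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msg <- c(msg, "gene and sample ids are required (dimnames)")
    if (is.null(msg)) TRUE else msg
})

#' Construct a TwoClassExperiment
#'
#' @param values numeric matrix of expression values (genes x samples),
#'   log2 scale, with unique row and column names.
#' @param classes character vector giving each sample's class
#'   (\code{"control"} or \code{"case"}).  Either named by sample id or in
#'   column order of \code{values}.
#'
#' @return A [TwoClassExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' tce <- TwoClassExperiment(m, c(s1 = "control", s2 = "control",
#'                                s3 = "case", s4 = "case"))
#' caseSamples(tce)
#' @export
TwoClassExperiment <- function(values, classes) {
    values <- as.matrix(values)
    if (!is.numeric(values))
        stop("'values' must be a numeric matrix")
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("'values' must have row (gene) and column (sample) names")
    nm <- names(classes)
    classes <- as.character(classes)
    names(classes) <- nm
    if (!is.null(names(classes))) {
        missing <- setdiff(colnames(values), names(classes))
        if (length(missing))
            stop("no class label for sample(s): ",
                 paste(missing, collapse = ", "))
        classes <- classes[colnames(values)]
    } else if (length(classes) != ncol(values)) {
        stop("'classes' must be named or have one entry per sample")
    }
    se <- SummarizedExperiment(
        assays = list(log2expr = values),
        colData = DataFrame(class = unname(classes),
                            row.names = colnames(values)))
    new("TwoClassExperiment", se)
}

#' A named gene set
#'
#' An identifier, a free-text description and a non-empty set of unique
#' member gene ids, as parsed from one GMT line.
#'
#' @slot setId character(1), unique within a collection.
#' @slot description character(1) free text.
#' @slot members character vector of unique gene ids, non-empty.
#'
#' @seealso [readGmt()], [GeneSetCollection-class]
#' @exportClass GeneSet
setClass("GeneSet",
         representation(setId = "character",
                        description = "character",
                        members = "character"))

setValidity("GeneSet", function(object) {
    msg <- NULL
    if (length(object@setId) != 1L || !nzchar(object@setId))
        msg <- c(msg, "setId must be a single non-empty string")
    if (length(object@members) < 1L)
        msg <- c(msg, "members must be non-empty")
    if (anyDuplicated(object@members))
        msg <- c(msg, "members must be unique")
    if (is.null(msg)) TRUE else msg
})

#' Construct a GeneSet
#'
#' Duplicate members are removed, keeping first occurrence.
#'
#' @param setId set identifier.
#' @param members character vector of member gene ids.
#' @param description optional free text.
#' @return A [GeneSet-class] object.
#' @export
GeneSet <- function(setId, members, description = "") {
    new("GeneSet", setId = as.character(setId),
        description = as.character(description),
        members = unique(as.character(members)))
}

#' An ordered collection of gene sets
#'
#' Wraps a list of [GeneSet-class] objects with unique ids, preserving the
#' order of the source GMT file.  Supports \code{length}, \code{names},
#' \code{[[} (by position or by set id) and \code{[} (subsetting to a smaller
#' collection).
#'
#' @slot sets list of [GeneSet-class] objects.
#' @seealso [readGmt()]
#' @exportClass GeneSetCollection
setClass("GeneSetCollection", representation(sets = "list"))

setValidity("GeneSetCollection", function(object) {
    msg <- NULL
    if (!all(vapply(object@sets, is, logical(1), "GeneSet")))
        msg <- c(msg, "all elements must be GeneSet objects")
    else if (anyDuplicated(vapply(object@sets, slot, character(1), "setId")))
        msg <- c(msg, "set ids must be unique")
    if (is.null(msg)) TRUE else msg
})

#' Construct a GeneSetCollection
#'
#' @param sets list of [GeneSet-class] objects (possibly empty).
#' @return A [GeneSetCollection-class] object.
#' @export
GeneSetCollection <- function(sets = list()) {
    new("GeneSetCollection", sets = sets)
}

#' Case-sample coexpression network over DEGs
#'
#' An undirected graph whose nodes are the dataset's DEGs with non-constant
#' expression across case samples; an edge joins two DEGs whose Pearson
#' correlation over case samples satisfies \code{|r| >= c} (inclusive).
#' DEGs with identical expression across all case samples have no defined
#' correlation and are kept aside in \code{excludedNodes}: they remain
#' eligible members of pair universes (they contribute possible pairs) but
#' can never form a coexpressed pair.
#'
#' @slot nodes character vector of gene ids with defined correlations.
#' @slot edges data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{r}; \code{gene_a < gene_b} lexicographically.
#' @slot threshold the correlation cutoff c in (0, 1].
#' @slot excludedNodes gene ids dropped for zero variance across case
#'   samples.
#'
#' @seealso [buildNetwork()], [coexpressionNetwork()],
#'   [coexpressedPartners()]
#' @exportClass CoexpressionNetwork
setClass("CoexpressionNetwork",
         representation(nodes = "character",
                        edges = "data.frame",
                        threshold = "numeric",
                        excludedNodes = "character"))

setValidity("CoexpressionNetwork", function(object) {
    msg <- NULL
    e <- object@edges
    if (!all(c("gene_a", "gene_b", "r") %in% colnames(e)))
        msg <- c(msg, "edges need columns gene_a, gene_b, r")
    else if (nrow(e)) {
        if (any(e$gene_a == e$gene_b))
            msg <- c(msg, "self-edges are not allowed")
        if (any(!(e$gene_a %in% object@nodes) |
                !(e$gene_b %in% object@nodes)))
            msg <- c(msg, "edge endpoints must be nodes")
        if (any(abs(e$r) < object@threshold - 1e-12))
            msg <- c(msg, "all edges must satisfy |r| >= threshold")
        if (any(abs(e$r) > 1 + 1e-12))
            msg <- c(msg, "|r| must not exceed 1")
    }
    if (length(object@threshold) != 1L || object@threshold <= 0 ||
        object@threshold > 1)
        msg <- c(msg, "threshold must be a single value in (0, 1]")
    if (length(intersect(object@nodes, object@excludedNodes)))
        msg <- c(msg, "nodes and excludedNodes must be disjoint")
    if (is.null(msg)) TRUE else msg
})

#' Construct a CoexpressionNetwork from an edge list
#'
#' Mostly useful for importing a network computed elsewhere, or for building
#' small fixtures; [buildNetwork()] is the usual route.  Edge endpoint order
#' is canonicalised (\code{gene_a < gene_b}) and rows are sorted.
#'
#' @param edges data.frame with columns \code{gene_a}, \code{gene_b} and
#'   optionally \code{r} (defaults to 1 when absent).
#' @param nodes node ids; defaults to the ids appearing in \code{edges}.
#' @param threshold the correlation cutoff c used to build the edges.
#' @param excludedNodes ids of zero-variance genes (degree 0 by definition).
#' @return A [CoexpressionNetwork-class] object.
#' @export
coexpressionNetwork <- function(edges, nodes = NULL, threshold = 0.7,
                                excludedNodes = character()) {
    if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
        edges <- data.frame(gene_a = character(), gene_b = character(),
                            r = numeric(), stringsAsFactors = FALSE)
    } else {
        edges <- as.data.frame(edges, stringsAsFactors = FALSE)
        if (!"r" %in% colnames(edges)) edges$r <- 1
        a <- as.character(edges$gene_a); b <- as.character(edges$gene_b)
        swap <- a > b
        edges$gene_a <- ifelse(swap, b, a)
        edges$gene_b <- ifelse(swap, a, b)
        edges <- edges[order(edges$gene_a, edges$gene_b, method = "radix"),
                       c("gene_a", "gene_b", "r")]
        rownames(edges) <- NULL
    }
    if (is.null(nodes))
        nodes <- sort(unique(c(edges$gene_a, edges$gene_b)), method = "radix")
    new("CoexpressionNetwork", nodes = as.character(nodes), edges = edges,
        threshold = threshold, excludedNodes = as.character(excludedNodes))
}

#' Result bundle of a full gene set correlation enrichment run
#'
#' Holds everything [runGsce()] produces: the per-gene differential
#' expression table, the case-sample coexpression network, the list-level and
#' gene-level association tables and a provenance record (configuration and
#' software version) sufficient to reproduce the run.
#'
#' @slot degTable data.frame: gene_id, log2fc, t_stat, p_value, q_value,
#'   is_deg (one row per gene in the dataset).
#' @slot network the [CoexpressionNetwork-class] built on case samples.
#' @slot listResults association table for the query DEG list (one row per
#'   testable gene set).
#' @slot geneResults association table for each query DEG x gene set.
#' @slot provenance list of run parameters.
#'
#' @seealso [runGsce()], [writeGsceResult()]
#' @exportClass GsceResult
setClass("GsceResult",
         representation(degTable = "data.frame",
                        network = "CoexpressionNetwork",
                        listResults = "data.frame",
                        geneResults = "data.frame",
                        provenance = "list"))
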