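#' Pearson product-moment correlation
#'
#' Wrapper around [stats::cor()] with the preconditions the network
#' construction relies on: at least 3 paired observations and no constant
#' vector (a constant vector has no defined correlation; callers must
#' exclude such genes, see [buildNetwork()]).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in [-1, 1].
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3L) stop("need at least 3 paired observations")
    if (max(x) == min(x) || max(y) == min(y))
        stop("correlation undefined for a constant vector")
    stats::cor(x, y)
}

#' Build the case-sample coexpression network over DEGs
#'
#' Correlations are computed over \emph{case samples only}: the network is
#' meant to capture gene-gene dependencies in the disease state.  Two DEGs
#' are joined by an edge when their Pearson correlation across case samples
#' satisfies \code{|r| >= c} (inclusive).  DEGs with identical expression
#' across all case samples have no defined correlation; they are placed in
#' \code{excludedNodes} and get no edges, but remain eligible members of
#' pair universes downstream.
#'
#' @param dataset a [TwoClassExperiment-class] with >= 3 case samples.
#' @param degs character vector of DEG gene ids (subset of dataset genes).
#' @param c correlation threshold in (0, 1]; typical choices 0.3 (low),
#'   0.5 (moderate), 0.7 (high). Default 0.7.
#' @return A [CoexpressionNetwork-class].
#' @examples
#' sim <- generateDataset(simulationConfig(nGenes = 100, nDegs = 20,
#'                                         moduleSize = 10, seed = 7))
#' deg <- selectDegs(sim$dataset)
#' net <- buildNetwork(sim$dataset, deg$gene_id[deg$is_deg], c = 0.7)
#' net
#' @export
buildNetwork <- function(dataset, degs, c = 0.7) {
    stopifnot(is(dataset, "TwoClassExperiment"))
    if (!is.numeric(c) || length(c) != 1L || c <= 0 || c > 1)
        stop("'c' must be a single value in (0, 1]")
    degs <- as.character(degs)
    absent <- setdiff(degs, rownames(dataset))
    if (length(absent))
        stop("DEG(s) absent from the dataset: ",
             paste(absent, collapse = ", "))
    caseMat <- .classMatrix(dataset, "case")[degs, , drop = FALSE]
    if (ncol(caseMat) < 3L)
        stop("need at least 3 case samples to compute correlations")

    ## zero-variance rule: exactly constant across all case samples
    constant <- apply(caseMat, 1L, function(v) max(v) == min(v))
    excluded <- degs[constant]
    kept <- degs[!constant]

    if (length(kept) >= 2L) {
        r <- stats::cor(t(caseMat[kept, , drop = FALSE]))
        r[r > 1] <- 1; r[r < -1] <- -1          # guard fp overshoot
        hit <- which(abs(r) >= c & upper.tri(r), arr.ind = TRUE)
        edges <- data.frame(gene_a = kept[hit[, 1L]],
                            gene_b = kept[hit[, 2L]],
                            r = r[hit], stringsAsFactors = FALSE)
    } else {
        edges <- data.frame(gene_a = character(), gene_b = character(),
                            r = numeric(), stringsAsFactors = FALSE)
    }
    coexpressionNetwork(edges, nodes = kept, threshold = c,
                        excludedNodes = excluded)
}

## adjacency lookup: named list gene -> character vector of neighbors,
## covering every node and excluded node (empty for the latter)
.adjacency <- function(network) {
    all <- c(network@nodes, network@excludedNodes)
    adj <- vector("list", length(all))
    names(adj) <- all
    for (g in all) adj[[g]] <- character()
    e <- network@edges
    if (nrow(e)) {
        byA <- split(e$gene_b, e$gene_a)
        byB <- split(e$gene_a, e$gene_b)
        for (g in names(byA)) adj[[g]] <- c(adj[[g]], byA[[g]])
        for (g in names(byB)) adj[[g]] <- c(adj[[g]], byB[[g]])
    }
    adj
}

#' Neighbors of a gene in the coexpression network
#'
#' @param network a [CoexpressionNetwork-class].
#' @param gene a gene id among the network's nodes or excluded nodes.
#' @return character vector of coexpressed partner gene ids (empty for an
#'   excluded zero-variance gene).
#' @export
coexpressedPartners <- function(network, gene) {
    stopifnot(is(network, "CoexpressionNetwork"))
    if (!(gene %in% c(network@nodes, network@excludedNodes)))
        stop("unknown gene '", gene, "'")
    e <- network@edges
    sort(unique(c(e$gene_b[e$gene_a == gene], e$gene_a[e$gene_b == gene])),
         method = "radix")
}

#' Write network edges to TSV
#'
#' Columns \code{gene_a}, \code{gene_b}, \code{r} with
#' \code{gene_a < gene_b} lexicographically; r with 12 significant digits.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeNetworkEdges <- function(network, path) {
    e <- network@edges
    out <- data.frame(gene_a = e$gene_a, gene_b = e$gene_b,
                      r = sprintf("%.12g", e$r), stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}
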