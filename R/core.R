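#' Configuration of a gene set correlation enrichment run
#'
#' @param c Pearson correlation threshold for the coexpression network,
#'   in (0, 1]; 0.3 (low), 0.5 (moderate) and 0.7 (high) are the usual
#'   choices.  Default 0.7.
#' @param degConfig a [degConfig()] object controlling DEG calling
#'   (default: \code{degConfig()}).
#' @param fdrLevel FDR level at which associations are declared significant
#'   (default 0.05).
#' @param geneFamily BH family for the gene-level tests:
#'   \code{"per_gene"} (default) corrects each query DEG across gene sets
#'   separately; \code{"global"} corrects all (gene, set) tests jointly.
#' @param queryTopK optional integer: restrict the query list to the top-k
#'   DEGs by |log2 fold change| (ties by gene id).
#' @param background how the background counts (M, N) pool over gene sets:
#'   \code{"per_set_sum"} (default) sums each set's contribution, so a gene
#'   shared by two sets contributes two possible pairs and \code{n <= N} is
#'   guaranteed; \code{"dedup_union"} counts each distinct pair once
#'   (sensitivity-analysis alternative).
#' @return a list of class \code{"GsceConfig"}.
#' @export
gsceConfig <- function(c = 0.7, degConfig = NULL,
                       fdrLevel = 0.05,
                       geneFamily = c("per_gene", "global"),
                       queryTopK = NULL,
                       background = c("per_set_sum", "dedup_union")) {
    geneFamily <- match.arg(geneFamily)
    background <- match.arg(background)
    if (is.null(degConfig)) degConfig <- .defaultDegConfig()
    stopifnot(is.numeric(c), length(c) == 1L, c > 0, c <= 1,
              inherits(degConfig, "DEGConfig"),
              is.numeric(fdrLevel), length(fdrLevel) == 1L,
              fdrLevel > 0, fdrLevel < 1)
    if (!is.null(queryTopK)) {
        stopifnot(is.numeric(queryTopK), length(queryTopK) == 1L,
                  queryTopK >= 1)
        queryTopK <- as.integer(queryTopK)
    }
    structure(list(c = c, degConfig = degConfig, fdrLevel = fdrLevel,
                   geneFamily = geneFamily, queryTopK = queryTopK,
                   background = background),
              class = "GsceConfig")
}

#' DEG membership of a gene set
#'
#' The enrichment statistics only ever see the differentially expressed
#' members of a gene set: this returns the intersection of the set's members
#' with the dataset's full DEG set (not merely the query list).
#'
#' @param geneSet a [GeneSet-class].
#' @param datasetDegs character vector: all DEGs called in the dataset.
#' @return character vector of DEG members.
#' @export
setDegs <- function(geneSet, datasetDegs) {
    stopifnot(is(geneSet, "GeneSet"))
    intersect(members(geneSet), datasetDegs)
}

#' Upper-tail hypergeometric P value on pair counts
#'
#' The association statistic: with N possible gene pairs in the background of
#' which M are coexpressed, and n possible pairs drawn for the query, the P
#' value is \code{P(X >= m)} for X hypergeometric -- the chance of seeing at
#' least the observed number of coexpressed pairs.  Computed via
#' [stats::phyper()] (log-gamma based, stable for large N); exactly 1 at
#' \code{m = 0}; clipped to \code{[1e-300, 1]}.
#'
#' @param m observed coexpressed pairs for the query/set, \code{0 <= m}.
#' @param n possible pairs for the query/set, \code{m <= n <= N}.
#' @param M coexpressed pairs in the background, \code{m <= M <= N}.
#' @param N possible pairs in the background, \code{N >= 1}.
#' @return P value in [0, 1].
#' @examples
#' hypergeomUpperTail(1, 1, 3, 10)  # single draw: M/N = 0.3
#' @export
hypergeomUpperTail <- function(m, n, M, N) {
    stopifnot(length(m) == 1L, length(n) == 1L, length(M) == 1L,
              length(N) == 1L)
    if (any(c(m, n, M, N) %% 1 != 0) || m < 0 || n < 1 || N < 1)
        stop("counts must be non-negative integers with n >= 1, N >= 1")
    if (m > n || n > N || m > M || M > N)
        stop("pair-count invariants violated: need m <= n <= N and ",
             "m <= M <= N (got m=", m, ", n=", n, ", M=", M, ", N=", N, ")")
    if (m == 0) return(1)
    p <- stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
    min(max(p, 1e-300), 1)
}

## ---- internal: indexed pair counting -------------------------------------
## Work in integer indices over the dataset DEG vector; precompute per-set
## DEG membership and the adjacency structure once per run.

.pairContext <- function(collection, datasetDegs, network) {
    stopifnot(is(collection, "GeneSetCollection"),
              is(network, "CoexpressionNetwork"))
    datasetDegs <- as.character(datasetDegs)
    adj <- .adjacency(network)
    known <- names(adj)
    if (length(setdiff(datasetDegs, known)))
        stop("dataset DEG(s) absent from the network: ",
             paste(utils::head(setdiff(datasetDegs, known), 5L),
                   collapse = ", "))
    setsDegs <- lapply(collection@sets, function(s)
        intersect(s@members, datasetDegs))
    names(setsDegs) <- setIds(collection)
    list(degs = datasetDegs, setsDegs = setsDegs, adj = adj)
}

## per-set (n, m) for a single query gene across every set in the context
.geneCountsAll <- function(gene, ctx) {
    nbr <- ctx$adj[[gene]]
    n <- integer(length(ctx$setsDegs))
    m <- integer(length(ctx$setsDegs))
    for (k in seq_along(ctx$setsDegs)) {
        u <- setdiff(ctx$setsDegs[[k]], gene)    # self-pair excluded
        n[k] <- length(u)
        m[k] <- sum(u %in% nbr)
    }
    list(n = n, m = m)
}

## per-set (n_g, m_g) for a query list L across every set in the context.
## Unordered pairs {a, x}, a in L, x in S', a != x, each counted once:
## n_g = |L||S'| - k - choose(k, 2) with k = |L intersect S'|;
## m_g = sum_a |adj(a) ∩ S'\{a}|  minus edges counted twice (both ends in
## L ∩ S').
.listCountsAll <- function(degList, ctx) {
    L <- unique(degList)
    nSets <- length(ctx$setsDegs)
    n <- integer(nSets); m <- integer(nSets)
    for (j in seq_len(nSets)) {
        S <- ctx$setsDegs[[j]]
        k <- length(intersect(L, S))
        n[j] <- as.integer(length(L) * length(S) - k -
                           (k * (k - 1L)) %/% 2L)
        tot <- 0L; dup <- 0L
        for (a in L) {
            nbrInS <- sum(ctx$adj[[a]] %in% S)   # a never in adj[[a]]
            tot <- tot + nbrInS
            if (a %in% S)
                dup <- dup + sum(ctx$adj[[a]] %in% intersect(L, S))
        }
        m[j] <- as.integer(tot - dup %/% 2L)
    }
    list(n = n, m = m)
}

## distinct-pair background (dedup_union) for a query gene: possible pairs
## are (gene, x) for x in the union of set DEG memberships minus the gene.
.geneBackgroundUnion <- function(gene, ctx) {
    u <- setdiff(unique(unlist(ctx$setsDegs, use.names = FALSE)), gene)
    list(N = length(u), M = sum(u %in% ctx$adj[[gene]]))
}

## distinct-pair background for a query list: each unordered pair {a, x}
## with a in L, x in some S', a != x counted once across all sets.
.listBackgroundUnion <- function(degList, ctx) {
    L <- unique(degList)
    keys <- character(0)
    for (S in ctx$setsDegs) {
        if (!length(S)) next
        g <- expand.grid(a = L, x = S, stringsAsFactors = FALSE)
        g <- g[g$a != g$x, , drop = FALSE]
        keys <- c(keys, paste(pmin(g$a, g$x), pmax(g$a, g$x), sep = "\r"))
    }
    keys <- unique(keys)
    if (!length(keys)) return(list(N = 0L, M = 0L))
    e <- data.frame(do.call(rbind, strsplit(keys, "\r", fixed = TRUE)),
                    stringsAsFactors = FALSE)
    isEdge <- mapply(function(a, b) b %in% ctx$adj[[a]], e[[1L]], e[[2L]])
    list(N = length(keys), M = sum(isEdge))
}

#' Pair counts between one query DEG and a gene set
#'
#' The per-set universe is the set of unordered pairs (gene, x) with x a DEG
#' member of the set other than the gene itself; \code{n} is its size and
#' \code{m} the number of those pairs that are coexpression-network edges.
#' The background \code{N, M} pools the same quantities over every set in
#' the collection (per-set sum by default; see [gsceConfig()]).
#'
#' @param gene a dataset DEG (query gene).
#' @param geneSet the [GeneSet-class] being tested.
#' @param collection the full [GeneSetCollection-class] (background).
#' @param datasetDegs character vector of all dataset DEGs.
#' @param network the case-sample [CoexpressionNetwork-class].
#' @param background \code{"per_set_sum"} or \code{"dedup_union"}.
#' @return list with integers \code{m, n, M, N}.
#' @examples
#' net <- coexpressionNetwork(
#'     data.frame(gene_a = "a", gene_b = c("g1", "g2", "g3")),
#'     nodes = c("a", paste0("g", 1:5)))
#' gs <- GeneSet("SetA", paste0("g", 1:5))
#' pairCountsGene("a", gs, GeneSetCollection(list(gs)),
#'                c("a", paste0("g", 1:5)), net)
#' @export
pairCountsGene <- function(gene, geneSet, collection, datasetDegs, network,
                           background = c("per_set_sum", "dedup_union")) {
    background <- match.arg(background)
    stopifnot(is(geneSet, "GeneSet"))
    if (!gene %in% datasetDegs)
        stop("query gene '", gene, "' is not a dataset DEG")
    ctx <- .pairContext(collection, datasetDegs, network)
    counts <- .geneCountsAll(gene, ctx)
    k <- match(setId(geneSet), names(ctx$setsDegs))
    if (is.na(k)) stop("gene set '", setId(geneSet),
                       "' is not in the collection")
    bg <- if (background == "per_set_sum")
        list(N = sum(counts$n), M = sum(counts$m))
    else .geneBackgroundUnion(gene, ctx)
    list(m = counts$m[k], n = counts$n[k], M = bg$M, N = bg$N)
}

#' Pair counts between a query DEG list and a gene set
#'
#' The universe is the set of unordered pairs {a, x} with a in the query
#' list L and x a DEG member of the set, a != x, each pair counted once.
#' With k genes shared between list and set this gives
#' \code{n_g = |L||S'| - k - choose(k, 2)}; \code{m_g} counts the universe
#' pairs that are network edges.  Background \code{N_g, M_g} pools over the
#' collection as in [pairCountsGene()].
#'
#' @param degList character vector of query DEGs (subset of
#'   \code{datasetDegs}, non-empty).
#' @inheritParams pairCountsGene
#' @return list with integers \code{m, n, M, N} (list-level counts).
#' @export
pairCountsList <- function(degList, geneSet, collection, datasetDegs,
                           network,
                           background = c("per_set_sum", "dedup_union")) {
    background <- match.arg(background)
    stopifnot(is(geneSet, "GeneSet"))
    degList <- as.character(degList)
    if (!length(degList)) stop("query DEG list is empty")
    if (length(setdiff(degList, datasetDegs)))
        stop("query list gene(s) not among dataset DEGs: ",
             paste(utils::head(setdiff(degList, datasetDegs), 5L),
                   collapse = ", "))
    ctx <- .pairContext(collection, datasetDegs, network)
    counts <- .listCountsAll(degList, ctx)
    k <- match(setId(geneSet), names(ctx$setsDegs))
    if (is.na(k)) stop("gene set '", setId(geneSet),
                       "' is not in the collection")
    bg <- if (background == "per_set_sum")
        list(N = sum(counts$n), M = sum(counts$m))
    else .listBackgroundUnion(degList, ctx)
    list(m = counts$m[k], n = counts$n[k], M = bg$M, N = bg$N)
}

## assemble an association table from per-set counts for one query
.assocTable <- function(queryId, setIds, counts, bg) {
    data.frame(query_id = queryId, set_id = setIds,
               m = counts$m, n = counts$n, M = bg$M, N = bg$N,
               p_value = NA_real_, q_value = NA_real_, significant = NA,
               stringsAsFactors = FALSE)
}

## fill p values for testable rows (n >= 1)
.fillP <- function(df) {
    testable <- which(df$n >= 1L & df$N >= 1L)
    df$p_value[testable] <- vapply(testable, function(i)
        hypergeomUpperTail(df$m[i], df$n[i], df$M[i], df$N[i]), numeric(1))
    df
}

## BH within the given row groups; untestable rows keep NA
.fillQ <- function(df, groups, fdrLevel) {
    testable <- !is.na(df$p_value)
    for (g in split(which(testable), groups[testable])) {
        df$q_value[g] <- benjaminiHochberg(df$p_value[g])
    }
    df$significant <- ifelse(is.na(df$q_value), NA,
                             df$q_value <= fdrLevel)
    df
}

#' Gene-level association of query DEGs with each gene set
#'
#' For each query DEG and each gene set with at least one possible pair, an
#' upper-tail hypergeometric P value on the pair counts of
#' [pairCountsGene()], BH-corrected over the family chosen in the
#' configuration (default: all sets for that gene), significant when
#' \code{q <= fdrLevel}.  Sets with no possible pair (\code{n = 0}) are
#' reported with \code{NA} p and q and excluded from the BH family.
#'
#' @param genes character vector of query DEGs (each must be a dataset DEG).
#' @param collection a [GeneSetCollection-class].
#' @param datasetDegs all DEGs called in the dataset.
#' @param network the case-sample [CoexpressionNetwork-class].
#' @param config a [gsceConfig()] object.
#' @return association data.frame, one row per (gene, set): columns
#'   \code{query_id, set_id, m, n, M, N, p_value, q_value, significant}.
#' @export
geneAssociation <- function(genes, collection, datasetDegs, network,
                            config = gsceConfig()) {
    stopifnot(inherits(config, "GsceConfig"))
    genes <- as.character(genes)
    if (length(setdiff(genes, datasetDegs)))
        stop("query gene(s) not among dataset DEGs: ",
             paste(utils::head(setdiff(genes, datasetDegs), 5L),
                   collapse = ", "))
    ctx <- .pairContext(collection, datasetDegs, network)
    ids <- names(ctx$setsDegs)
    tabs <- lapply(genes, function(g) {
        counts <- .geneCountsAll(g, ctx)
        bg <- if (config$background == "per_set_sum") {
            b <- list(N = sum(counts$n), M = sum(counts$m))
            stopifnot(sum(counts$n) == b$N)      # background consistency
            b
        } else .geneBackgroundUnion(g, ctx)
        df <- .assocTable(g, ids, counts, bg)
        if (all(df$n == 0L))
            warning("gene '", g, "': no testable gene set (all n = 0)")
        .fillP(df)
    })
    df <- do.call(rbind, tabs)
    groups <- if (config$geneFamily == "per_gene") df$query_id
              else rep("global", nrow(df))
    .fillQ(df, groups, config$fdrLevel)
}

#' List-level association of the query DEG list with each gene set
#'
#' One upper-tail hypergeometric test per gene set on the pair counts of
#' [pairCountsList()], BH-corrected across the collection's testable sets,
#' significant when \code{q <= fdrLevel}.
#'
#' @param degList character vector of query DEGs, non-empty.
#' @inheritParams geneAssociation
#' @param listLabel label used in the \code{query_id} column.
#' @return association data.frame, one row per gene set.
#' @export
listAssociation <- function(degList, collection, datasetDegs, network,
                            config = gsceConfig(), listLabel = "DEG_list") {
    stopifnot(inherits(config, "GsceConfig"))
    degList <- as.character(degList)
    if (!length(degList)) stop("query DEG list is empty")
    if (length(setdiff(degList, datasetDegs)))
        stop("query list gene(s) not among dataset DEGs: ",
             paste(utils::head(setdiff(degList, datasetDegs), 5L),
                   collapse = ", "))
    ctx <- .pairContext(collection, datasetDegs, network)
    counts <- .listCountsAll(degList, ctx)
    bg <- if (config$background == "per_set_sum") {
        b <- list(N = sum(counts$n), M = sum(counts$m))
        stopifnot(sum(counts$n) == b$N)          # background consistency
        b
    } else .listBackgroundUnion(degList, ctx)
    df <- .assocTable(listLabel, names(ctx$setsDegs), counts, bg)
    if (all(df$n == 0L))
        warning("no testable gene set for the query list (all n = 0)")
    df <- .fillP(df)
    .fillQ(df, rep("list", nrow(df)), config$fdrLevel)
}

#' Run the full gene set correlation enrichment analysis
#'
#' Orchestrates the pipeline: DEG calling (or a precomputed query list),
#' case-sample coexpression network at the configured threshold, optional
#' restriction of the query list to the top-k DEGs by |log2 fold change|,
#' and both association levels.  For statistically meaningful correlations
#' and tests, the control and case classes should have at least 3 and 5
#' samples respectively; smaller classes are an error unless
#' \code{strict = FALSE}, which downgrades the check to a warning.
#'
#' @param dataset a [TwoClassExperiment-class].
#' @param collection a [GeneSetCollection-class].
#' @param config a [gsceConfig()] object.
#' @param query optional precomputed DEG list (character); when given, DEG
#'   status is taken from it (every id must be in the dataset) and
#'   differential statistics are still computed for the record.
#' @param strict enforce the minimum class sizes (default TRUE).
#' @param listLabel label for the query list in result tables.
#' @return A [GsceResult-class].
#' @examples
#' sim <- generateDataset(simulationConfig(nGenes = 300, nDegs = 30,
#'                                         moduleSize = 10,
#'                                         plantedSetOverlap = 8,
#'                                         nSets = 10, seed = 42))
#' res <- runGsce(sim$dataset, sim$collection)
#' head(listResults(res))
#' @export
runGsce <- function(dataset, collection, config = gsceConfig(),
                    query = NULL, strict = TRUE, listLabel = "DEG_list") {
    stopifnot(is(dataset, "TwoClassExperiment"),
              is(collection, "GeneSetCollection"),
              inherits(config, "GsceConfig"))
    cls <- sampleClasses(dataset)
    nCtrl <- sum(cls == "control"); nCase <- sum(cls == "case")
    if (nCtrl < 3L || nCase < 5L) {
        msg <- paste0("class sizes below the recommended minimum of 3 ",
                      "control and 5 case samples (got ", nCtrl,
                      " control, ", nCase, " case)")
        if (strict) stop(msg, "; use strict = FALSE to proceed anyway")
        warning(msg)
    }

    degCfg <- config$degConfig
    if (!is.null(query)) {
        degCfg$mode <- "precomputed"
        degTab <- selectDegs(dataset, degCfg, degList = query)
    } else {
        degTab <- selectDegs(dataset, degCfg)
    }
    datasetDegs <- degTab$gene_id[degTab$is_deg]
    if (!length(datasetDegs))
        stop("no DEGs called; nothing to test")

    queryList <- if (!is.null(query)) as.character(query) else
        rankDegsByFoldChange(degTab)
    if (!is.null(config$queryTopK)) {
        sub <- degTab[degTab$gene_id %in% queryList, , drop = FALSE]
        queryList <- utils::head(rankDegsByFoldChange(sub),
                                 config$queryTopK)
    }

    net <- buildNetwork(dataset, datasetDegs, config$c)
    listRes <- listAssociation(queryList, collection, datasetDegs, net,
                               config, listLabel = listLabel)
    geneRes <- geneAssociation(queryList, collection, datasetDegs, net,
                               config)

    prov <- list(
        package = "gsce",
        version = as.character(utils::packageVersion("gsce")),
        threshold_c = config$c,
        deg_mode = degCfg$mode,
        deg_config = unclass(degCfg),
        fdr_level = config$fdrLevel,
        gene_family = config$geneFamily,
        background = config$background,
        query_top_k = config$queryTopK,
        strict = strict,
        n_genes = nrow(dataset),
        n_control = nCtrl, n_case = nCase,
        n_sets = length(collection),
        n_degs = length(datasetDegs),
        query_size = length(queryList),
        precomputed_query = !is.null(query))

    new("GsceResult", degTable = degTab, network = net,
        listResults = listRes, geneResults = geneRes, provenance = prov)
}

#' Write a GsceResult to a directory
#'
#' Writes \code{deg_table.tsv}, \code{network_edges.tsv},
#' \code{list_associations.tsv}, \code{gene_associations.tsv} and
#' \code{run_provenance.json}.  All numeric columns use 12 significant
#' digits, and row orders are deterministic, so two runs on the same input
#' produce byte-identical tables.
#'
#' @param result a [GsceResult-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the directory path.
#' @export
writeGsceResult <- function(result, dir) {
    stopifnot(is(result, "GsceResult"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    deg <- degTable(result)
    degOut <- data.frame(
        gene_id = deg$gene_id,
        log2fc = sprintf("%.12g", deg$log2fc),
        t_stat = sprintf("%.12g", deg$t_stat),
        p_value = sprintf("%.12g", deg$p_value),
        q_value = sprintf("%.12g", deg$q_value),
        is_deg = deg$is_deg, stringsAsFactors = FALSE)
    utils::write.table(degOut, file.path(dir, "deg_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = TRUE)
    writeNetworkEdges(network(result), file.path(dir, "network_edges.tsv"))
    writeAssociationTable(listResults(result),
                          file.path(dir, "list_associations.tsv"))
    writeAssociationTable(geneResults(result),
                          file.path(dir, "gene_associations.tsv"))
    jsonlite::write_json(provenance(result),
                         file.path(dir, "run_provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    invisible(dir)
}
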