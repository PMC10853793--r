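#' Configuration of the synthetic two-class expression generator
#'
#' The defaults are the reference simulation settings used throughout the
#' package's benchmark: 1000 genes, 10 control and 50 case samples, 100
#' planted DEGs with a +1.5 log2 mean shift in case samples, a 20-gene
#' coexpression module at target within-module correlation 0.8, and 50 gene
#' sets of 15-40 genes of which one (the planted set) contains 15 module
#' genes.
#'
#' @param nGenes total genes.
#' @param nControl,nCase samples per class.
#' @param nDegs planted DEGs (mean-shifted in case samples).
#' @param degShift log2 mean shift added to DEGs in case samples.
#' @param moduleSize number of DEGs forming the coexpressed module
#'   (\code{moduleSize <= nDegs}).
#' @param moduleR target pairwise within-module correlation in case samples,
#'   in [0, 1).
#' @param nSets gene sets generated.
#' @param setSizeRange integer pair: inclusive range of set sizes.
#' @param plantedSetOverlap module genes placed into the planted set
#'   (\code{<= moduleSize}).
#' @param noiseSd standard deviation of the log2 expression noise.
#' @param seed RNG seed making the dataset fully reproducible.
#' @return a list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nGenes = 1000L, nControl = 10L, nCase = 50L,
                             nDegs = 100L, degShift = 1.5,
                             moduleSize = 20L, moduleR = 0.8,
                             nSets = 50L, setSizeRange = c(15L, 40L),
                             plantedSetOverlap = 15L, noiseSd = 1,
                             seed = 20240101L) {
    cfg <- list(nGenes = as.integer(nGenes), nControl = as.integer(nControl),
                nCase = as.integer(nCase), nDegs = as.integer(nDegs),
                degShift = degShift, moduleSize = as.integer(moduleSize),
                moduleR = moduleR, nSets = as.integer(nSets),
                setSizeRange = as.integer(setSizeRange),
                plantedSetOverlap = as.integer(plantedSetOverlap),
                noiseSd = noiseSd, seed = as.integer(seed))
    with(cfg, {
        stopifnot(nGenes >= 2, nControl >= 2, nCase >= 3,
                  nDegs >= 1, nDegs <= nGenes,
                  moduleSize >= 0, moduleSize <= nDegs,
                  moduleR >= 0, moduleR < 1,
                  nSets >= 1, length(setSizeRange) == 2,
                  setSizeRange[1] >= 1, setSizeRange[1] <= setSizeRange[2],
                  setSizeRange[2] <= nGenes,
                  plantedSetOverlap >= 0, plantedSetOverlap <= moduleSize,
                  noiseSd > 0)
    })
    structure(cfg, class = "SimulationConfig")
}

#' Generate a synthetic two-class dataset with planted ground truth
#'
#' Background genes are independent Normal(7, noiseSd) on the log2 scale in
#' both classes.  Planted DEGs get \code{+degShift} in case samples.  The
#' first \code{moduleSize} DEGs additionally share, in case samples, a
#' single latent factor: per case sample s with factor value f_s, a module
#' gene's noise term is \code{sqrt(moduleR) * f_s + sqrt(1 - moduleR) * e},
#' the equicorrelated construction with pairwise correlation
#' \code{moduleR}.  One gene set (the planted set) contains
#' \code{plantedSetOverlap} module genes plus random fill; the remaining
#' sets are uniform random draws from all genes, so null sets contain DEGs
#' at roughly the dataset's DEG proportion.
#'
#' @param config a [simulationConfig()] object.
#' @return list with elements \code{dataset}
#'   ([TwoClassExperiment-class]), \code{collection}
#'   ([GeneSetCollection-class]) and \code{truth} (list with
#'   \code{trueDegs}, \code{moduleGenes}, \code{plantedSetId}).
#' @examples
#' sim <- generateDataset(simulationConfig(nGenes = 100, nDegs = 10,
#'                                         moduleSize = 5,
#'                                         plantedSetOverlap = 4,
#'                                         nSets = 5, seed = 1))
#' sim$truth$plantedSetId
#' @export
generateDataset <- function(config = simulationConfig()) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    mu0 <- 7
    geneIds <- sprintf("g%05d", seq_len(config$nGenes))
    sampleIds <- c(sprintf("ctrl%03d", seq_len(config$nControl)),
                   sprintf("case%03d", seq_len(config$nCase)))
    classes <- stats::setNames(
        rep(c("control", "case"), c(config$nControl, config$nCase)),
        sampleIds)

    vals <- matrix(stats::rnorm(config$nGenes * length(sampleIds),
                                mean = mu0, sd = config$noiseSd),
                   nrow = config$nGenes,
                   dimnames = list(geneIds, sampleIds))
    isCase <- classes == "case"

    trueDegs <- sample(geneIds, config$nDegs)
    moduleGenes <- trueDegs[seq_len(config$moduleSize)]
    vals[trueDegs, isCase] <- vals[trueDegs, isCase] + config$degShift

    if (config$moduleSize >= 1L) {
        rho <- config$moduleR
        f <- stats::rnorm(config$nCase)          # shared latent factor
        eps <- matrix(stats::rnorm(config$moduleSize * config$nCase),
                      nrow = config$moduleSize)
        noise <- sqrt(rho) * matrix(f, config$moduleSize, config$nCase,
                                    byrow = TRUE) + sqrt(1 - rho) * eps
        vals[moduleGenes, isCase] <-
            mu0 + config$degShift + config$noiseSd * noise
    }

    ## gene sets: ids in random order so the planted set's position is
    ## arbitrary; planted set = module overlap + random fill
    setIds <- sprintf("set%03d", seq_len(config$nSets))
    plantedSetId <- sample(setIds, 1L)
    sets <- lapply(setIds, function(id) {
        size <- sample(seq(config$setSizeRange[1L], config$setSizeRange[2L]),
                       1L)
        if (id == plantedSetId) {
            overlap <- sample(moduleGenes, config$plantedSetOverlap)
            size <- max(size, config$plantedSetOverlap)
            fill <- sample(setdiff(geneIds, moduleGenes),
                           size - config$plantedSetOverlap)
            GeneSet(id, c(overlap, fill), description = "planted")
        } else {
            GeneSet(id, sample(geneIds, size), description = "random")
        }
    })
    list(dataset = TwoClassExperiment(vals, classes),
         collection = GeneSetCollection(sets),
         truth = list(trueDegs = trueDegs, moduleGenes = moduleGenes,
                      plantedSetId = plantedSetId))
}

#' Write a simulated dataset to plain-text files
#'
#' Produces the external artifacts of a run: expression TSV, labels TSV,
#' GMT gene sets and a ground-truth JSON.
#'
#' @param sim result of [generateDataset()].
#' @param dir output directory (created if absent).
#' @return invisibly, \code{dir}.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    vals <- assay(sim$dataset, 1L)
    expr <- data.frame(gene = rownames(vals),
                       apply(vals, 2L, function(x) sprintf("%.12g", x)),
                       check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(expr, file.path(dir, "expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = TRUE)
    cls <- sampleClasses(sim$dataset)
    utils::write.table(data.frame(names(cls), unname(cls)),
                       file.path(dir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    gmt <- vapply(sim$collection@sets, function(s)
        paste(c(s@setId, s@description, s@members), collapse = "\t"),
        character(1))
    writeLines(gmt, file.path(dir, "gene_sets.gmt"))
    jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(dir)
}

#' Exact-enumeration hypergeometric upper tail (oracle)
#'
#' Independent check of [hypergeomUpperTail()]: evaluates
#' \code{sum_{i=m}^{min(n,M)} C(M,i) C(N-M,n-i) / C(N,n)} term by term with
#' base [choose()].  Intended for small backgrounds (the enumeration is
#' exact in double precision for N up to a few dozen); refuses N > 200.
#'
#' @param m,n,M,N pair counts as in [hypergeomUpperTail()].
#' @return P value in [0, 1].
#' @export
hypergeomOracle <- function(m, n, M, N) {
    if (any(c(m, n, M, N) %% 1 != 0) || m < 0 || n < 1 || N < 1)
        stop("counts must be non-negative integers with n >= 1, N >= 1")
    if (m > n || n > N || m > M || M > N)
        stop("invalid pair-count tuple")
    if (N > 200) stop("oracle restricted to N <= 200")
    if (m == 0) return(1)
    i <- seq.int(m, min(n, M))
    sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

#' Confusion-matrix evaluation of a binary gene call
#'
#' Standard counts and ratios over a fixed gene universe:
#' accuracy = (tp+tn)/total, precision = tp/(tp+fp), recall = tp/(tp+fn),
#' fpr = fp/(fp+tn); a ratio with zero denominator is \code{NA}.
#'
#' @param predicted gene ids called positive (subset of \code{universe}).
#' @param positives true positive gene ids (subset of \code{universe}).
#' @param universe all evaluable gene ids, non-empty.
#' @return list with \code{tp, fp, fn, tn, accuracy, precision, recall,
#'   fpr}.
#' @examples
#' evaluateBinary(c("a", "b", "c"), c("a", "b", "d", "e", "f"),
#'                c(letters[1:6], "g", "h", "i", "j"))
#' @export
evaluateBinary <- function(predicted, positives, universe) {
    universe <- unique(as.character(universe))
    if (!length(universe)) stop("empty universe")
    predicted <- unique(as.character(predicted))
    positives <- unique(as.character(positives))
    if (length(setdiff(predicted, universe)) ||
        length(setdiff(positives, universe)))
        stop("predicted and positives must be subsets of the universe")
    tp <- length(intersect(predicted, positives))
    fp <- length(setdiff(predicted, positives))
    fn <- length(setdiff(positives, predicted))
    tn <- length(universe) - tp - fp - fn
    ratio <- function(num, den) if (den == 0) NA_real_ else num / den
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         accuracy = ratio(tp + tn, tp + fp + fn + tn),
         precision = ratio(tp, tp + fp),
         recall = ratio(tp, tp + fn),
         fpr = ratio(fp, fp + tn))
}

## rank of the planted set by list-level q, ascending, NA q last,
## ties broken uniformly at random (seeded by the caller's RNG state)
.plantedRank <- function(listRes, plantedSetId) {
    ord <- order(is.na(listRes$q_value), listRes$q_value,
                 stats::runif(nrow(listRes)))
    match(plantedSetId, listRes$set_id[ord])
}

#' Planted-signal recovery experiment
#'
#' Runs \code{nReplicates} independent simulate-and-analyze cycles: each
#' replicate draws a dataset from \code{config} (with a fresh seed derived
#' from \code{seed}), runs the full analysis, ranks the planted gene set by
#' list-level q (ties broken uniformly at random, so under a pure null the
#' planted set's top-1 rate is 1/nSets in expectation) and scores gene-level
#' calls against module membership.
#'
#' @param config a [simulationConfig()] object.
#' @param nReplicates number of replicates (>= 1).
#' @param seed master seed; the full experiment is reproducible from it.
#' @param gsceConfig analysis configuration (default [gsceConfig()]).
#' @return list with \code{top1Rate}, \code{medianRank}, \code{ranks}
#'   (integer vector), \code{geneMetrics} (mean accuracy/precision/recall/
#'   fpr of gene-level calls against module membership, NA-removed means)
#'   and \code{perReplicate} (data.frame).
#' @export
recoveryExperiment <- function(config = simulationConfig(),
                               nReplicates = 100L, seed = 20240101L,
                               gsceConfig = NULL) {
    stopifnot(nReplicates >= 1)
    if (is.null(gsceConfig)) gsceConfig <- gsce::gsceConfig()
    set.seed(seed)
    repSeeds <- sample.int(.Machine$integer.max, nReplicates)
    rows <- vector("list", nReplicates)
    for (i in seq_len(nReplicates)) {
        cfg <- config
        cfg$seed <- repSeeds[i]
        sim <- generateDataset(cfg)
        res <- runGsce(sim$dataset, sim$collection, gsceConfig)
        set.seed(repSeeds[i] %% 1000003L + i)    # tie-break RNG
        rank <- .plantedRank(listResults(res), sim$truth$plantedSetId)
        gr <- geneResults(res)
        planted <- gr[gr$set_id == sim$truth$plantedSetId, , drop = FALSE]
        predicted <- planted$query_id[!is.na(planted$significant) &
                                      planted$significant]
        universe <- unique(gr$query_id)
        met <- evaluateBinary(predicted,
                              intersect(sim$truth$moduleGenes, universe),
                              universe)
        rows[[i]] <- data.frame(
            replicate = i, seed = repSeeds[i], planted_rank = rank,
            n_degs = sum(degTable(res)$is_deg),
            accuracy = met$accuracy, precision = met$precision,
            recall = met$recall, fpr = met$fpr)
    }
    per <- do.call(rbind, rows)
    list(top1Rate = mean(per$planted_rank == 1L),
         medianRank = stats::median(per$planted_rank),
         ranks = per$planted_rank,
         geneMetrics = list(
             accuracy = mean(per$accuracy, na.rm = TRUE),
             precision = mean(per$precision, na.rm = TRUE),
             recall = mean(per$recall, na.rm = TRUE),
             fpr = mean(per$fpr, na.rm = TRUE)),
         perReplicate = per)
}
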