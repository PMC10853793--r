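#' DEG-calling configuration
#'
#' Three calling modes are supported.  \code{"microarray_topN"}: among genes
#' with two-sample t-test P < \code{pCut}, the \code{topN} genes with largest
#' |log2 fold change| are DEGs (all of them if fewer qualify).
#' \code{"threshold"}: genes with |log2 fold change| >= \code{lfcCut} and
#' Benjamini-Hochberg q <= \code{qCut} are DEGs (both bounds inclusive).
#' \code{"precomputed"}: DEG status is taken from a user-supplied gene list.
#'
#' @param mode one of \code{"microarray_topN"}, \code{"threshold"},
#'   \code{"precomputed"}.
#' @param pCut nominal P cutoff for the microarray rule (default 0.05,
#'   strict \code{<}).
#' @param topN cap on DEG count in the microarray rule (default 400).
#' @param lfcCut |log2 fold change| cutoff of the threshold rule (default 1).
#' @param qCut BH-adjusted P cutoff of the threshold rule (default 0.05).
#' @param equalVariance use the pooled-variance (Student) t test when
#'   \code{TRUE} (default); Welch when \code{FALSE}.
#' @return a list of class \code{"DEGConfig"}.
#' @export
degConfig <- function(mode = c("microarray_topN", "threshold", "precomputed"),
                      pCut = 0.05, topN = 400L, lfcCut = 1, qCut = 0.05,
                      equalVariance = TRUE) {
    mode <- match.arg(mode)
    stopifnot(is.numeric(pCut), length(pCut) == 1L, pCut > 0, pCut <= 1,
              is.numeric(topN), length(topN) == 1L, topN >= 1,
              is.numeric(lfcCut), length(lfcCut) == 1L, lfcCut >= 0,
              is.numeric(qCut), length(qCut) == 1L, qCut > 0, qCut <= 1,
              is.logical(equalVariance), length(equalVariance) == 1L)
    structure(list(mode = mode, pCut = pCut, topN = as.integer(topN),
                   lfcCut = lfcCut, qCut = qCut,
                   equalVariance = equalVariance),
              class = "DEGConfig")
}

.defaultDegConfig <- function() degConfig()

#' Two-sample t test on one gene
#'
#' Thin wrapper around [stats::t.test()] returning the two-sided statistic
#' and P value; pooled-variance (Student) form when \code{equalVariance} is
#' \code{TRUE}, Welch otherwise.  The degenerate case of two constant, equal
#' groups returns \code{t = 0, p = 1}; constant but different groups return
#' \code{p = 0} (perfect separation limit).
#'
#' @param x numeric values of the control group (length >= 2).
#' @param y numeric values of the case group (length >= 2).
#' @param equalVariance pooled (TRUE, default) vs Welch (FALSE).
#' @return list with \code{t_stat} and \code{p_value}.
#' @export
twoSampleTTest <- function(x, y, equalVariance = TRUE) {
    if (length(x) < 2L || length(y) < 2L)
        stop("each group needs at least 2 values")
    if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
    if (stats::var(x) == 0 && stats::var(y) == 0) {
        if (mean(x) == mean(y))
            return(list(t_stat = 0, p_value = 1))
        return(list(t_stat = sign(mean(y) - mean(x)) * Inf, p_value = 0))
    }
    tt <- stats::t.test(y, x, var.equal = equalVariance)
    list(t_stat = unname(tt$statistic), p_value = unname(tt$p.value))
}

#' Log2 fold change (case minus control)
#'
#' Values are assumed to be on the log2 scale already, so the fold change is
#' the difference of group means: \code{mean(case) - mean(control)}.
#'
#' @param control,case numeric vectors, non-empty.
#' @return numeric(1).
#' @export
log2FoldChange <- function(control, case) {
    if (!length(control) || !length(case)) stop("empty group")
    mean(case) - mean(control)
}

#' Benjamini-Hochberg adjusted P values
#'
#' Standard step-up FDR adjustment (via [stats::p.adjust()]) with input
#' validation; q values are returned in input order.
#'
#' @param p numeric vector of P values in [0, 1].
#' @return numeric vector of q values, same length and order.
#' @export
benjaminiHochberg <- function(p) {
    if (!length(p)) return(numeric())
    if (anyNA(p) || any(p < 0) || any(p > 1))
        stop("p values must lie in [0, 1] with no NA")
    stats::p.adjust(p, method = "BH")
}

## vectorized row-wise two-sample t test (pooled or Welch), genes x samples.
## Constant-equal rows get t = 0 / p = 1; constant-different rows p = 0.
.rowTTest <- function(ctrlMat, caseMat, equalVariance = TRUE) {
    n1 <- ncol(ctrlMat); n2 <- ncol(caseMat)
    m1 <- rowMeans(ctrlMat); m2 <- rowMeans(caseMat)
    v1 <- rowSums((ctrlMat - m1)^2) / (n1 - 1)
    v2 <- rowSums((caseMat - m2)^2) / (n2 - 1)
    d <- m2 - m1
    if (equalVariance) {
        sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
        se <- sqrt(sp2 * (1 / n1 + 1 / n2))
        df <- rep.int(n1 + n2 - 2, length(d))
    } else {
        se <- sqrt(v1 / n1 + v2 / n2)
        df <- (v1 / n1 + v2 / n2)^2 /
            ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    }
    t <- d / se
    degen <- se == 0
    t[degen] <- ifelse(d[degen] == 0, 0, sign(d[degen]) * Inf)
    p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
    p[degen & d == 0] <- 1
    p[degen & d != 0] <- 0
    list(t_stat = t, p_value = p, log2fc = d)
}

#' Call differentially expressed genes
#'
#' Computes, for every gene, the log2 fold change (case mean minus control
#' mean), the two-sample t statistic and P value between classes, and the
#' BH-adjusted q value, then flags DEGs according to the mode in
#' \code{config} (see [degConfig()]).  In \code{microarray_topN} mode a tie
#' at the cap boundary is broken by smaller P, then by gene id, so output is
#' deterministic.
#'
#' @param dataset a [TwoClassExperiment-class] with >= 2 samples per class.
#' @param config a [degConfig()] object.
#' @param degList character vector of gene ids, required when
#'   \code{config$mode == "precomputed"}; every id must be in the dataset.
#' @return data.frame with columns \code{gene_id, log2fc, t_stat, p_value,
#'   q_value, is_deg}, one row per gene in dataset row order.
#' @examples
#' sim <- generateDataset(simulationConfig(nGenes = 200, nDegs = 20,
#'                                         seed = 1))
#' deg <- selectDegs(sim$dataset, degConfig("microarray_topN"))
#' sum(deg$is_deg)
#' @export
selectDegs <- function(dataset, config = degConfig(), degList = NULL) {
    stopifnot(is(dataset, "TwoClassExperiment"),
              inherits(config, "DEGConfig"))
    ctrl <- .classMatrix(dataset, "control")
    case <- .classMatrix(dataset, "case")
    if (ncol(ctrl) < 2L || ncol(case) < 2L)
        stop("need at least 2 samples per class for the t test")
    tt <- .rowTTest(ctrl, case, config$equalVariance)
    q <- benjaminiHochberg(tt$p_value)
    geneIds <- rownames(dataset)
    isDeg <- switch(
        config$mode,
        microarray_topN = {
            eligible <- which(tt$p_value < config$pCut)
            ## rank by |log2fc| desc; cap ties by smaller p, then gene id
            ord <- eligible[order(-abs(tt$log2fc[eligible]),
                                  tt$p_value[eligible],
                                  geneIds[eligible], method = "radix")]
            flag <- logical(length(geneIds))
            flag[utils::head(ord, config$topN)] <- TRUE
            flag
        },
        threshold = abs(tt$log2fc) >= config$lfcCut & q <= config$qCut,
        precomputed = {
            if (is.null(degList))
                stop("precomputed mode requires 'degList'")
            absent <- setdiff(degList, geneIds)
            if (length(absent))
                stop("DEG list gene(s) absent from the expression matrix: ",
                     paste(absent, collapse = ", "))
            geneIds %in% degList
        })
    data.frame(gene_id = geneIds, log2fc = tt$log2fc, t_stat = tt$t_stat,
               p_value = tt$p_value, q_value = q, is_deg = isDeg,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank DEGs by absolute fold change
#'
#' Returns the gene ids flagged as DEGs, sorted by descending |log2 fold
#' change| with ties broken lexicographically by gene id (so a "top k DEGs"
#' query list is deterministic).
#'
#' @param records DEG table from [selectDegs()].
#' @return character vector of DEG gene ids.
#' @export
rankDegsByFoldChange <- function(records) {
    records <- records[records$is_deg, , drop = FALSE]
    if (!nrow(records)) return(character())
    records$gene_id[order(-abs(records$log2fc), records$gene_id,
                          method = "radix")]
}
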