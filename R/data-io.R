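#' Read a two-class expression dataset from TSV files
#'
#' The expression file is a tab-separated matrix with a header row of sample
#' ids and gene ids in the first column.  The label file maps each sample id
#' to \code{control} or \code{case} (two tab-separated columns, no header; a
#' header line whose second field is "class" is tolerated and skipped).
#'
#' Rows sharing a gene id are collapsed to their per-sample median (the usual
#' rule when several probes map to one gene).  Rows containing missing values
#' are dropped with a message (\code{missingValues = "drop"}, the default) or
#' raise an error (\code{"error"}); no imputation is offered.
#'
#' @param path expression matrix TSV.
#' @param labelPath sample-to-class TSV.
#' @param log2Transform if \code{TRUE}, values are transformed to
#'   \code{log2(x + 1)} after loading (use for raw intensity/count-scale
#'   input; the analysis assumes log2-scale values).
#' @param missingValues \code{"drop"} or \code{"error"}.
#' @return A [TwoClassExperiment-class].
#' @examples
#' ef <- tempfile(); lf <- tempfile()
#' writeLines(c("gene\ts1\ts2\ts3\ts4",
#'              "g1\t1\t2\t3\t4",
#'              "g2\t4\t3\t2\t1"), ef)
#' writeLines(c("s1\tcontrol", "s2\tcontrol", "s3\tcase", "s4\tcase"), lf)
#' readExpression(ef, lf)
#' @export
readExpression <- function(path, labelPath, log2Transform = FALSE,
                           missingValues = c("drop", "error")) {
    missingValues <- match.arg(missingValues)
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character",
                             stringsAsFactors = FALSE, quote = "")
    if (ncol(raw) < 2L)
        stop("expression file needs a gene id column and >=1 sample column")
    sampleIds <- colnames(raw)[-1L]
    dup <- sampleIds[duplicated(sampleIds)]
    if (length(dup))
        stop("duplicate sample id(s) in expression header: ",
             paste(unique(dup), collapse = ", "))
    geneIds <- raw[[1L]]

    ## character -> numeric with cell-level diagnostics
    vals <- matrix(NA_real_, nrow(raw), length(sampleIds),
                   dimnames = list(NULL, sampleIds))
    for (j in seq_along(sampleIds)) {
        colChr <- raw[[j + 1L]]
        suppressWarnings(colNum <- as.numeric(colChr))
        bad <- which(is.na(colNum) & !(is.na(colChr) |
                                       colChr %in% c("", "NA", "NaN")))
        if (length(bad))
            stop("non-numeric value '", colChr[bad[1L]], "' at gene '",
                 geneIds[bad[1L]], "', sample '", sampleIds[j], "'")
        vals[, j] <- colNum
    }

    ## collapse duplicate gene rows to per-sample median
    if (anyDuplicated(geneIds)) {
        keep <- unique(geneIds)
        vals <- do.call(rbind, lapply(keep, function(g) {
            rows <- vals[geneIds == g, , drop = FALSE]
            if (nrow(rows) == 1L) rows[1L, ]
            else apply(rows, 2L, stats::median)
        }))
        geneIds <- keep
    }
    rownames(vals) <- geneIds

    ## rows with missing values: reject
    hasNA <- rowSums(is.na(vals)) > 0L
    if (any(hasNA)) {
        if (missingValues == "error")
            stop("missing values in gene(s): ",
                 paste(utils::head(geneIds[hasNA], 5L), collapse = ", "))
        message("dropping ", sum(hasNA), " gene row(s) with missing values")
        vals <- vals[!hasNA, , drop = FALSE]
    }

    labels <- .readLabels(labelPath)
    missing <- setdiff(sampleIds, names(labels))
    if (length(missing))
        stop("sample(s) missing from label file: ",
             paste(missing, collapse = ", "))

    if (log2Transform) {
        if (any(vals < 0))
            stop("negative values cannot be log2(x + 1) transformed")
        vals <- log2(vals + 1)
    }
    TwoClassExperiment(vals, labels[sampleIds])
}

.readLabels <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("label file is empty")
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 2L))
        stop("label file lines must be 'sample_id<TAB>class'")
    ids <- vapply(parts, `[[`, character(1), 1L)
    cls <- tolower(trimws(vapply(parts, `[[`, character(1), 2L)))
    if (cls[1L] == "class") {          # tolerated header line
        ids <- ids[-1L]; cls <- cls[-1L]
    }
    if (anyDuplicated(ids))
        stop("duplicate sample id(s) in label file: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    bad <- setdiff(unique(cls), .CLASS_LEVELS)
    if (length(bad))
        stop("invalid class label(s): ", paste(bad, collapse = ", "),
             " (expected control/case)")
    names(cls) <- ids
    cls
}

#' Read a GMT gene set file
#'
#' Broad-dialect GMT: one set per line, tab-separated fields
#' \code{set_id<TAB>description<TAB>member...} with at least one member.
#' File order is preserved; duplicate members within a line are dropped.
#'
#' @param path GMT file path.
#' @return A [GeneSetCollection-class]; empty file gives an empty collection.
#' @export
readGmt <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    sets <- vector("list", length(lines))
    for (k in seq_along(lines)) {
        f <- strsplit(lines[k], "\t", fixed = TRUE)[[1L]]
        f <- f[nzchar(f) | seq_along(f) <= 2L]   # drop empty trailing fields
        if (length(f) < 3L)
            stop("GMT line ", k, " has fewer than 3 fields")
        sets[[k]] <- GeneSet(f[1L], f[-(1:2)], description = f[2L])
    }
    ids <- vapply(sets, setId, character(1))
    if (anyDuplicated(ids))
        stop("duplicate gene set id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    GeneSetCollection(sets)
}

#' Read a DEG list file
#'
#' One gene id per line, optionally followed by a tab and a log2 fold
#' change (ignored here).  Blank lines are skipped; order is preserved.
#'
#' @param path file path.
#' @return character vector of gene ids, file order.
#' @export
readDegList <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    ids <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
    ids <- trimws(ids)
    if (anyDuplicated(ids))
        stop("duplicate gene id(s) in DEG list: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    ids
}

.ASSOC_COLS <- c("query_id", "set_id", "m", "n", "M", "N",
                 "p_value", "q_value", "significant")

## canonical row order of an association table: descending -log10(q)
## (i.e. ascending q), NA q last, ties by set_id then query_id
.orderAssociations <- function(df) {
    order(is.na(df$q_value), df$q_value, df$set_id, df$query_id,
          method = "radix")
}

#' Write / read an association table
#'
#' TSV with columns \code{query_id, set_id, m, n, M, N, p_value, q_value,
#' significant}; rows ordered by descending -log10(q) (ties by set_id).
#' Numeric columns are written with 12 significant digits so that a
#' write/read round-trip is value-identical at that precision.  Untestable
#' associations (no possible pairs) carry \code{NA} p and q.
#'
#' @param results association data.frame as produced by [listAssociation()]
#'   or [geneAssociation()].
#' @param path output TSV path.
#' @return \code{writeAssociationTable} invisibly returns \code{path};
#'   \code{readAssociationTable} returns the data.frame.
#' @export
writeAssociationTable <- function(results, path) {
    results <- as.data.frame(results)
    missingCols <- setdiff(.ASSOC_COLS, colnames(results))
    if (length(missingCols))
        stop("association table lacks column(s): ",
             paste(missingCols, collapse = ", "))
    results <- results[.orderAssociations(results), .ASSOC_COLS]
    fmtNum <- function(x) ifelse(is.na(x), "NA", sprintf("%.12g", x))
    out <- data.frame(
        query_id = results$query_id, set_id = results$set_id,
        m = as.integer(results$m), n = as.integer(results$n),
        M = as.integer(results$M), N = as.integer(results$N),
        p_value = fmtNum(results$p_value),
        q_value = fmtNum(results$q_value),
        significant = ifelse(is.na(results$significant), "NA",
                             as.character(results$significant)),
        stringsAsFactors = FALSE)
    ok <- tryCatch({
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = TRUE)
        TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("cannot write association table to '", path,
                          "': ", conditionMessage(ok))
    invisible(path)
}

#' @rdname writeAssociationTable
#' @export
readAssociationTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = c(query_id = "character",
                                           set_id = "character"))
    missingCols <- setdiff(.ASSOC_COLS, colnames(df))
    if (length(missingCols))
        stop("not an association table; lacks column(s): ",
             paste(missingCols, collapse = ", "))
    df$m <- as.integer(df$m); df$n <- as.integer(df$n)
    df$M <- as.integer(df$M); df$N <- as.integer(df$N)
    df$p_value <- as.numeric(df$p_value)
    df$q_value <- as.numeric(df$q_value)
    df$significant <- as.logical(df$significant)
    df
}
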