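.ONE_SIDED_Z <- 1.64
.TWO_SIDED_Z <- 1.96
.Q_CLIP <- 1e-15

#' Transform an FDR q value (or P value) to a z score
#'
#' \code{z = qnorm(1 - q)}: small q maps to large positive z.  To keep z
#' finite, q is clipped to \code{[1e-15, 1 - 1e-15]} before the transform.
#'
#' @param q numeric vector of q (or nominal P) values in (0, 1].
#' @return numeric vector of z scores.
#' @examples
#' qToZ(0.5)   # 0
#' qToZ(0.05)  # ~1.6449
#' @export
qToZ <- function(q) {
    if (!length(q)) return(numeric())
    if (anyNA(q) || any(q <= 0) || any(q > 1))
        stop("q values must lie in (0, 1] with no NA")
    q <- pmin(pmax(q, .Q_CLIP), 1 - .Q_CLIP)
    stats::qnorm(1 - q)
}

#' Stouffer's unweighted Z combination
#'
#' \code{sum(z) / sqrt(k)} for k stratum z scores.
#'
#' @param zs numeric vector of z scores, non-empty and finite.
#' @return the combined meta-z.
#' @examples
#' stoufferMetaZ(c(2, 2, 2, 2))  # 4
#' @export
stoufferMetaZ <- function(zs) {
    if (!length(zs)) stop("no z scores to combine")
    if (anyNA(zs) || any(!is.finite(zs)))
        stop("all z scores must be finite")
    sum(zs) / sqrt(length(zs))
}

## normalize a 'tables' argument: list of data.frames or file paths
.loadTables <- function(tables) {
    if (is.data.frame(tables)) tables <- list(tables)
    if (!length(tables)) stop("at least one association table is required")
    out <- lapply(tables, function(t) {
        if (is.character(t)) t <- readAssociationTable(t)
        t <- as.data.frame(t)
        missingCols <- setdiff(.ASSOC_COLS, colnames(t))
        if (length(missingCols))
            stop("association table lacks column(s): ",
                 paste(missingCols, collapse = ", "))
        t
    })
    if (is.null(names(out)) || any(!nzchar(names(out))))
        names(out) <- paste0("stratum", seq_along(out))
    out
}

#' Combine association significance across strata or across gene sets
#'
#' Each stratum (dataset/cancer type) contributes one association table.
#' Every testable association's q value (or nominal P with
#' \code{useNominalP = TRUE}) is transformed to a z score and the z scores
#' belonging to one entity are combined with Stouffer's unweighted method.
#' With \code{axis = "strata"} an entity is an association, matched by
#' (query_id, set_id) across tables: the meta-z asks whether the association
#' recurs across strata.  With \code{axis = "sets"} an entity is a query
#' gene, pooling its z scores over all sets (and tables): the meta-z asks
#' whether the gene is broadly enriched pathway-wide.  Entities testable in
#' no stratum are omitted with a warning; missing strata reduce k rather
#' than contributing z = 0.
#'
#' @param tables a list of association data.frames (or TSV paths), one per
#'   stratum; names are used as stratum labels.
#' @param axis \code{"strata"} or \code{"sets"}.
#' @param useNominalP combine nominal P values instead of FDR q values.
#' @return data.frame with columns \code{entity_id} (plus \code{query_id} /
#'   \code{set_id} where applicable), \code{k}, \code{meta_z},
#'   \code{significant_one_sided} (meta-z >= 1.64, inclusive) and
#'   \code{significant_two_sided} (|meta-z| >= 1.96); the per-stratum z
#'   scores are attached as a list column \code{stratum_zs}.
#' @export
combineAcrossStrata <- function(tables, axis = c("strata", "sets"),
                                useNominalP = FALSE) {
    axis <- match.arg(axis)
    tables <- .loadTables(tables)
    rows <- do.call(rbind, lapply(names(tables), function(s) {
        t <- tables[[s]]
        t$stratum <- s
        t
    }))
    rows <- rows[order(rows$stratum, rows$query_id, rows$set_id,
                       method = "radix"), , drop = FALSE]
    val <- if (useNominalP) rows$p_value else rows$q_value
    testable <- !is.na(val)
    rows$z <- NA_real_
    rows$z[testable] <- qToZ(val[testable])
    rows$entity <- if (axis == "strata")
        paste(rows$query_id, rows$set_id, sep = "|") else rows$query_id

    allEntities <- unique(rows$entity)
    rows <- rows[testable, , drop = FALSE]
    lost <- setdiff(allEntities, unique(rows$entity))
    if (length(lost))
        warning(length(lost), " entit(ies) testable in zero strata omitted")

    groups <- split(rows, rows$entity)
    groups <- groups[order(names(groups), method = "radix")]
    res <- do.call(rbind, lapply(groups, function(g) {
        mz <- stoufferMetaZ(g$z)
        data.frame(entity_id = g$entity[1L], k = nrow(g),
                   meta_z = mz,
                   significant_one_sided = mz >= .ONE_SIDED_Z,
                   significant_two_sided = abs(mz) >= .TWO_SIDED_Z,
                   stringsAsFactors = FALSE)
    }))
    if (axis == "strata") {
        parts <- strsplit(res$entity_id, "|", fixed = TRUE)
        res$query_id <- vapply(parts, `[[`, character(1), 1L)
        res$set_id <- vapply(parts, `[[`, character(1), 2L)
    } else {
        res$query_id <- res$entity_id
    }
    res$stratum_zs <- lapply(groups, function(g)
        stats::setNames(g$z, g$stratum))
    rownames(res) <- NULL
    res
}

#' Percentage of significant associations
#'
#' \code{100 * (cumulative significant associations) / (nSets * nStrata)}:
#' a summary of how much of the tested (set, stratum) grid a method lights
#' up.  Untestable (NA) associations count in the denominator.
#'
#' @param tables association tables as in [combineAcrossStrata()].
#' @param nSets number of gene sets per stratum.
#' @param nStrata number of strata.
#' @return percentage in [0, 100].
#' @export
percentSignificant <- function(tables, nSets, nStrata) {
    tables <- .loadTables(tables)
    denom <- nSets * nStrata
    if (!is.numeric(denom) || denom <= 0)
        stop("nSets * nStrata must be positive")
    sig <- sum(vapply(tables, function(t)
        sum(t$significant, na.rm = TRUE), numeric(1)))
    100 * sig / denom
}
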