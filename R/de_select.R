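#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: \eqn{q_{(i)} = \min_{j \ge i} m p_{(j)} / j},
#' clipped at 1. Thin validated wrapper over \code{stats::p.adjust}.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return q-values, same length and order as the input.
#' @examples
#' adjustBH(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
adjustBH <- function(pvals) {
    if (!is.numeric(pvals))
        stop("p-values must be numeric")
    if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(pvals, method = "BH")
}

# Condition labels are carried in column names: log2fc_<cond>, pval_<cond>,
# and (after adjustment) qval_<cond>.
expressionConditions <- function(table) {
    sub("^log2fc_", "", grep("^log2fc_", names(table), value = TRUE))
}

.checkExpressionTable <- function(table) {
    if (!is.data.frame(table) || !"gene_id" %in% names(table))
        stop("an expression table needs a 'gene_id' column")
    if (anyDuplicated(table$gene_id))
        stop("gene ids must be unique")
    conds <- expressionConditions(table)
    if (length(conds) < 2L)
        stop("fewer than 2 conditions in the expression table")
    for (cc in conds) {
        pc <- paste0("pval_", cc)
        if (!pc %in% names(table))
            stop("missing column '", pc, "'")
        if (any(table[[pc]] < 0 | table[[pc]] > 1, na.rm = TRUE))
            stop("p-values in '", pc, "' outside [0, 1]")
    }
    conds
}

#' Add BH-adjusted p-value columns to an expression table
#'
#' @param table expression table with \code{log2fc_*} and \code{pval_*}
#'   columns.
#' @return the table with one \code{qval_*} column per condition (existing
#'   qval columns are left untouched).
#' @export
addAdjustedP <- function(table) {
    conds <- .checkExpressionTable(table)
    for (cc in conds) {
        qc <- paste0("qval_", cc)
        if (!qc %in% names(table))
            table[[qc]] <- adjustBH(table[[paste0("pval_", cc)]])
    }
    table
}

#' Threshold an expression table into per-condition up/down gene sets
#'
#' A gene is in the up-set of a condition when its log2 fold-change exceeds
#' \code{lfcCut} and its adjusted p-value is below \code{alpha}; the
#' down-set is symmetric. Both inequalities are strict, so boundary genes
#' (log2FC exactly 1.5, q exactly 0.01) are excluded.
#'
#' @param table expression table; adjusted p-values are computed with
#'   [addAdjustedP()] if absent.
#' @param lfcCut log2 fold-change threshold (default 1.5).
#' @param alpha adjusted p-value threshold (default 0.01).
#' @return named list (one element per condition) of
#'   \code{list(up = , down = )} character vectors of gene ids, with the
#'   thresholds attached as attributes.
#' @export
filterDE <- function(table, lfcCut = 1.5, alpha = 0.01) {
    table <- addAdjustedP(table)
    conds <- expressionConditions(table)
    out <- lapply(conds, function(cc) {
        lfc <- table[[paste0("log2fc_", cc)]]
        q <- table[[paste0("qval_", cc)]]
        list(up = table$gene_id[lfc > lfcCut & q < alpha],
             down = table$gene_id[lfc < -lfcCut & q < alpha])
    })
    names(out) <- conds
    attr(out, "lfcCut") <- lfcCut
    attr(out, "alpha") <- alpha
    out
}

.regionKey <- function(conds) paste(sort(conds), collapse = "&")

#' Partition genes into Venn exclusivity regions
#'
#' Each gene is assigned to exactly the region matching the subset of
#' conditions in which it appears. Input sets may be plain character
#' vectors, or \code{list(up =, down =)} pairs as returned by [filterDE()]
#' (membership is then up or down, and each region is additionally split
#' by direction).
#'
#' @param sets named list: condition -> gene set (or up/down pair).
#' @return a [VennPartition-class] with one (possibly empty) region per
#'   non-empty condition subset.
#' @export
vennPartition <- function(sets) {
    if (length(sets) < 2L || is.null(names(sets)))
        stop("need a named list of at least 2 condition sets")
    conds <- names(sets)
    split_dir <- all(vapply(sets, function(s)
        is.list(s) && all(c("up", "down") %in% names(s)), logical(1)))
    members <- if (split_dir) lapply(sets, function(s) union(s$up, s$down))
               else lapply(sets, as.character)
    genes <- unique(unlist(members, use.names = FALSE))
    # membership signature per gene
    inset <- vapply(members, function(m) genes %in% m,
                    logical(length(genes)))
    if (length(genes) == 1L) inset <- matrix(inset, nrow = 1L)
    sig <- apply(inset, 1L, function(row) .regionKey(conds[row]))
    # all non-empty subsets, in size-then-lexicographic order
    keys <- unlist(lapply(seq_along(conds), function(k)
        apply(utils::combn(sort(conds), k), 2L, paste, collapse = "&")))
    regions <- lapply(keys, function(k) sort(genes[sig == k]))
    names(regions) <- keys
    directions <- lapply(keys, function(k) {
        gs <- regions[[k]]
        if (!split_dir || length(gs) == 0L)
            return(list(up = character(), down = character(),
                        mixed = if (split_dir) character() else gs))
        cset <- strsplit(k, "&", fixed = TRUE)[[1L]]
        dir <- vapply(gs, function(g) {
            up <- all(vapply(cset, function(cc) g %in% sets[[cc]]$up,
                             logical(1)))
            dn <- all(vapply(cset, function(cc) g %in% sets[[cc]]$down,
                             logical(1)))
            if (up) "up" else if (dn) "down" else "mixed"
        }, character(1))
        list(up = gs[dir == "up"], down = gs[dir == "down"],
             mixed = gs[dir == "mixed"])
    })
    names(directions) <- keys
    new("VennPartition", conditions = conds, regions = regions,
        directions = directions)
}

#' @rdname vennPartition
#' @param partition a [VennPartition-class].
#' @return \code{vennRegions}: the named list of region gene sets.
#' @export
vennRegions <- function(partition) partition@regions

#' Select the top-regulated gene panel
#'
#' For each of the four categories -- exclusive to each condition, plus the
#' genes shared by all conditions -- takes the \code{k} genes with the
#' largest |log2FC| among up-regulated and among down-regulated genes
#' (default 10 + 10 per category, hence a panel of up to 80 genes for three
#' conditions). Shared genes are ranked by their maximum |log2FC| across
#' conditions. Ties at rank k are broken lexicographically by gene id, so
#' the panel is invariant to input row order.
#'
#' @param table the expression table the partition was built from.
#' @param partition a [VennPartition-class] over the table's conditions.
#' @param k genes per category and direction (default 10).
#' @param sharedStat how to aggregate |log2FC| across conditions for the
#'   shared category: \code{"max"} (default) or \code{"mean"}.
#' @return data.frame (category, direction, rank, gene_id, log2fc,
#'   condition) where \code{condition} names the condition whose fold
#'   change was used for ranking ("aggregate" for shared/mean).
#' @export
selectTopPanel <- function(table, partition, k = 10,
                           sharedStat = c("max", "mean")) {
    sharedStat <- match.arg(sharedStat)
    if (k <= 0) stop("'k' must be positive")
    conds <- partition@conditions
    rows <- stats::setNames(seq_len(nrow(table)), table$gene_id)
    pick <- function(genes, lfc, condLabel, category) {
        keep <- !is.na(lfc)
        genes <- genes[keep]; lfc <- lfc[keep]
        condLabel <- rep_len(condLabel, length(genes))
        res <- list()
        for (dir in c("up", "down")) {
            sel <- if (dir == "up") lfc > 0 else lfc < 0
            g <- genes[sel]; v <- lfc[sel]; cl <- condLabel[sel]
            ord <- order(-abs(v), g)
            n <- min(k, length(g))
            if (n > 0L)
                res[[dir]] <- data.frame(
                    category = category, direction = dir, rank = seq_len(n),
                    gene_id = g[ord][seq_len(n)],
                    log2fc = v[ord][seq_len(n)],
                    condition = cl[ord][seq_len(n)],
                    stringsAsFactors = FALSE)
        }
        do.call(rbind, res)
    }
    out <- list()
    for (cc in conds) {
        genes <- partition@regions[[.regionKey(cc)]]
        lfc <- table[[paste0("log2fc_", cc)]][rows[genes]]
        out[[cc]] <- pick(genes, lfc, cc, paste0("exclusive-", cc))
    }
    sharedKey <- .regionKey(conds)
    genes <- partition@regions[[sharedKey]]
    if (length(genes)) {
        lfcMat <- vapply(conds, function(cc)
            table[[paste0("log2fc_", cc)]][rows[genes]],
            numeric(length(genes)))
        if (length(genes) == 1L) lfcMat <- matrix(lfcMat, nrow = 1L)
        if (sharedStat == "max") {
            j <- apply(abs(lfcMat), 1L, which.max)
            lfc <- lfcMat[cbind(seq_along(genes), j)]
            lab <- conds[j]
        } else {
            lfc <- sign(lfcMat[, 1L]) * rowMeans(abs(lfcMat))
            lab <- "aggregate"
        }
        out[["shared"]] <- pick(genes, lfc, lab, "shared-by-all")
    }
    panel <- do.call(rbind, out)
    if (is.null(panel))
        panel <- data.frame(category = character(), direction = character(),
                            rank = integer(), gene_id = character(),
                            log2fc = numeric(), condition = character(),
                            stringsAsFactors = FALSE)
    rownames(panel) <- NULL
    panel
}
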