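#' Per-factor binding-site density over a promoter set
#'
#' Density is the total number of predicted sites attributed to a factor
#' across all listed promoters, divided by the number of genes in the set;
#' genes with zero hits still count in the denominator. Hits from several
#' matrices with the same \code{tf_name} are pooled.
#'
#' @param hits hit table from [scanPromoters()]; every \code{promoter_id}
#'   must be in \code{geneIds}.
#' @param geneIds gene ids of the promoter set (the denominator).
#' @param tfNames factor universe to report (zero-hit factors are reported
#'   with density 0); defaults to the factors present in \code{hits}.
#' @return data.frame (tf_name, n_sites, n_genes, density).
#' @export
siteDensity <- function(hits, geneIds, tfNames = NULL) {
    geneIds <- unique(as.character(geneIds))
    if (length(geneIds) == 0L)
        stop("empty gene set")
    if (nrow(hits) > 0L && !all(hits$promoter_id %in% geneIds))
        stop("hit table contains promoters outside the gene set")
    if (is.null(tfNames)) tfNames <- sort(unique(hits$tf_name))
    counts <- table(factor(hits$tf_name, levels = tfNames))
    data.frame(tf_name = tfNames,
               n_sites = as.integer(counts),
               n_genes = length(geneIds),
               density = as.numeric(counts) / length(geneIds),
               stringsAsFactors = FALSE)
}

#' Compare factor densities in regulated vs internal-control promoters
#'
#' Classifies each factor, eliminating those with ubiquitous site abundance:
#' \describe{
#'   \item{absent_in_controls}{sites in the regulated panel but none in the
#'     control promoters.}
#'   \item{retained}{control density positive and regulated density equal
#'     to or higher than the control density.}
#'   \item{dropped}{everything else (including factors with no sites at
#'     all).}
#' }
#' Records with regulated density at or below \code{reportFloor} are kept in
#' the computation but flagged \code{reported = FALSE} (they are omitted
#' from written reports).
#'
#' @param reg density table over the regulated panel ([siteDensity()]).
#' @param ctrl density table over the internal-control promoters, computed
#'   with the same matrix library.
#' @param reportFloor densities at or below this value are not reported
#'   (default 0.01).
#' @return data.frame (tf_name, n_sites_reg, n_genes_reg, density_reg,
#'   n_sites_ctrl, n_genes_ctrl, density_ctrl, klass, reported).
#' @export
compareToControls <- function(reg, ctrl, reportFloor = 0.01) {
    if (!setequal(reg$tf_name, ctrl$tf_name))
        stop("regulated and control densities must cover the same factors ",
             "(same PWM library on both sides)")
    m <- merge(reg, ctrl, by = "tf_name", suffixes = c("_reg", "_ctrl"))
    klass <- ifelse(m$n_sites_ctrl == 0L & m$n_sites_reg > 0L,
                    "absent_in_controls",
             ifelse(m$density_ctrl > 0 & m$density_reg >= m$density_ctrl,
                    "retained", "dropped"))
    m$klass <- klass
    m$reported <- m$density_reg > reportFloor
    m[order(m$tf_name), , drop = FALSE]
}

#' Keep-classes of a density comparison
#'
#' Convenience accessor: factors classified \code{absent_in_controls} or
#' \code{retained} (and above the report floor) -- the promoter-derived
#' candidate list.
#' @param comparison output of [compareToControls()].
#' @return character vector of factor names.
#' @export
keptTFs <- function(comparison)
    sort(comparison$tf_name[comparison$reported &
        comparison$klass %in% c("absent_in_controls", "retained")])

#' Factors exclusive to each experimental group
#'
#' \code{exclusive(g)} is the factors retained in group g minus those
#' retained in any other group; outputs are pairwise disjoint.
#'
#' @param retained named list: group -> character vector of retained
#'   factors.
#' @return named list: group -> exclusive factor set.
#' @export
groupExclusiveTFs <- function(retained) {
    if (length(retained) < 2L)
        stop("need at least 2 groups")
    out <- lapply(seq_along(retained), function(i)
        sort(setdiff(retained[[i]],
                     unlist(retained[-i], use.names = FALSE))))
    names(out) <- names(retained)
    out
}

#' Intersect promoter-derived and network-derived factor lists
#'
#' Both lists are canonicalised through a synonym map (alias -> canonical
#' symbol) before intersecting; names without a map entry pass through
#' unchanged with a warning.
#'
#' @param promoterTFs factors surviving the promoter density filter.
#' @param networkTFs the network-derived factor list.
#' @param synonymMap named character vector, alias -> canonical symbol. An
#'   alias mapped to two different canonicals is an error.
#' @param perGroupExclusive optional output of [groupExclusiveTFs()] to
#'   carry along.
#' @return a [CandidateSet-class].
#' @export
intersectWithNetwork <- function(promoterTFs, networkTFs,
                                 synonymMap = character(),
                                 perGroupExclusive = list()) {
    synonymMap <- synonymMap %||% character()
    if (length(synonymMap)) {
        dup <- duplicated(names(synonymMap))
        if (any(dup)) {
            conflict <- vapply(unique(names(synonymMap)[dup]), function(a)
                length(unique(synonymMap[names(synonymMap) == a])) > 1L,
                logical(1))
            if (any(conflict))
                stop("conflicting synonym entries for: ",
                     paste(names(conflict)[conflict], collapse = ", "))
            synonymMap <- synonymMap[!dup]
        }
    }
    canon <- function(x) {
        x <- unique(as.character(x))
        hit <- x %in% names(synonymMap)
        if (length(synonymMap) && any(!hit))
            warning("no synonym entry for: ",
                    paste(x[!hit], collapse = ", "),
                    "; passed through unchanged")
        x[hit] <- synonymMap[x[hit]]
        unique(x)
    }
    final <- sort(intersect(canon(promoterTFs), canon(networkTFs)))
    new("CandidateSet", promoterTFs = unique(as.character(promoterTFs)),
        networkTFs = unique(as.character(networkTFs)),
        synonymMap = synonymMap, final = final,
        perGroupExclusive = perGroupExclusive)
}
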