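#' @import methods
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Position weight matrix with a 5-position core window
#'
#' A \code{PWM} holds per-position nucleotide frequencies \eqn{f(i,B)} for a
#' binding motif, the name of the factor it belongs to, and the start of the
#' 5-position core window (the most conserved 5 consecutive positions, used
#' for the core similarity score). Frequencies are stored as an L x 4 matrix
#' with columns A, C, G, T; each row sums to 1.
#'
#' @slot id unique matrix identifier.
#' @slot tfName transcription factor name; several matrices may share one
#'   factor (hits are pooled by \code{tfName} downstream).
#' @slot freq L x 4 frequency matrix, rows summing to 1.
#' @slot coreStart 1-based start of the 5-position core window.
#' @seealso [PWM()], [informationVector()], [findCore()]
#' @export
setClass("PWM",
    representation(id = "character", tfName = "character",
                   freq = "matrix", coreStart = "integer"))

setValidity("PWM", function(object) {
    f <- object@freq
    msg <- character()
    if (length(object@id) != 1L || !nzchar(object@id))
        msg <- c(msg, "'id' must be a single non-empty string")
    if (length(object@tfName) != 1L)
        msg <- c(msg, "'tfName' must be a single string")
    if (!is.numeric(f) || ncol(f) != 4L)
        msg <- c(msg, "'freq' must be a numeric L x 4 matrix")
    else {
        if (!identical(colnames(f), DNA_BASES))
            msg <- c(msg, "'freq' columns must be named A, C, G, T")
        if (nrow(f) < 5L)
            msg <- c(msg, "motif length must be >= 5 (core window must fit)")
        if (any(f < 0))
            msg <- c(msg, "frequencies must be non-negative")
        if (any(abs(rowSums(f) - 1) > 1e-9))
            msg <- c(msg, "each frequency row must sum to 1 (tol 1e-9)")
        if (length(object@coreStart) != 1L || is.na(object@coreStart) ||
            object@coreStart < 1L || object@coreStart > nrow(f) - 4L)
            msg <- c(msg, "'coreStart' must lie in [1, L - 4]")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PWM
#'
#' @param id unique matrix identifier.
#' @param freq numeric L x 4 matrix of per-position base frequencies (or
#'   counts, see \code{pseudocount}); columns in A, C, G, T order.
#' @param tfName factor name; defaults to \code{id}.
#' @param coreStart 1-based core window start; found automatically with
#'   [findCore()] when \code{NULL}.
#' @param pseudocount added to every cell before row-normalisation when the
#'   rows do not already sum to 1 (e.g. count matrices). Default 0.
#' @return a [PWM-class] object.
#' @examples
#' m <- matrix(c(1, 0, 0, 0), 6, 4, byrow = TRUE)
#' pwm <- PWM("M1", m)
#' @export
PWM <- function(id, freq, tfName = id, coreStart = NULL, pseudocount = 0) {
    freq <- as.matrix(freq)
    if (ncol(freq) != 4L)
        stop("'freq' must have 4 columns (A, C, G, T)")
    colnames(freq) <- DNA_BASES
    storage.mode(freq) <- "double"
    rs <- rowSums(freq)
    if (any(abs(rs - 1) > 1e-9)) {
        if (any(rs <= 0))
            stop("frequency rows must have positive sums")
        freq <- (freq + pseudocount) / (rs + 4 * pseudocount)
    }
    if (is.null(coreStart))
        coreStart <- findCore(freq)
    new("PWM", id = as.character(id), tfName = as.character(tfName),
        freq = freq, coreStart = as.integer(coreStart))
}

setMethod("show", "PWM", function(object) {
    L <- nrow(object@freq)
    cat("PWM ", object@id, " (", object@tfName, "): length ", L,
        ", core ", object@coreStart, "-", object@coreStart + 4L,
        ", consensus ", consensusWord(object), "\n", sep = "")
})

#' @describeIn PWM motif length (number of positions)
#' @param x,object a \code{PWM}
#' @export
setMethod("length", "PWM", function(x) nrow(x@freq))

#' Accessors for PWM slots
#' @param x a [PWM-class] object.
#' @return \code{pwmId}/\code{tfName}: a string; \code{pwmFreq}: the L x 4
#'   frequency matrix; \code{coreStart}: integer core window start.
#' @export
pwmId <- function(x) x@id
#' @rdname pwmId
#' @export
tfName <- function(x) x@tfName
#' @rdname pwmId
#' @export
pwmFreq <- function(x) x@freq
#' @rdname pwmId
#' @export
coreStart <- function(x) x@coreStart

#' A list of PWM objects with unique ids
#'
#' Plain list container; names are kept equal to the matrix ids.
#' @export
setClass("PWMList", contains = "list")

setValidity("PWMList", function(object) {
    if (!all(vapply(object@.Data, is, logical(1), "PWM")))
        return("all elements must be PWM objects")
    ids <- vapply(object@.Data, pwmId, character(1))
    if (anyDuplicated(ids))
        return("PWM ids must be unique")
    if (!identical(names(object), ids))
        return("names must equal the PWM ids")
    TRUE
})

#' @rdname PWMList-class
#' @param x list of [PWM-class] objects (or PWMs given as \code{...}).
#' @export
PWMList <- function(x = list()) {
    if (is(x, "PWM")) x <- list(x)
    names(x) <- vapply(x, pwmId, character(1))
    new("PWMList", x)
}

setMethod("show", "PWMList", function(object) {
    cat("PWMList of", length(object), "matrices\n")
    if (length(object)) {
        ids <- names(object)
        tfs <- vapply(object@.Data, tfName, character(1))
        n <- min(5L, length(object))
        for (i in seq_len(n))
            cat("  ", ids[i], " (", tfs[i], ")\n", sep = "")
        if (length(object) > n) cat("  ...\n")
    }
})

setMethod("[", "PWMList", function(x, i, j, ..., drop = TRUE)
    PWMList(x@.Data[i]))

#' Matrix and core similarity cutoffs for scanning
#'
#' @slot mssCut matrix similarity cutoff in [0, 1].
#' @slot cssCut core similarity cutoff in [0, 1].
#' @slot profileKind one of \code{"minFP"}, \code{"minFN"}, \code{"minSUM"},
#'   \code{"manual"}.
#' @slot metadata calibration metadata (background composition, window
#'   counts, target rates, seed).
#' @seealso [calibrateCutoffs()]
#' @export
setClass("CutoffProfile",
    representation(mssCut = "numeric", cssCut = "numeric",
                   profileKind = "character", metadata = "list"))

setValidity("CutoffProfile", function(object) {
    msg <- character()
    if (length(object@mssCut) != 1L || object@mssCut < 0 || object@mssCut > 1)
        msg <- c(msg, "'mssCut' must be a single value in [0, 1]")
    if (length(object@cssCut) != 1L || object@cssCut < 0 || object@cssCut > 1)
        msg <- c(msg, "'cssCut' must be a single value in [0, 1]")
    if (!object@profileKind %in% c("minFP", "minFN", "minSUM", "manual"))
        msg <- c(msg, "'profileKind' must be minFP, minFN, minSUM or manual")
    if (length(msg)) msg else TRUE
})

#' @rdname CutoffProfile-class
#' @param mssCut,cssCut similarity cutoffs in [0, 1].
#' @param profileKind calibration profile label.
#' @param metadata free-form calibration metadata list.
#' @export
CutoffProfile <- function(mssCut, cssCut = 0.75, profileKind = "manual",
                          metadata = list()) {
    new("CutoffProfile", mssCut = as.numeric(mssCut),
        cssCut = as.numeric(cssCut), profileKind = profileKind,
        metadata = metadata)
}

setMethod("show", "CutoffProfile", function(object) {
    cat("CutoffProfile (", object@profileKind, "): mss >= ",
        format(object@mssCut, digits = 4), ", css >= ",
        format(object@cssCut, digits = 4), "\n", sep = "")
})

#' Ground truth planted by the synthetic-data generators
#'
#' @slot deLabels named list: gene -> named numeric vector of signs (+1/-1)
#'   per condition in which the gene is truly regulated.
#' @slot plantedSites data.frame (promoter_id, pwm_id, start, strand) of
#'   motif instances written into the promoter sequences (1-based starts).
#' @slot enrichedTFs pwm ids planted preferentially in regulated promoters.
#' @slot correlationBlocks partition of genes into co-expressed blocks.
#' @slot trueFoldChanges data.frame (gene, timepoint, fold) of linear fold
#'   changes behind a simulated qPCR plate.
#' @export
setClass("PlantedTruth",
    representation(deLabels = "list", plantedSites = "data.frame",
                   enrichedTFs = "character", correlationBlocks = "list",
                   trueFoldChanges = "data.frame"))

PlantedTruth <- function(deLabels = list(),
                         plantedSites = data.frame(
                             promoter_id = character(), pwm_id = character(),
                             start = integer(), strand = character(),
                             stringsAsFactors = FALSE),
                         enrichedTFs = character(),
                         correlationBlocks = list(),
                         trueFoldChanges = data.frame(
                             gene = character(), timepoint = numeric(),
                             fold = numeric(), stringsAsFactors = FALSE)) {
    new("PlantedTruth", deLabels = deLabels, plantedSites = plantedSites,
        enrichedTFs = enrichedTFs, correlationBlocks = correlationBlocks,
        trueFoldChanges = trueFoldChanges)
}

setMethod("show", "PlantedTruth", function(object) {
    cat("PlantedTruth:", length(object@deLabels), "regulated genes,",
        nrow(object@plantedSites), "planted sites,",
        length(object@enrichedTFs), "enriched TFs,",
        length(object@correlationBlocks), "correlation blocks\n")
})

#' Exclusivity partition of differentially expressed genes
#'
#' Assigns each DE gene to the exact subset of conditions in which it passes
#' the thresholds (the regions of a Venn diagram). Region keys are the
#' sorted condition names joined by "&".
#'
#' @slot conditions condition labels.
#' @slot regions named list: region signature -> character vector of genes.
#' @slot directions named list: region signature -> list(up, down, mixed)
#'   splitting the region's genes by direction (a gene is "up"/"down" when
#'   its sign agrees across every condition of its signature).
#' @export
setClass("VennPartition",
    representation(conditions = "character", regions = "list",
                   directions = "list"))

setValidity("VennPartition", function(object) {
    all_genes <- unlist(object@regions, use.names = FALSE)
    if (anyDuplicated(all_genes))
        return("regions must be pairwise disjoint")
    TRUE
})

setMethod("show", "VennPartition", function(object) {
    cat("VennPartition over", length(object@conditions), "conditions\n")
    sizes <- vapply(object@regions, length, integer(1))
    for (k in names(sizes))
        cat(sprintf("  %-20s %d\n", k, sizes[k]))
})

#' Candidate transcription factors after promoter/network intersection
#'
#' @slot promoterTFs factors surviving the promoter density filter.
#' @slot networkTFs the network-derived factor list.
#' @slot synonymMap alias -> canonical symbol map used.
#' @slot final the canonicalised intersection.
#' @slot perGroupExclusive per-treatment exclusive factor sets.
#' @export
setClass("CandidateSet",
    representation(promoterTFs = "character", networkTFs = "character",
                   synonymMap = "character", final = "character",
                   perGroupExclusive = "list"))

setMethod("show", "CandidateSet", function(object) {
    cat("CandidateSet:", length(object@final), "final candidates of",
        length(object@promoterTFs), "promoter-filtered x",
        length(object@networkTFs), "network-derived TFs\n")
    if (length(object@final))
        cat("  ", paste(sort(object@final), collapse = ", "), "\n")
})

#' @rdname CandidateSet-class
#' @param x a \code{CandidateSet}.
#' @export
finalCandidates <- function(x) x@final

#' Minimum spanning tree over correlation distances
#'
#' @slot vertices data.frame (gene, weight) where weight is the standard
#'   deviation of the gene's relative expression across tissues.
#' @slot edges data.frame (from, to, distance) of the n - 1 tree edges.
#' @slot totalWeight sum of tree edge distances.
#' @slot metadata list recording the correlation and distance transforms.
#' @export
setClass("MSTGraph",
    representation(vertices = "data.frame", edges = "data.frame",
                   totalWeight = "numeric", metadata = "list"))

setValidity("MSTGraph", function(object) {
    v <- object@vertices; e <- object@edges
    msg <- character()
    if (nrow(e) != nrow(v) - 1L)
        msg <- c(msg, "a spanning tree must have |V| - 1 edges")
    if (!all(c(e$from, e$to) %in% v$gene))
        msg <- c(msg, "edge endpoints must be vertices")
    if (any(e$distance < 0))
        msg <- c(msg, "edge distances must be non-negative")
    # connectivity (with |V|-1 edges this also implies acyclicity)
    if (nrow(v) > 0 && nrow(e) == nrow(v) - 1L) {
        comp <- stats::setNames(seq_len(nrow(v)), v$gene)
        for (i in seq_len(nrow(e))) {
            a <- comp[e$from[i]]; b <- comp[e$to[i]]
            comp[comp == b] <- a
        }
        if (length(unique(comp)) != 1L)
            msg <- c(msg, "tree must be connected")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "MSTGraph", function(object) {
    cat("MSTGraph:", nrow(object@vertices), "vertices,",
        nrow(object@edges), "edges, total weight",
        format(object@totalWeight, digits = 6), "\n")
    if (!is.null(object@metadata$distance))
        cat("  distance transform:", object@metadata$distance, "\n")
})

#' @rdname MSTGraph-class
#' @param x an \code{MSTGraph}.
#' @export
mstVertices <- function(x) x@vertices
#' @rdname MSTGraph-class
#' @export
mstEdges <- function(x) x@edges
#' @rdname MSTGraph-class
#' @export
mstTotalWeight <- function(x) x@totalWeight
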