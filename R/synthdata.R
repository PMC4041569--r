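# Synthetic-data generators. Every generator takes an explicit seed, is
# bit-reproducible given that seed, and returns the planted ground truth
# alongside the data so downstream recovery is checkable.

#' Simulate a multi-condition differential expression table
#'
#' Plants exclusive and shared regulated genes across the conditions.
#' Regulated genes draw |log2FC| at or above \code{effectMu} (sign recorded
#' in the truth; shared genes use one sign across all conditions) and
#' p-values concentrated near 0 (scaled Beta(0.1, 10)); null genes draw
#' log2FC ~ Normal(0, noiseSd) and uniform p-values.
#'
#' @param nGenes number of genes (> 0).
#' @param conditions condition labels (>= 2; default the three
#'   androgen-deprivation arms Cas, E2, Cas+E2).
#' @param fracExclusive fraction of genes regulated exclusively in each
#'   condition (scalar or one value per condition).
#' @param fracShared fraction regulated in all conditions.
#' @param effectMu minimum |log2FC| of regulated genes (default 4).
#' @param noiseSd log2FC dispersion of null genes (default 0.3).
#' @param seed RNG seed.
#' @return list(table = expression data.frame with gene_id, log2fc_*,
#'   pval_* columns; truth = [PlantedTruth-class]).
#' @export
simulateExpressionTable <- function(nGenes = 2000,
                                    conditions = c("Cas", "E2", "CasE2"),
                                    fracExclusive = 0.05, fracShared = 0.02,
                                    effectMu = 4, noiseSd = 0.3,
                                    seed = NULL) {
    if (nGenes <= 0) stop("'nGenes' must be positive")
    if (length(conditions) < 2L) stop("need at least 2 conditions")
    fracExclusive <- rep_len(fracExclusive, length(conditions))
    if (sum(fracExclusive) + fracShared >= 1)
        stop("regulated fractions must sum to less than 1")
    withSeed(seed, {
        genes <- sprintf("g%04d", seq_len(nGenes))
        nShared <- round(fracShared * nGenes)
        nExcl <- round(fracExclusive * nGenes)
        pool <- sample(genes)  # random assignment order
        sharedGenes <- pool[seq_len(nShared)]
        used <- nShared
        exclGenes <- lapply(nExcl, function(k) {
            g <- pool[used + seq_len(k)]
            used <<- used + k
            g
        })
        names(exclGenes) <- conditions
        regP <- function(n) 1e-4 * stats::rbeta(n, 0.1, 10)
        regLfc <- function(n, sgn) sgn * (effectMu + abs(stats::rnorm(n, 0, 0.5)))
        tab <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
        sharedSign <- sample(c(-1, 1), nShared, replace = TRUE)
        deLabels <- list()
        for (g in seq_len(nShared))
            deLabels[[sharedGenes[g]]] <-
                stats::setNames(rep(sharedSign[g], length(conditions)),
                                conditions)
        for (ci in seq_along(conditions)) {
            cc <- conditions[ci]
            lfc <- stats::rnorm(nGenes, 0, noiseSd)
            p <- stats::runif(nGenes)
            iSh <- match(sharedGenes, genes)
            if (nShared) {
                lfc[iSh] <- regLfc(nShared, sharedSign)
                p[iSh] <- regP(nShared)
            }
            ex <- exclGenes[[cc]]
            if (length(ex)) {
                iEx <- match(ex, genes)
                sgn <- sample(c(-1, 1), length(ex), replace = TRUE)
                lfc[iEx] <- regLfc(length(ex), sgn)
                p[iEx] <- regP(length(ex))
                for (k in seq_along(ex)) {
                    deLabels[[ex[k]]] <- c(deLabels[[ex[k]]],
                                           stats::setNames(sgn[k], cc))
                }
            }
            tab[[paste0("log2fc_", cc)]] <- lfc
            tab[[paste0("pval_", cc)]] <- p
        }
        list(table = tab, truth = PlantedTruth(deLabels = deLabels))
    })
}

#' Simulate a PWM library
#'
#' Each matrix gets a random length in \code{lenRange}; each position has a
#' random dominant base at frequency \code{conservation}, the other three
#' bases sharing the remainder equally. \code{conservation = 1} gives
#' one-hot matrices, \code{0.25} uniform ones. Ids are M001... and factor
#' names TF01... (one matrix per factor).
#'
#' @param nPWMs number of matrices.
#' @param lenRange integer (min, max) motif length; minimum 5 so the core
#'   window fits. Default (12, 18).
#' @param conservation per-position maximum base frequency in [0.25, 1].
#' @param seed RNG seed.
#' @return a [PWMList-class].
#' @export
simulatePWMLibrary <- function(nPWMs = 40, lenRange = c(12, 18),
                               conservation = 0.85, seed = NULL) {
    if (nPWMs <= 0) stop("'nPWMs' must be positive")
    lenRange <- as.integer(lenRange)
    if (min(lenRange) < 5L)
        stop("motif lengths below 5 are rejected (core window must fit)")
    if (conservation < 0.25 || conservation > 1)
        stop("'conservation' must lie in [0.25, 1]")
    withSeed(seed, {
        lens <- seq(lenRange[1L], lenRange[2L])
        pwms <- lapply(seq_len(nPWMs), function(i) {
            L <- lens[sample.int(length(lens), 1L)]
            dom <- sample.int(4L, L, replace = TRUE)
            f <- matrix((1 - conservation) / 3, L, 4L)
            f[cbind(seq_len(L), dom)] <- conservation
            colnames(f) <- DNA_BASES
            PWM(sprintf("M%03d", i), f, tfName = sprintf("TF%02d", i))
        })
        PWMList(pwms)
    })
}

#' Simulate promoter sequences with planted motif instances
#'
#' Backgrounds are i.i.d. with the given GC fraction, all exactly
#' \code{length} bp (the proximal promoter window upstream of the TSS).
#' For each regulated promoter and each matrix in \code{plantSpec}, a
#' Poisson-distributed number of sites (mean = the spec value) is written
#' into the sequence at non-overlapping random positions, on a random
#' strand; the planted word is the matrix consensus (guaranteeing a
#' maximal-score hit) or a word sampled from the matrix. Internal-control
#' promoters receive no planted sites.
#'
#' @param geneIds regulated gene ids (one promoter each).
#' @param pwms the [PWMList-class] the sites are drawn from.
#' @param plantSpec named numeric: pwm id -> expected sites per regulated
#'   promoter. Ids must exist in \code{pwms}.
#' @param controlIds internal-control gene ids (disjoint from
#'   \code{geneIds}); default \code{c("Gapdh", "Tbp7")}.
#' @param length promoter length in bp (default 3000).
#' @param gc background GC fraction (default 0.41, rat genome-wide).
#' @param plantMethod \code{"consensus"} (default) or \code{"sample"}.
#' @param seed RNG seed.
#' @return list(promoters = \code{DNAStringSet} named by gene id (controls
#'   included); truth = [PlantedTruth-class] with the planted sites and
#'   enriched factor ids).
#' @export
simulatePromoters <- function(geneIds, pwms, plantSpec = numeric(),
                              controlIds = c("Gapdh", "Tbp7"),
                              length = 3000, gc = 0.41,
                              plantMethod = c("consensus", "sample"),
                              seed = NULL) {
    plantMethod <- match.arg(plantMethod)
    geneIds <- as.character(geneIds)
    if (any(controlIds %in% geneIds))
        stop("control ids must be disjoint from regulated gene ids")
    if (length(plantSpec) && !all(names(plantSpec) %in% names(pwms)))
        stop("plantSpec names must be pwm ids in the library")
    withSeed(seed, {
        sites <- list()
        mkseq <- function(id, planted) {
            s <- randomDNA(length, gc = gc)
            if (planted && length(plantSpec)) {
                occupied <- cbind(integer(0), integer(0))
                for (pid in names(plantSpec)) {
                    p <- pwms[[pid]]
                    word0 <- if (plantMethod == "consensus") consensusWord(p)
                             else samplePWMWord(p)
                    Lw <- nchar(word0)
                    nSites <- stats::rpois(1L, plantSpec[[pid]])
                    if (nSites * Lw > length)
                        stop("planted sites exceed sequence capacity for '",
                             id, "'")
                    for (k in seq_len(nSites)) {
                        strand <- sample(c("+", "-"), 1L)
                        word <- if (strand == "+") word0
                                else revcompString(word0)
                        pos <- NA_integer_
                        for (try in 1:200) {
                            cand <- sample.int(length - Lw + 1L, 1L)
                            if (!any(cand <= occupied[, 2L] &
                                     cand + Lw - 1L >= occupied[, 1L])) {
                                pos <- cand; break
                            }
                        }
                        if (is.na(pos))
                            stop("planted sites exceed sequence capacity ",
                                 "for '", id, "'")
                        occupied <- rbind(occupied, c(pos, pos + Lw - 1L))
                        substr(s, pos, pos + Lw - 1L) <- word
                        sites[[base::length(sites) + 1L]] <<- data.frame(
                            promoter_id = id, pwm_id = pid, start = pos,
                            strand = strand, stringsAsFactors = FALSE)
                    }
                }
            }
            s
        }
        seqs <- c(vapply(geneIds, mkseq, character(1), planted = TRUE),
                  vapply(as.character(controlIds), mkseq, character(1),
                         planted = FALSE))
        planted <- if (length(sites)) do.call(rbind, sites)
                   else data.frame(promoter_id = character(),
                                   pwm_id = character(), start = integer(),
                                   strand = character(),
                                   stringsAsFactors = FALSE)
        list(promoters = Biostrings::DNAStringSet(seqs),
             truth = PlantedTruth(plantedSites = planted,
                                  enrichedTFs = names(plantSpec) %||%
                                      character()))
    })
}

#' Sample a word from a PWM (one base per position, by its frequencies)
#' @param pwm a [PWM-class].
#' @return a character string of the motif length.
#' @export
samplePWMWord <- function(pwm) {
    f <- pwmFreq(pwm)
    paste(DNA_BASES[vapply(seq_len(nrow(f)), function(i)
        sample.int(4L, 1L, prob = f[i, ]), integer(1))], collapse = "")
}

#' Simulate a block-correlated genes x tissues expression matrix
#'
#' Genes within a block share a latent tissue factor so their expected
#' pairwise correlation is \code{rho}; genes in different blocks are
#' independent (expected correlation 0).
#'
#' @param geneIds gene ids.
#' @param blocks list of character vectors partitioning \code{geneIds}.
#' @param nTissues number of tissues (>= 3; default 50).
#' @param rho within-block correlation, 0 <= rho < 1 (default 0.8).
#' @param seed RNG seed.
#' @return numeric matrix, genes in rows (rownames = ids), tissues in
#'   columns.
#' @export
simulateTissueMatrix <- function(geneIds, blocks, nTissues = 50, rho = 0.8,
                                 seed = NULL) {
    geneIds <- as.character(geneIds)
    if (nTissues < 3L) stop("need at least 3 tissues")
    if (rho < 0 || rho >= 1) stop("'rho' must satisfy 0 <= rho < 1")
    flat <- unlist(blocks, use.names = FALSE)
    if (anyDuplicated(flat) || !setequal(flat, geneIds))
        stop("'blocks' must partition the gene set exactly")
    withSeed(seed, {
        m <- matrix(NA_real_, length(geneIds), nTissues,
                    dimnames = list(geneIds,
                                    sprintf("tissue%02d", seq_len(nTissues))))
        for (b in blocks) {
            shared <- stats::rnorm(nTissues)
            for (g in b)
                m[g, ] <- sqrt(rho) * shared +
                    sqrt(1 - rho) * stats::rnorm(nTissues)
        }
        m
    })
}

#' Simulate a qPCR Ct plate with known fold changes
#'
#' Ct values are generated as \code{baseCt - log2(fold) + Normal(0, ctSd)}
#' with replicate measurements per (gene, timepoint); the reference gene's
#' true fold is identically 1 (enforced).
#'
#' @param trueFold data.frame (gene, timepoint, fold) of linear fold
#'   changes; must include the reference gene with fold 1 at every
#'   timepoint, and fold 1 at the calibrator timepoint for exact recovery.
#' @param referenceGene housekeeping gene id (default "Gapdh").
#' @param ctSd replicate Ct noise SD (default 0.2).
#' @param nReplicates replicates per (gene, timepoint); default 3.
#' @param baseCt baseline Ct (default 24).
#' @param seed RNG seed.
#' @return list(ct = data.frame(gene, timepoint, replicate, ct);
#'   truth = [PlantedTruth-class] carrying \code{trueFold}).
#' @export
simulateCtTable <- function(trueFold, referenceGene = "Gapdh", ctSd = 0.2,
                            nReplicates = 3, baseCt = 24, seed = NULL) {
    need <- c("gene", "timepoint", "fold")
    if (!all(need %in% names(trueFold)))
        stop("'trueFold' needs columns: ", paste(need, collapse = ", "))
    ref <- trueFold[trueFold$gene == referenceGene, ]
    if (nrow(ref) == 0L)
        stop("reference gene '", referenceGene, "' missing from trueFold")
    if (any(ref$fold != 1))
        stop("the reference gene must have true fold 1 at every timepoint")
    tps <- unique(trueFold$timepoint)
    if (!all(tps %in% ref$timepoint))
        stop("reference gene must cover every timepoint")
    withSeed(seed, {
        rows <- trueFold[rep(seq_len(nrow(trueFold)), each = nReplicates), ]
        ct <- data.frame(gene = rows$gene, timepoint = rows$timepoint,
                         replicate = rep(seq_len(nReplicates),
                                         nrow(trueFold)),
                         ct = baseCt - log2(rows$fold) +
                             stats::rnorm(nrow(rows), 0, ctSd),
                         stringsAsFactors = FALSE)
        rownames(ct) <- NULL
        list(ct = ct, truth = PlantedTruth(trueFoldChanges = trueFold))
    })
}
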