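#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults mirror
#' the study design: three androgen-deprivation arms against control,
#' log2FC threshold 1.5 with adjusted p < 0.01, a 10-up/10-down panel per
#' category, 3,000-bp proximal promoters, and density reporting floored at
#' 0.01. Synthetic-input parameters define the default simulated study
#' (2,000 genes, 40 matrices, 8 enriched factors at 0.5 sites per
#' regulated promoter).
#'
#' @param seed master RNG seed; every stage's randomness derives from it.
#' @param conditions treatment labels.
#' @param nGenes,fracExclusive,fracShared,effectMu,noiseSd expression
#'   simulator settings (see [simulateExpressionTable()]).
#' @param lfcCut,alpha DE thresholds (see [filterDE()]).
#' @param topK panel size per category and direction.
#' @param promoterLen,gc promoter simulator settings.
#' @param nPWMs,lenRange,conservation matrix library simulator settings.
#' @param nEnriched,sitesPerGene planted enrichment: how many factors are
#'   planted and at what expected per-promoter rate.
#' @param controlIds internal-control gene ids.
#' @param mssCut,cssCut fixed scanning cutoffs (a manual
#'   [CutoffProfile-class]); chosen so consensus-planted sites (score 1)
#'   always pass while near-random windows do not.
#' @param reportFloor density report floor.
#' @param nDecoyTFs library factors added to the synthetic network list as
#'   decoys.
#' @param distance,nTissues,rho MST stage settings.
#' @param expressionFile,pwmFile,promoterFile,networkFile,tissueFile
#'   optional input paths; when set, the corresponding stage reads the file
#'   instead of simulating.
#' @param synonymMap named alias -> canonical vector for the intersection.
#' @return a config list of class \code{androTFConfig}.
#' @export
pipelineConfig <- function(seed = 1,
                           conditions = c("Cas", "E2", "CasE2"),
                           nGenes = 2000, fracExclusive = 0.05,
                           fracShared = 0.02, effectMu = 4, noiseSd = 0.3,
                           lfcCut = 1.5, alpha = 0.01, topK = 10,
                           promoterLen = 3000, gc = 0.41,
                           nPWMs = 40, lenRange = c(12, 18),
                           conservation = 0.85,
                           nEnriched = 8, sitesPerGene = 0.5,
                           controlIds = c("Gapdh", "Tbp7"),
                           mssCut = 0.95, cssCut = 0.9,
                           reportFloor = 0.01, nDecoyTFs = 5,
                           distance = "sqrt2", nTissues = 50, rho = 0.8,
                           expressionFile = NULL, pwmFile = NULL,
                           promoterFile = NULL, networkFile = NULL,
                           tissueFile = NULL, synonymMap = NULL) {
    cfg <- as.list(environment())
    stopifnot(lfcCut > 0, alpha > 0, alpha < 1, topK > 0,
              promoterLen >= 100, reportFloor >= 0,
              mssCut >= 0, mssCut <= 1, cssCut >= 0, cssCut <= 1,
              distance %in% c("sqrt2", "oneMinus"))
    class(cfg) <- "androTFConfig"
    cfg
}

.stageSeed <- function(seed, k) (as.integer(seed) * 131L + k) %% 2147483647L

#' Run the full discovery pipeline
#'
#' Executes, in order: DE thresholding and exclusivity partitioning of the
#' expression table; selection of the top-regulated panel; PWM scanning of
#' panel and internal-control promoters; per-factor density comparison and
#' per-group exclusivity; intersection with the network-derived factor
#' list; and a correlation-distance MST over candidate expression across
#' tissues. Inputs are read from the paths in the config when given, and
#' simulated (with planted truth) otherwise. All outputs are written under
#' \code{outDir} with metadata headers, and a JSON run manifest records the
#' parameter snapshot and an md5 digest per output file; re-running with
#' the same config reproduces identical digests.
#'
#' An empty DE result does not abort: the pipeline completes with an empty
#' panel and a warning.
#'
#' @param config a [pipelineConfig()] list.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the intermediate objects
#'   (\code{expression}, \code{truth}, \code{deSets}, \code{venn},
#'   \code{panel}, \code{pwms}, \code{promoterTruth}, \code{hits},
#'   \code{comparison}, \code{perGroupExclusive}, \code{candidates},
#'   \code{mst}, \code{centrality}) and the \code{manifest}.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("run")) {
    stopifnot(inherits(config, "androTFConfig"))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    seed <- config$seed
    manifest <- list(tool = paste0("androTF/", pkgVersion()),
                     seed = seed,
                     parameters = config[!vapply(config, is.null,
                                                 logical(1))],
                     started = format(Sys.time(), usetz = TRUE),
                     stages = list())
    outputs <- character()
    emit <- function(stage, n_in, n_out) {
        manifest$stages[[stage]] <<- list(records_in = n_in,
                                          records_out = n_out)
        message(sprintf("[%s] %s -> %s", stage, n_in, n_out))
    }
    baseMeta <- list(seed = seed)

    ## stage 1: expression table + DE selection
    truth <- NULL
    if (!is.null(config$expressionFile)) {
        expr <- readExpressionTable(config$expressionFile)
    } else {
        sim <- simulateExpressionTable(
            nGenes = config$nGenes, conditions = config$conditions,
            fracExclusive = config$fracExclusive,
            fracShared = config$fracShared, effectMu = config$effectMu,
            noiseSd = config$noiseSd, seed = .stageSeed(seed, 1L))
        expr <- sim$table
        truth <- sim$truth
        writePlantedTruth(truth, file.path(outDir, "expression_truth.json"))
        outputs <- c(outputs, "expression_truth.json")
    }
    expr <- addAdjustedP(expr)
    writeExpressionTable(expr, file.path(outDir, "expression.tsv"),
                         baseMeta)
    outputs <- c(outputs, "expression.tsv")
    deSets <- filterDE(expr, lfcCut = config$lfcCut, alpha = config$alpha)
    nDE <- length(unique(unlist(lapply(deSets, unlist),
                                use.names = FALSE)))
    emit("de_select", nrow(expr), nDE)

    result <- list(expression = expr, truth = truth, deSets = deSets)
    if (nDE == 0L) {
        warning("no differentially expressed genes at the configured ",
                "thresholds; pipeline completed with an empty panel")
        panel <- selectTopPanel(expr, vennPartition(deSets),
                                k = config$topK)
        .writeTSV(panel, file.path(outDir, "panel.tsv"), baseMeta)
        outputs <- c(outputs, "panel.tsv")
        manifest$status <- "EMPTY_DE"
        manifest <- .finishManifest(manifest, outDir, outputs)
        result$panel <- panel
        result$manifest <- manifest
        return(invisible(result))
    }

    ## stage 2: exclusivity partition and top panel
    venn <- vennPartition(deSets)
    panel <- selectTopPanel(expr, venn, k = config$topK)
    .writeTSV(panel, file.path(outDir, "panel.tsv"), baseMeta)
    outputs <- c(outputs, "panel.tsv")
    emit("panel", nDE, nrow(panel))

    ## stage 3: matrix library and promoters
    if (!is.null(config$pwmFile)) {
        pwms <- readTransfac(config$pwmFile)
    } else {
        pwms <- simulatePWMLibrary(nPWMs = config$nPWMs,
                                   lenRange = config$lenRange,
                                   conservation = config$conservation,
                                   seed = .stageSeed(seed, 2L))
    }
    writeTransfac(pwms, file.path(outDir, "pwms.transfac"), baseMeta)
    outputs <- c(outputs, "pwms.transfac")
    panelGenes <- sort(unique(panel$gene_id))
    promoterTruth <- NULL
    if (!is.null(config$promoterFile)) {
        promoters <- readPromoterFasta(config$promoterFile)
        missing <- setdiff(c(panelGenes, config$controlIds),
                           names(promoters))
        if (length(missing))
            stop("promoter FASTA misses: ", paste(missing, collapse = ", "))
        promoters <- promoters[c(panelGenes, config$controlIds)]
        enriched <- character()
    } else {
        enriched <- withSeed(.stageSeed(seed, 3L),
                             sample(names(pwms), config$nEnriched))
        plantSpec <- stats::setNames(rep(config$sitesPerGene,
                                         length(enriched)), enriched)
        simP <- simulatePromoters(panelGenes, pwms, plantSpec = plantSpec,
                                  controlIds = config$controlIds,
                                  length = config$promoterLen,
                                  gc = config$gc,
                                  seed = .stageSeed(seed, 4L))
        promoters <- simP$promoters
        promoterTruth <- simP$truth
        writePlantedTruth(promoterTruth,
                          file.path(outDir, "promoter_truth.json"))
        outputs <- c(outputs, "promoter_truth.json")
    }
    writePromoterFasta(promoters, file.path(outDir, "promoters.fa"))
    outputs <- c(outputs, "promoters.fa")

    ## stage 4: scanning
    cutoffs <- CutoffProfile(mssCut = config$mssCut, cssCut = config$cssCut,
                             profileKind = "manual",
                             metadata = list(source = "pipelineConfig"))
    hits <- scanPromoters(promoters, pwms, cutoffs)
    writeHits(hits, file.path(outDir, "hits.tsv"), baseMeta)
    outputs <- c(outputs, "hits.tsv")
    emit("scan", length(promoters) * length(pwms), nrow(hits))

    ## stage 5: density filtering against the internal controls
    tfUniverse <- sort(unique(vapply(pwms@.Data, tfName, character(1))))
    ctrlHits <- hits[hits$promoter_id %in% config$controlIds, , drop = FALSE]
    panelHits <- hits[hits$promoter_id %in% panelGenes, , drop = FALSE]
    regDen <- siteDensity(panelHits, panelGenes, tfNames = tfUniverse)
    ctrlDen <- siteDensity(ctrlHits, config$controlIds,
                           tfNames = tfUniverse)
    comparison <- compareToControls(regDen, ctrlDen,
                                    reportFloor = config$reportFloor)
    writeDensityReport(comparison, file.path(outDir, "density_report.tsv"),
                       baseMeta)
    outputs <- c(outputs, "density_report.tsv")
    promoterTFs <- keptTFs(comparison)
    emit("density", length(tfUniverse), length(promoterTFs))

    ## per-group exclusive factors (per panel category vs the controls)
    groups <- paste0("exclusive-", config$conditions)
    retainedPerGroup <- lapply(groups, function(gp) {
        gg <- unique(panel$gene_id[panel$category == gp])
        if (length(gg) == 0L) return(character())
        keptTFs(compareToControls(
            siteDensity(hits[hits$promoter_id %in% gg, , drop = FALSE], gg,
                        tfNames = tfUniverse),
            ctrlDen, reportFloor = config$reportFloor))
    })
    names(retainedPerGroup) <- config$conditions
    perGroup <- groupExclusiveTFs(retainedPerGroup)

    ## stage 6: intersect with the network-derived factor list
    if (!is.null(config$networkFile)) {
        networkTFs <- readGeneList(config$networkFile)
    } else {
        # synthetic network list: the planted factors, a few library
        # decoys, and external symbols never in the library
        enrichedTF <- vapply(pwms@.Data[names(pwms) %in% enriched], tfName,
                             character(1))
        decoys <- withSeed(.stageSeed(seed, 5L),
            sample(setdiff(tfUniverse, enrichedTF),
                   min(config$nDecoyTFs,
                       length(setdiff(tfUniverse, enrichedTF)))))
        networkTFs <- sort(c(enrichedTF, decoys,
                             c("AR", "ESR1", "ESR2", "TMF1", "OCT1")))
    }
    writeGeneList(networkTFs, file.path(outDir, "network_tfs.txt"),
                  baseMeta)
    outputs <- c(outputs, "network_tfs.txt")
    candidates <- intersectWithNetwork(promoterTFs, networkTFs,
                                       synonymMap = config$synonymMap %||%
                                           character(),
                                       perGroupExclusive = perGroup)
    writeGeneList(finalCandidates(candidates),
                  file.path(outDir, "candidates.txt"), baseMeta)
    outputs <- c(outputs, "candidates.txt")
    emit("intersect", length(promoterTFs), length(finalCandidates(candidates)))

    ## stage 7: correlation-distance MST over candidate expression
    mst <- NULL; centr <- NULL
    mstGenes <- finalCandidates(candidates)
    if (!is.null(config$tissueFile)) {
        tissue <- readTissueMatrix(config$tissueFile)
    } else {
        if (length(mstGenes) < 4L)
            mstGenes <- sort(unique(c(mstGenes, tfUniverse[seq_len(
                min(6L, length(tfUniverse)))])))
        nb <- max(2L, ceiling(length(mstGenes) / 4))
        blocks <- split(mstGenes,
                        rep(seq_len(nb), length.out = length(mstGenes)))
        tissue <- simulateTissueMatrix(mstGenes, blocks,
                                       nTissues = config$nTissues,
                                       rho = config$rho,
                                       seed = .stageSeed(seed, 6L))
    }
    writeTissueMatrix(tissue, file.path(outDir, "tissue_matrix.tsv"),
                      baseMeta)
    outputs <- c(outputs, "tissue_matrix.tsv")
    if (nrow(tissue) >= 2L) {
        r <- correlationMatrix(tissue)
        d <- toDistance(r, method = config$distance)
        mst <- buildMST(d, vertexWeights = vertexSD(tissue))
        centr <- mstCentrality(mst)
        writePajek(mst, file.path(outDir, "mst.net"))
        .writeTSV(centr, file.path(outDir, "hub_report.tsv"), baseMeta)
        outputs <- c(outputs, "mst.net", "hub_report.tsv")
        emit("mst", nrow(tissue), nrow(mstEdges(mst)))
    }

    manifest$status <- "OK"
    manifest <- .finishManifest(manifest, outDir, outputs)
    result <- c(result, list(
        venn = venn, panel = panel, pwms = pwms,
        promoterTruth = promoterTruth, hits = hits,
        comparison = comparison, perGroupExclusive = perGroup,
        candidates = candidates, mst = mst, centrality = centr,
        manifest = manifest))
    invisible(result)
}

.finishManifest <- function(manifest, outDir, outputs) {
    digests <- tools::md5sum(file.path(outDir, outputs))
    names(digests) <- outputs
    manifest$digests <- as.list(digests)
    manifest$finished <- format(Sys.time(), usetz = TRUE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    manifest
}
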