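# Synthetic-data generators: determinism and truth consistency.

test_that("generators are bit-reproducible given a seed", {
    a <- simulateExpressionTable(nGenes = 200, seed = 9)
    b <- simulateExpressionTable(nGenes = 200, seed = 9)
    expect_identical(a, b)
    p1 <- simulatePWMLibrary(5, seed = 9)
    p2 <- simulatePWMLibrary(5, seed = 9)
    expect_identical(lapply(p1@.Data, pwmFreq), lapply(p2@.Data, pwmFreq))
    s1 <- simulatePromoters(c("g1", "g2"), p1,
                            plantSpec = setNames(1, names(p1)[1]),
                            length = 500, seed = 9)
    s2 <- simulatePromoters(c("g1", "g2"), p1,
                            plantSpec = setNames(1, names(p1)[1]),
                            length = 500, seed = 9)
    expect_identical(as.character(s1$promoters), as.character(s2$promoters))
    expect_identical(s1$truth@plantedSites, s2$truth@plantedSites)
    m1 <- simulateTissueMatrix(letters[1:4], list(letters[1:2],
                                                  letters[3:4]), seed = 9)
    m2 <- simulateTissueMatrix(letters[1:4], list(letters[1:2],
                                                  letters[3:4]), seed = 9)
    expect_identical(m1, m2)
})

test_that("generators leave the session RNG stream untouched", {
    set.seed(123)
    before <- .Random.seed
    invisible(simulateExpressionTable(nGenes = 50, seed = 1))
    invisible(simulatePWMLibrary(3, seed = 2))
    expect_identical(.Random.seed, before)
})

test_that("expression simulator plants the requested structure", {
    sim <- simulateExpressionTable(nGenes = 1000, fracExclusive = 0.05,
                                   fracShared = 0.02, seed = 10)
    truth <- sim$truth@deLabels
    nCond <- vapply(truth, length, integer(1))
    expect_identical(sum(nCond == 3), 20L)           # shared genes
    expect_identical(sum(nCond == 1), 150L)          # exclusive genes
    # regulated effect sizes honour the floor
    tab <- sim$table
    for (g in names(truth)) for (cc in names(truth[[g]])) {
        lfc <- tab[tab$gene_id == g, paste0("log2fc_", cc)]
        expect_gte(abs(lfc), 4)
        expect_identical(sign(lfc), unname(truth[[g]][cc]))
    }
    # degenerate settings
    null <- simulateExpressionTable(nGenes = 300, fracExclusive = 0,
                                    fracShared = 0, seed = 11)
    expect_length(null$truth@deLabels, 0)
    de <- filterDE(null$table)
    expect_true(all(vapply(de, function(s)
        length(s$up) + length(s$down), integer(1)) == 0))
    expect_error(simulateExpressionTable(nGenes = 0), "positive")
    expect_error(simulateExpressionTable(conditions = "Cas"),
                 "at least 2")
    expect_error(simulateExpressionTable(fracExclusive = 0.3,
                                         fracShared = 0.2), "less than 1")
})

test_that("all-shared tables collapse the partition to the triple region", {
    sim <- simulateExpressionTable(nGenes = 60, fracExclusive = 0,
                                   fracShared = 0.999, effectMu = 4,
                                   seed = 12)
    # every gene is regulated in all three conditions
    vp <- vennPartition(filterDE(sim$table))
    occ <- names(Filter(length, vennRegions(vp)))
    expect_identical(occ, "Cas&CasE2&E2")
})

test_that("PWM library simulator respects its limits", {
    lib <- simulatePWMLibrary(nPWMs = 10, lenRange = c(8, 14), seed = 13)
    expect_length(lib, 10)
    for (p in lib@.Data) {
        expect_true(nrow(pwmFreq(p)) >= 8 && nrow(pwmFreq(p)) <= 14)
        expect_equal(rowSums(pwmFreq(p)), rep(1, nrow(pwmFreq(p))),
                     tolerance = 1e-12)
    }
    expect_false(anyDuplicated(names(lib)) > 0)
    onehot <- simulatePWMLibrary(3, conservation = 1, seed = 14)
    for (p in onehot@.Data)
        expect_identical(matrixSimilarity(p, consensusWord(p)), 1)
    uniform <- simulatePWMLibrary(2, conservation = 0.25, seed = 15)
    for (p in uniform@.Data)
        expect_equal(informationVector(p), rep(0, nrow(pwmFreq(p))))
    expect_error(simulatePWMLibrary(3, lenRange = c(3, 6)), "below 5")
})

test_that("promoter simulator writes sites where the truth says", {
    pwms <- simulatePWMLibrary(6, seed = 16)
    genes <- sprintf("g%02d", 1:10)
    plant <- setNames(c(1, 0.5), names(pwms)[1:2])
    sim <- simulatePromoters(genes, pwms, plantSpec = plant,
                             controlIds = c("c1", "c2"), length = 2000,
                             seed = 17)
    proms <- sim$promoters
    expect_identical(sort(names(proms)), sort(c(genes, "c1", "c2")))
    expect_true(all(Biostrings::width(proms) == 2000))
    st <- sim$truth@plantedSites
    expect_gt(nrow(st), 0)
    for (i in seq_len(nrow(st))) {
        p <- pwms[[st$pwm_id[i]]]
        word <- consensusWord(p)
        if (st$strand[i] == "-")
            word <- revcompChar(word)
        seen <- substr(as.character(proms[[st$promoter_id[i]]]),
                       st$start[i], st$start[i] + nchar(word) - 1L)
        expect_identical(seen, word)
    }
    # controls receive no planted sites
    expect_false(any(st$promoter_id %in% c("c1", "c2")))
    expect_error(simulatePromoters(genes, pwms, controlIds = genes[1]),
                 "disjoint")
    expect_error(simulatePromoters("g1", pwms,
                                   plantSpec = setNames(40, names(pwms)[1]),
                                   length = 100, seed = 1),
                 "capacity")
})

test_that("background-only promoters match the calibrated false-positive rate", {
    pwm <- simulatePWMLibrary(1, lenRange = c(10, 10), seed = 18)[[1]]
    prof <- calibrateCutoffs(pwm, gc = 0.5, nWindows = 5e4,
                             fpTarget = 5e-3, cssCut = 0, profile = "minFP",
                             seed = 19)
    sim <- simulatePromoters(sprintf("g%02d", 1:20), PWMList(list(pwm)),
                             length = 2000, gc = 0.5, seed = 20)
    hits <- scanPromoters(sim$promoters, PWMList(list(pwm)), prof)
    nWin <- 20 * (2000 - 9) * 2
    expected <- nWin * 5e-3
    # within 3 SD of the binomial expectation
    expect_lt(abs(nrow(hits) - expected), 3 * sqrt(expected))
})

test_that("tissue matrix plants the requested correlation structure", {
    genes <- sprintf("g%02d", 1:10)
    blocks <- list(genes[1:5], genes[6:10])
    m <- simulateTissueMatrix(genes, blocks, nTissues = 200, rho = 0.8,
                              seed = 21)
    r <- correlationMatrix(m)
    within <- r[genes[1:5], genes[1:5]][upper.tri(diag(5))]
    across <- as.vector(r[genes[1:5], genes[6:10]])
    expect_gt(mean(within), 0.7)
    expect_lt(abs(mean(across)), 0.15)
    # rho = 0 gives near-independence
    m0 <- simulateTissueMatrix(genes, blocks, nTissues = 200, rho = 0,
                               seed = 22)
    r0 <- correlationMatrix(m0)
    expect_lt(max(abs(r0[upper.tri(r0)])), 0.35)
    expect_error(simulateTissueMatrix(genes, list(genes[1:4])),
                 "partition")
    expect_error(simulateTissueMatrix(genes, blocks, nTissues = 2),
                 "at least 3")
})

test_that("Ct simulator enforces the reference-gene contract", {
    tf <- data.frame(gene = c("T", "T"), timepoint = c(0, 3),
                     fold = c(1, 2))
    expect_error(simulateCtTable(tf, referenceGene = "Gapdh"),
                 "missing")
    tf2 <- rbind(tf, data.frame(gene = "Gapdh", timepoint = c(0, 3),
                                fold = c(1, 2)))
    expect_error(simulateCtTable(tf2), "fold 1")
    tf2$fold[tf2$gene == "Gapdh"] <- 1
    sim <- simulateCtTable(tf2, ctSd = 0, nReplicates = 3, seed = 23)
    expect_identical(nrow(sim$ct), 12L)
    expect_true(all(table(sim$ct$gene, sim$ct$timepoint) == 3))
})
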