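# DE thresholding, Venn partitioning and panel selection.

test_that("BH adjustment matches the step-up definition", {
    expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(adjustBH(rep(1, 5)), rep(1, 5))
    expect_equal(adjustBH(0.37), 0.37)
    set.seed(21)
    for (rep in 1:50) {
        p <- runif(sample(1:40, 1))
        expect_equal(adjustBH(p), stepUpBH(p), tolerance = 1e-12)
    }
    expect_error(adjustBH(c(0.5, 1.2)), "\\[0, 1\\]")
})

makeTable <- function(lfc, p, conds = c("A", "B")) {
    tab <- data.frame(gene_id = sprintf("g%02d", seq_along(lfc[[1]])),
                      stringsAsFactors = FALSE)
    for (cc in conds) {
        tab[[paste0("log2fc_", cc)]] <- lfc[[cc]]
        tab[[paste0("pval_", cc)]] <- p[[cc]]
    }
    tab
}

test_that("filterDE applies strict thresholds on log2FC and adjusted p", {
    tab <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                      log2fc_X = c(2, 1.5, -3, -2, 0.2),
                      pval_X = c(1e-5, 1e-5, 1e-5, 1e-5, 1e-5),
                      log2fc_Y = c(0, 0, 0, 0, 0),
                      pval_Y = rep(0.5, 5),
                      qval_X = c(0.005, 0.005, 0.02, 0.005, 0.005),
                      qval_Y = rep(1, 5), stringsAsFactors = FALSE)
    de <- filterDE(tab)
    expect_identical(de$X$up, "a")          # 2 > 1.5, q < 0.01
    expect_false("b" %in% de$X$up)          # boundary 1.5 excluded
    expect_false("c" %in% de$X$down)        # q = 0.02 fails alpha
    expect_identical(de$X$down, "d")
    expect_identical(de$Y$up, character(0))
})

test_that("filterDE recovers planted labels with high sensitivity/specificity", {
    sens <- spec <- numeric(10)
    for (s in 1:10) {
        sim <- simulateExpressionTable(nGenes = 2000, fracExclusive = 0.05,
                                       fracShared = 0.02, effectMu = 4,
                                       noiseSd = 0.3, seed = 100 + s)
        de <- filterDE(sim$table)
        truth <- sim$truth@deLabels
        tp <- fp <- fn <- tn <- 0
        for (cc in names(de)) {
            called <- union(de[[cc]]$up, de[[cc]]$down)
            regulated <- names(truth)[vapply(truth, function(x)
                cc %in% names(x), logical(1))]
            tp <- tp + length(intersect(called, regulated))
            fn <- fn + length(setdiff(regulated, called))
            fp <- fp + length(setdiff(called, regulated))
            tn <- tn + 2000 - length(union(called, regulated))
        }
        sens[s] <- tp / (tp + fn)
        spec[s] <- tn / (tn + fp)
    }
    expect_true(all(sens >= 0.95))
    expect_true(all(spec >= 0.95))
})

test_that("venn partition matches hand enumeration and brute force", {
    sets <- list(A = c("g1", "g2"), B = "g2", C = c("g2", "g3"))
    vp <- vennPartition(sets)
    r <- vennRegions(vp)
    expect_identical(r[["A"]], "g1")
    expect_identical(r[["C"]], "g3")
    expect_identical(r[["A&B&C"]], "g2")
    expect_identical(unname(vapply(r[c("B", "A&B", "A&C", "B&C")], length,
                                   integer(1))), rep(0L, 4))
    # pairwise-disjoint sets leave only singleton regions occupied
    vp2 <- vennPartition(list(A = "x", B = "y", C = "z"))
    occupied <- names(Filter(length, vennRegions(vp2)))
    expect_setequal(occupied, c("A", "B", "C"))
    # random instances vs the bitmask oracle, 3 and 4 sets
    set.seed(22)
    for (rep in 1:20) {
        k <- sample(3:4, 1)
        sets <- lapply(seq_len(k), function(i)
            sample(sprintf("g%03d", 1:100), sample(5:60, 1)))
        names(sets) <- LETTERS[seq_len(k)]
        got <- Filter(length, vennRegions(vennPartition(sets)))
        want <- bruteVenn(sets)
        expect_identical(got[order(names(got))],
                         want[order(names(want))])
    }
})

test_that("venn partition is a partition: disjoint and covering", {
    set.seed(23)
    for (rep in 1:10) {
        sets <- lapply(1:3, function(i) sample(sprintf("g%02d", 1:50), 20))
        names(sets) <- c("Cas", "E2", "CasE2")
        r <- vennRegions(vennPartition(sets))
        all_genes <- unlist(r, use.names = FALSE)
        expect_false(anyDuplicated(all_genes) > 0)
        expect_setequal(all_genes, unique(unlist(sets)))
    }
})

test_that("top panel takes 10 up + 10 down per category, 80 in total", {
    sim <- simulateExpressionTable(nGenes = 2000, seed = 42)
    de <- filterDE(sim$table)
    vp <- vennPartition(de)
    panel <- selectTopPanel(sim$table, vp, k = 10)
    expect_identical(nrow(panel), 80L)
    counts <- table(panel$category, panel$direction)
    expect_true(all(counts == 10))
    expect_setequal(rownames(counts),
                    c("exclusive-Cas", "exclusive-E2", "exclusive-CasE2",
                      "shared-by-all"))
    # a gene appears in exactly one category
    expect_false(anyDuplicated(panel$gene_id) > 0)
    # ranked by |log2FC| within category and direction
    for (cat in rownames(counts)) for (dir in c("up", "down")) {
        v <- abs(panel$log2fc[panel$category == cat &
                              panel$direction == dir])
        expect_true(all(diff(v) <= 1e-12))
    }
})

test_that("scarce categories contribute what they have, without padding", {
    tab <- makeTable(
        lfc = list(A = c(3, 4, 5, -3, 0, 0), B = c(0, 0, 0, 0, 3, -4)),
        p = list(A = c(1e-9, 1e-9, 1e-9, 1e-9, 0.9, 0.9),
                 B = c(0.9, 0.9, 0.9, 0.9, 1e-9, 1e-9)),
        conds = c("A", "B"))
    de <- filterDE(tab)
    panel <- selectTopPanel(tab, vennPartition(de), k = 10)
    a <- panel[panel$category == "exclusive-A", ]
    expect_identical(sum(a$direction == "up"), 3L)
    expect_identical(sum(a$direction == "down"), 1L)
})

test_that("panel selection is deterministic under row shuffling and ties", {
    set.seed(24)
    sim <- simulateExpressionTable(nGenes = 500, seed = 7)
    # force ties: round fold changes coarsely
    tab <- sim$table
    for (cc in c("Cas", "E2", "CasE2"))
        tab[[paste0("log2fc_", cc)]] <-
            round(tab[[paste0("log2fc_", cc)]], 1)
    de <- filterDE(tab)
    vp <- vennPartition(de)
    ref <- selectTopPanel(tab, vp, k = 10)
    for (rep in 1:5) {
        shuf <- tab[sample(nrow(tab)), ]
        got <- selectTopPanel(shuf, vennPartition(filterDE(shuf)), k = 10)
        expect_identical(got, ref)
    }
})
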