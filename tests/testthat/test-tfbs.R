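# Match-style PWM scoring and scanning.

test_that("information vector hits its analytic limits and formula values", {
    expect_equal(informationVector(matrix(0.25, 6, 4)), rep(0, 6))
    onehot <- matrix(c(1, 0, 0, 0), 5, 4, byrow = TRUE)
    expect_equal(informationVector(onehot), rep(log(4), 5))
    half <- matrix(c(0.5, 0.5, 0, 0), 5, 4, byrow = TRUE)
    expect_equal(informationVector(half), rep(log(2), 5))
    expect_error(informationVector(matrix(0.3, 5, 4)), "sum to 1")
})

test_that("mss/css equal brute-force evaluation over all windows of toy PWMs", {
    set.seed(11)
    for (L in c(5, 6)) {
        f <- randomFreqMatrix(L)
        pwm <- PWM("toy", f)
        words <- allWords(L)
        mss <- vapply(words, function(w) matrixSimilarity(pwm, w),
                      numeric(1), USE.NAMES = FALSE)
        css <- vapply(words, function(w) coreSimilarity(pwm, w),
                      numeric(1), USE.NAMES = FALSE)
        expect_equal(mss, vapply(words, function(w) oracleScore(f, w),
                                 numeric(1), USE.NAMES = FALSE),
                     tolerance = 1e-12)
        core <- coreStart(pwm) + 0:4
        expect_equal(css, vapply(words, function(w) oracleScore(f, w, core),
                                 numeric(1), USE.NAMES = FALSE),
                     tolerance = 1e-12)
        expect_true(all(mss >= 0 & mss <= 1))
    }
})

test_that("consensus scores exactly 1 and anti-consensus exactly 0", {
    set.seed(12)
    pwm <- toyPWM(sample(BASES, 10, TRUE))
    f <- pwmFreq(pwm)
    anti <- paste(BASES[apply(f, 1, which.min)], collapse = "")
    expect_identical(matrixSimilarity(pwm, consensusWord(pwm)), 1)
    expect_identical(matrixSimilarity(pwm, anti), 0)
    # degenerate: fully uniform matrix scores 1 by the Max = Min convention
    uni <- PWM("u", matrix(0.25, 6, 4))
    expect_identical(matrixSimilarity(uni, "ACGTAC"), 1)
    expect_identical(coreSimilarity(uni, "ACGTAC"), 1)
})

test_that("css is 1 for a consensus core with mismatched flanks", {
    pwm <- toyPWM(c("A", "A", "C", "C", "G", "G", "T", "T"))
    core <- coreStart(pwm) + 0:4
    cons <- strsplit(consensusWord(pwm), "")[[1]]
    word <- cons
    flank <- setdiff(seq_along(word), core)[1]
    word[flank] <- BASES[which.min(pwmFreq(pwm)[flank, ])]
    word <- paste(word, collapse = "")
    expect_identical(coreSimilarity(pwm, word), 1)
    expect_lt(matrixSimilarity(pwm, word), 1)
})

test_that("ambiguity codes give no-score", {
    pwm <- toyPWM(c("A", "C", "G", "T", "A"))
    expect_true(is.na(matrixSimilarity(pwm, "ANGTA")))
    hits <- scanSequence("ACGTANNNNNACGTA", pwm, CutoffProfile(0, 0), "p")
    # windows overlapping the N run are skipped, the clean ends are scored
    expect_true(all(hits$start %in% c(1, 11)))
})

test_that("mss is invariant under scaling the information vector", {
    # multiplying all I(i) by c > 0 cancels in (cur-mn)/(mx-mn); verified
    # by comparing a PWM with a sharpened copy that has proportional info
    set.seed(13)
    f <- randomFreqMatrix(8)
    I <- informationVector(f)
    word <- randomString(8)
    # direct check on the normalised form with scaled weights
    sc <- function(k) {
        cur <- sum(k * I * f[cbind(1:8, match(strsplit(word, "")[[1]],
                                              BASES))])
        mx <- sum(k * I * apply(f, 1, max))
        mn <- sum(k * I * apply(f, 1, min))
        (cur - mn) / (mx - mn)
    }
    expect_equal(sc(1), sc(7.3), tolerance = 1e-12)
    expect_equal(matrixSimilarity(PWM("x", f), word), sc(1),
                 tolerance = 1e-12)
})

test_that("core finder maximises 5-window information, leftmost on ties", {
    # one-hot block at positions 4-8 of an otherwise uniform matrix
    f <- matrix(0.25, 12, 4, dimnames = list(NULL, BASES))
    f[4:8, ] <- 0; f[cbind(4:8, c(1, 2, 3, 4, 1))] <- 1
    expect_identical(findCore(f), 4L)
    expect_identical(findCore(matrix(0.25, 9, 4)), 1L)
    set.seed(14)
    for (rep in 1:20) {
        f <- randomFreqMatrix(sample(6:15, 1))
        info <- informationVector(f)
        brute <- which.max(vapply(seq_len(nrow(f) - 4), function(i)
            sum(info[i:(i + 4)]), numeric(1)))
        expect_identical(findCore(f), brute)
    }
})

test_that("planted sites are found at the recorded position and strand", {
    set.seed(15)
    pwm <- toyPWM(sample(BASES, 12, TRUE), id = "M1", tf = "TFX")
    bg <- randomString(600)
    s <- bg
    substr(s, 101, 112) <- consensusWord(pwm)
    hits <- scanSequence(s, pwm, CutoffProfile(0.95, 0.99), "prom")
    expect_true(any(hits$start == 101 & hits$strand == "+" & hits$mss == 1))
    # reverse-complement planting is reported on the minus strand
    s2 <- bg
    substr(s2, 201, 212) <- revcompChar(consensusWord(pwm))
    hits2 <- scanSequence(s2, pwm, CutoffProfile(0.95, 0.99), "prom")
    expect_true(any(hits2$start == 201 & hits2$strand == "-" &
                    hits2$mss == 1))
})

test_that("scanning S and revcomp(S) gives mirrored hit sets", {
    set.seed(16)
    pwm <- toyPWM(sample(BASES, 8, TRUE))
    L <- 8
    cut <- CutoffProfile(0.7, 0.7)
    for (rep in 1:25) {
        s <- randomString(300)
        n <- nchar(s)
        h1 <- scanSequence(s, pwm, cut, "p")
        h2 <- scanSequence(revcompChar(s), pwm, cut, "p")
        mirrored <- data.frame(
            start = n - h2$end + 1L,
            strand = as.character(ifelse(h2$strand == "+", "-", "+")),
            mss = h2$mss, stringsAsFactors = FALSE)
        o1 <- order(h1$start, h1$strand)
        o2 <- order(mirrored$start, mirrored$strand)
        expect_equal(h1$start[o1], mirrored$start[o2])
        expect_equal(h1$strand[o1], mirrored$strand[o2])
        expect_equal(h1$mss[o1], mirrored$mss[o2], tolerance = 1e-12)
    }
})

test_that("scanner equals a naive double-loop implementation", {
    set.seed(17)
    f <- randomFreqMatrix(6)
    pwm <- PWM("n", f)
    cut <- CutoffProfile(0.8, 0.75)
    s <- randomString(120)
    hits <- scanSequence(s, pwm, cut, "p")
    # naive: slide over both strands explicitly
    core <- coreStart(pwm) + 0:4
    naive <- list()
    for (i in 1:(nchar(s) - 5)) {
        w <- substr(s, i, i + 5)
        for (str in c("+", "-")) {
            word <- if (str == "+") w else revcompChar(w)
            m <- oracleScore(f, word)
            cs <- oracleScore(f, word, core)
            if (!is.na(m) && m >= 0.8 && cs >= 0.75)
                naive[[length(naive) + 1L]] <-
                    data.frame(start = i, strand = str, mss = m)
        }
    }
    naive <- do.call(rbind, naive)
    o1 <- order(hits$start, hits$strand)
    o2 <- order(naive$start, naive$strand)
    expect_equal(hits$start[o1], naive$start[o2])
    expect_equal(hits$strand[o1], naive$strand[o2])
    expect_equal(hits$mss[o1], naive$mss[o2], tolerance = 1e-12)
})

test_that("sequences shorter than the motif warn and return no hits", {
    pwm <- toyPWM(c("A", "C", "G", "T", "A", "C"))
    expect_warning(h <- scanSequence("ACG", pwm, CutoffProfile(0, 0), "p"),
                   "shorter than motif")
    expect_identical(nrow(h), 0L)
})

test_that("cutoff calibration behaves across profiles", {
    pwm <- toyPWM(c("A", "C", "G", "T", "A", "C", "G", "T"), cons = 0.9)
    # minFN with fnTarget = 0 on a one-hot matrix demands perfect sites
    onehot <- toyPWM(c("A", "C", "G", "T", "A"), cons = 1)
    prof <- calibrateCutoffs(onehot, nWindows = 2000, fpTarget = 1e-3,
                             fnTarget = 0, profile = "minFN", seed = 1)
    expect_identical(prof@mssCut, 1)
    # degenerate: uniform PWM, every window scores 1; profile well-defined
    uni <- PWM("u", matrix(0.25, 8, 4))
    prof2 <- calibrateCutoffs(uni, nWindows = 2000, fpTarget = 0.5,
                              profile = "minFP", seed = 2)
    expect_identical(prof2@mssCut, 1)
    # quantile semantics: requested rate needs enough windows
    expect_error(calibrateCutoffs(pwm, nWindows = 100, fpTarget = 1e-3),
                 "too small")
    # minSUM sits between pure-FP and pure-FN cutoffs
    p3 <- calibrateCutoffs(pwm, nWindows = 5000, fpTarget = 0.01,
                           fnTarget = 0.1, profile = "minSUM", seed = 3)
    expect_true(p3@mssCut > 0 && p3@mssCut <= 1)
    expect_identical(p3@profileKind, "minSUM")
})
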