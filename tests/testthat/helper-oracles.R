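# Independent oracles and small fixture builders. Each oracle is a direct,
# unoptimised transcription of the defining formula or a brute-force
# enumeration; none share code with the implementation under test.

BASES <- c("A", "C", "G", "T")

# Build a PWM with one dominant base per position at `cons` frequency.
toyPWM <- function(dominant, cons = 0.85, id = "toy", tf = id) {
    L <- length(dominant)
    f <- matrix((1 - cons) / 3, L, 4, dimnames = list(NULL, BASES))
    f[cbind(seq_len(L), match(dominant, BASES))] <- cons
    PWM(id, f, tfName = tf)
}

randomFreqMatrix <- function(L) {
    f <- matrix(stats::rexp(L * 4), L, 4, dimnames = list(NULL, BASES))
    f / rowSums(f)
}

# Direct evaluation of the information-weighted similarity over `pos`.
oracleScore <- function(freq, word, pos = seq_len(nrow(freq))) {
    I <- numeric(nrow(freq))
    for (i in seq_len(nrow(freq)))
        for (B in 1:4)
            if (freq[i, B] > 0)
                I[i] <- I[i] + freq[i, B] * log(4 * freq[i, B])
    cur <- 0; mx <- 0; mn <- 0
    for (i in pos) {
        b <- match(substr(word, i, i), BASES)
        if (is.na(b)) return(NA_real_)
        cur <- cur + I[i] * freq[i, b]
        mx <- mx + I[i] * max(freq[i, ])
        mn <- mn + I[i] * min(freq[i, ])
    }
    if (mx - mn < 1e-12) return(1)
    (cur - mn) / (mx - mn)
}

allWords <- function(L) {
    g <- do.call(expand.grid, rep(list(BASES), L))
    apply(g, 1, paste, collapse = "")
}

# Step-up BH definition evaluated literally.
stepUpBH <- function(p) {
    m <- length(p)
    ord <- order(p)
    q <- numeric(m)
    sorted <- p[ord]
    run <- Inf
    for (i in m:1) {
        run <- min(run, m * sorted[i] / i)
        q[i] <- min(run, 1)
    }
    out <- numeric(m)
    out[ord] <- q
    out
}

# Brute-force Venn regions via per-gene membership signatures.
bruteVenn <- function(sets) {
    genes <- sort(unique(unlist(sets, use.names = FALSE)))
    sig <- vapply(genes, function(g) {
        inn <- names(sets)[vapply(sets, function(s) g %in% s, logical(1))]
        paste(sort(inn), collapse = "&")
    }, character(1))
    split(genes, sig)
}

# Minimum spanning-tree weight by exhaustive enumeration (n <= 7).
bruteMSTWeight <- function(d) {
    n <- nrow(d)
    ij <- which(upper.tri(d), arr.ind = TRUE)
    ne <- nrow(ij)
    best <- Inf
    for (sel in utils::combn(ne, n - 1, simplify = FALSE)) {
        # connectivity check by label propagation
        comp <- seq_len(n)
        for (e in sel) {
            a <- comp[ij[e, 1]]; b <- comp[ij[e, 2]]
            comp[comp == b] <- a
        }
        if (length(unique(comp)) == 1L)
            best <- min(best, sum(d[ij[sel, , drop = FALSE]]))
    }
    best
}

# Two-pass Pearson correlation of two vectors.
naiveCor <- function(x, y) {
    mx <- sum(x) / length(x); my <- sum(y) / length(y)
    num <- sum((x - mx) * (y - my))
    num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Degree-4 polynomial least squares via explicit normal equations.
naiveQuartic <- function(x, y) {
    X <- outer(x, 0:4, `^`)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    fitted <- as.numeric(X %*% beta)
    list(coefficients = as.numeric(beta), rss = sum((y - fitted)^2))
}

randomString <- function(n) paste(sample(BASES, n, TRUE), collapse = "")

revcompChar <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}
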