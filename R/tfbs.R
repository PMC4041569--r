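#' Per-position information vector of a PWM
#'
#' The conservation weight of position i is
#' \eqn{I(i) = \sum_B f(i,B) \ln(4 f(i,B))}, with \eqn{0 \ln 0 \equiv 0}.
#' It is 0 for a uniform position and \eqn{\ln 4} for a one-hot position,
#' and is used to weight positions in the matrix similarity score so that
#' conserved positions dominate.
#'
#' @param pwm a [PWM-class] object or an L x 4 frequency matrix.
#' @return numeric vector of length L with values in \eqn{[0, \ln 4]}.
#' @examples
#' informationVector(PWM("M", matrix(0.25, 6, 4)))  # all zero
#' @export
informationVector <- function(pwm) {
    f <- if (is(pwm, "PWM")) pwmFreq(pwm) else as.matrix(pwm)
    if (any(abs(rowSums(f) - 1) > 1e-9))
        stop("frequency rows must sum to 1")
    term <- f * log(4 * f)
    term[f == 0] <- 0
    rowSums(term)
}

#' Locate the 5-position core window
#'
#' The core is the 5 consecutive positions maximising the summed
#' information vector; ties are broken leftmost.
#'
#' @param pwm a [PWM-class] object or frequency matrix.
#' @return 1-based start of the core window.
#' @export
findCore <- function(pwm) {
    f <- if (is(pwm, "PWM")) pwmFreq(pwm) else as.matrix(pwm)
    L <- nrow(f)
    if (L < 5L) stop("motif length must be >= 5")
    info <- informationVector(f)
    win <- vapply(seq_len(L - 4L), function(i) sum(info[i:(i + 4L)]),
                  numeric(1))
    which.max(win)  # leftmost maximum
}

#' Consensus word of a PWM
#'
#' Per position, the base with the highest frequency (ties broken in
#' A < C < G < T order).
#' @param pwm a [PWM-class] object.
#' @return a character string of length L.
#' @export
consensusWord <- function(pwm) {
    f <- pwmFreq(pwm)
    paste(DNA_BASES[apply(f, 1L, which.max)], collapse = "")
}

# Vectorised scoring machinery ------------------------------------------------

# Score all windows of an encoded sequence against positions `pos` of the
# PWM. Returns the normalised similarity for every window start
# 1..(n - L + 1); windows containing ambiguity codes score NA.
.scoreAllWindows <- function(freq, info, s, pos, L) {
    nw <- length(s) - L + 1L
    if (nw < 1L) return(numeric(0))
    cur <- numeric(nw)
    for (i in pos) {
        row <- unname(freq[i, ])
        cur <- cur + info[i] * row[s[i:(i + nw - 1L)]]
    }
    mx <- sum(info[pos] * apply(freq[pos, , drop = FALSE], 1L, max))
    mn <- sum(info[pos] * apply(freq[pos, , drop = FALSE], 1L, min))
    if (mx - mn < 1e-12) {
        out <- rep(1, nw)
        out[is.na(cur)] <- NA_real_
        return(out)
    }
    (cur - mn) / (mx - mn)
}

.scoreWord <- function(pwm, word, pos) {
    s <- encodeDNA(word)
    f <- pwmFreq(pwm)
    if (length(s) != nrow(f))
        stop("window length must equal the motif length")
    if (anyNA(s)) return(NA_real_)  # ambiguity code: no-score
    info <- informationVector(f)
    .scoreAllWindows(f, info, s, pos, nrow(f))[1L]
}

#' Matrix similarity score (MSS)
#'
#' Information-weighted similarity between a PWM and a DNA word of the same
#' length: \code{(Current - Min) / (Max - Min)} where
#' \code{Current = sum_i I(i) f(i, b_i)} and Max/Min use the per-position
#' maximum/minimum frequencies. The consensus word scores 1 and the
#' anti-consensus word 0. A fully uniform matrix (Max = Min) scores 1 by
#' convention. Windows containing ambiguity codes return \code{NA}.
#'
#' @param pwm a [PWM-class] object.
#' @param window a DNA word of the motif length.
#' @return a score in [0, 1], or \code{NA} for an unscorable window.
#' @export
matrixSimilarity <- function(pwm, window)
    .scoreWord(pwm, window, seq_len(nrow(pwmFreq(pwm))))

#' Core similarity score (CSS)
#'
#' The same normalised similarity as [matrixSimilarity()] restricted to the
#' 5 core positions of the matrix.
#' @inheritParams matrixSimilarity
#' @return a score in [0, 1], or \code{NA}.
#' @export
coreSimilarity <- function(pwm, window)
    .scoreWord(pwm, window, coreStart(pwm) + 0:4)

#' Scan a promoter sequence with one PWM
#'
#' Scores every window on the forward strand and on the reverse complement
#' and reports windows passing both cutoffs. Minus-strand hits are reported
#' in forward coordinates (1-based, closed interval \code{[start, end]}).
#' Position 1 of a promoter is the upstream (-promoterLength) end; the last
#' position abuts the transcription start site.
#'
#' @param sequence a character string, \code{DNAString}, or a single-element
#'   \code{DNAStringSet}.
#' @param pwm a [PWM-class] object.
#' @param cutoffs a [CutoffProfile-class].
#' @param promoterId identifier recorded in the hit table.
#' @return data.frame with columns promoter_id, pwm_id, tf_name, start, end,
#'   strand, mss, css. Overlapping hits and both-strand hits at one position
#'   are distinct rows. A sequence shorter than the motif yields zero rows
#'   with a warning.
#' @export
scanSequence <- function(sequence, pwm, cutoffs, promoterId = "promoter") {
    if (is(sequence, "XStringSet")) {
        if (length(sequence) != 1L)
            stop("give a single sequence; use scanPromoters() for sets")
        promoterId <- names(sequence) %||% promoterId
        sequence <- sequence[[1L]]
    }
    seqchar <- as.character(sequence)
    f <- pwmFreq(pwm)
    L <- nrow(f)
    n <- nchar(seqchar)
    empty <- data.frame(promoter_id = character(), pwm_id = character(),
                        tf_name = character(), start = integer(),
                        end = integer(), strand = character(),
                        mss = numeric(), css = numeric(),
                        stringsAsFactors = FALSE)
    if (n < L) {
        warning("sequence '", promoterId, "' shorter than motif ",
                pwmId(pwm), "; no windows scored")
        return(empty)
    }
    .scanEncoded(encodeDNA(seqchar), encodeDNA(revcompString(seqchar)),
                 n, pwm, cutoffs, promoterId, empty)
}

# Workhorse shared by scanSequence()/scanPromoters(): takes the forward
# and reverse-complement integer encodings so promoters are encoded once
# per library scan, not once per matrix.
.scanEncoded <- function(sF, sR, n, pwm, cutoffs, promoterId, empty) {
    f <- pwmFreq(pwm)
    L <- nrow(f)
    info <- informationVector(f)
    corepos <- coreStart(pwm) + 0:4
    oneStrand <- function(s) {
        mss <- .scoreAllWindows(f, info, s, seq_len(L), L)
        css <- .scoreAllWindows(f, info, s, corepos, L)
        keep <- which(!is.na(mss) & !is.na(css) &
                      mss >= cutoffs@mssCut & css >= cutoffs@cssCut)
        list(start = keep, mss = mss[keep], css = css[keep])
    }
    fw <- oneStrand(sF)
    rv <- oneStrand(sR)
    # window j on the reverse complement covers forward [n-j-L+2, n-j+1]
    rvStart <- n - rv$start - L + 2L
    if (length(fw$start) + length(rvStart) == 0L) return(empty)
    out <- data.frame(
        promoter_id = promoterId,
        pwm_id = pwmId(pwm),
        tf_name = tfName(pwm),
        start = c(fw$start, rvStart),
        end = c(fw$start, rvStart) + L - 1L,
        strand = rep(c("+", "-"), c(length(fw$start), length(rvStart))),
        mss = c(fw$mss, rv$mss),
        css = c(fw$css, rv$css),
        stringsAsFactors = FALSE)
    if (nrow(out) == 0L) return(empty)
    out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan a set of promoters with a PWM library
#'
#' @param promoters a named \code{DNAStringSet} (or named character vector)
#'   of promoter sequences; names are gene ids.
#' @param pwms a [PWMList-class].
#' @param cutoffs a [CutoffProfile-class] applied to every matrix.
#' @return one hit table (see [scanSequence()]) over all promoters and
#'   matrices.
#' @export
scanPromoters <- function(promoters, pwms, cutoffs) {
    if (is.character(promoters))
        promoters <- Biostrings::DNAStringSet(promoters)
    ids <- names(promoters)
    if (is.null(ids) || anyDuplicated(ids))
        stop("promoters must have unique names")
    if (is(pwms, "PWM")) pwms <- PWMList(list(pwms))
    empty <- data.frame(promoter_id = character(), pwm_id = character(),
                        tf_name = character(), start = integer(),
                        end = integer(), strand = character(),
                        mss = numeric(), css = numeric(),
                        stringsAsFactors = FALSE)
    res <- vector("list", length(promoters) * length(pwms))
    k <- 0L
    for (i in seq_along(promoters)) {
        seqchar <- as.character(promoters[[i]])
        n <- nchar(seqchar)
        sF <- encodeDNA(seqchar)
        sR <- encodeDNA(revcompString(seqchar))
        for (p in pwms@.Data) {
            k <- k + 1L
            if (n < nrow(pwmFreq(p))) {
                warning("sequence '", ids[i], "' shorter than motif ",
                        pwmId(p), "; no windows scored")
                res[[k]] <- empty
            } else {
                res[[k]] <- .scanEncoded(sF, sR, n, p, cutoffs, ids[i],
                                         empty)
            }
        }
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Calibrate per-matrix score cutoffs
#'
#' Estimates the score distributions of background windows (i.i.d. sequence
#' of the given composition) and of true sites (words sampled from the PWM)
#' and derives the matrix-similarity cutoff under one of three profiles:
#' \describe{
#'   \item{minFP}{the empirical (1 - fpTarget) quantile of background
#'     window scores, so a fraction fpTarget of background windows pass.}
#'   \item{minFN}{the empirical fnTarget quantile of sampled-site scores,
#'     so a fraction fnTarget of true sites are missed.}
#'   \item{minSUM}{the cutoff minimising estimated FP + FN rates.}
#' }
#' The core-similarity cutoff is not calibrated; it is fixed at
#' \code{cssCut} (default 0.75) as a fast pre-filter.
#'
#' @param pwm a [PWM-class].
#' @param gc background GC fraction for the i.i.d. background model.
#' @param nWindows number of background windows scored; must be at least
#'   \code{1/fpTarget} so the requested quantile is estimable.
#' @param fpTarget,fnTarget target false-positive / false-negative rates in
#'   (0, 1).
#' @param nSiteSamples number of words sampled from the PWM for the FN side.
#' @param cssCut fixed core-similarity cutoff.
#' @param profile which cutoff rule to apply.
#' @param seed RNG seed for the background and site samples.
#' @return a [CutoffProfile-class]; calibration settings are stored in its
#'   metadata.
#' @export
calibrateCutoffs <- function(pwm, gc = 0.5, nWindows = 1e5,
                             fpTarget = 1e-3, fnTarget = 0.05,
                             nSiteSamples = 2000, cssCut = 0.75,
                             profile = c("minFP", "minFN", "minSUM"),
                             seed = NULL) {
    profile <- match.arg(profile)
    if (fpTarget <= 0 || fpTarget >= 1 || fnTarget < 0 || fnTarget >= 1)
        stop("fpTarget must be in (0,1) and fnTarget in [0,1)")
    if (nWindows < 1 / fpTarget)
        stop("nWindows too small for the requested fpTarget quantile: need ",
             "at least ", format(1 / fpTarget, digits = 3), " windows")
    f <- pwmFreq(pwm)
    L <- nrow(f)
    info <- informationVector(f)
    withSeed(seed, {
        bg <- encodeDNA(randomDNA(nWindows + L - 1L, gc = gc))
        bgScores <- .scoreAllWindows(f, info, bg, seq_len(L), L)
        siteScores <- NULL
        if (profile != "minFP") {
            words <- vapply(seq_len(L), function(i)
                sample.int(4L, nSiteSamples, replace = TRUE, prob = f[i, ]),
                integer(nSiteSamples))
            cur <- numeric(nSiteSamples)
            for (i in seq_len(L))
                cur <- cur + info[i] * f[i, ][words[, i]]
            mx <- sum(info * apply(f, 1L, max))
            mn <- sum(info * apply(f, 1L, min))
            siteScores <- if (mx - mn < 1e-12) rep(1, nSiteSamples)
                          else (cur - mn) / (mx - mn)
        }
        mssCut <- switch(profile,
            minFP = sort(bgScores, decreasing = TRUE)[
                        max(1L, ceiling(fpTarget * nWindows))],
            minFN = stats::quantile(siteScores, probs = fnTarget,
                                    type = 1, names = FALSE),
            minSUM = {
                cand <- sort(unique(c(bgScores, siteScores)))
                fp <- vapply(cand, function(cc) mean(bgScores >= cc),
                             numeric(1))
                fn <- vapply(cand, function(cc) mean(siteScores < cc),
                             numeric(1))
                cand[which.min(fp + fn)]
            })
        CutoffProfile(mssCut = mssCut, cssCut = cssCut, profileKind = profile,
                      metadata = list(gc = gc, nWindows = nWindows,
                                      fpTarget = fpTarget,
                                      fnTarget = fnTarget,
                                      nSiteSamples = nSiteSamples,
                                      seed = seed))
    })
}
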