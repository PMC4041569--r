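# Internal helpers shared across modules.

# Run code under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so generators never perturb the
# session RNG stream.
withSeed <- function(seed, code) {
    if (!is.null(seed)) {
        if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
            stop("'seed' must be a single integer")
        had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(code)
}

# ASCII lookup table: A/a -> 1, C/c -> 2, G/g -> 3, T/t -> 4, else NA.
.DNA_CODE <- local({
    v <- rep(NA_integer_, 128L)
    v[utf8ToInt("A")] <- 1L; v[utf8ToInt("a")] <- 1L
    v[utf8ToInt("C")] <- 2L; v[utf8ToInt("c")] <- 2L
    v[utf8ToInt("G")] <- 3L; v[utf8ToInt("g")] <- 3L
    v[utf8ToInt("T")] <- 4L; v[utf8ToInt("t")] <- 4L
    v
})

# Encode a DNA string as integers 1..4 (NA for ambiguity codes).
encodeDNA <- function(x) {
    x <- as.character(x)
    code <- utf8ToInt(x)
    code[code > 128L] <- 1L  # non-ASCII -> NA via table would fail; map safe
    out <- .DNA_CODE[code]
    out
}

decodeDNA <- function(v) paste(DNA_BASES[v], collapse = "")

revcompString <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# Sample an i.i.d. DNA string of length n with the given GC fraction.
randomDNA <- function(n, gc = 0.5) {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
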