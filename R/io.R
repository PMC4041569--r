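# Readers and writers for every on-disk format the pipeline touches.
# Every writer emits a '#'-prefixed metadata header (version, seed,
# parameters); readers skip those lines. Malformed records are rejected
# with the offending line number.

pkgVersion <- function()
    as.character(utils::packageVersion("androTF"))

.metaHeader <- function(meta = list()) {
    meta <- c(list(tool = paste0("androTF/", pkgVersion())), meta)
    vapply(names(meta), function(k)
        paste0("# ", k, ": ", paste(format(meta[[k]]), collapse = " ")),
        character(1), USE.NAMES = FALSE)
}

.writeTSV <- function(df, path, meta = list()) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.metaHeader(meta), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

# Strict TSV reader: returns the data.frame; coerces `numericCols` and
# reports the exact file line of the first bad cell.
.readTSV <- function(path, numericCols = character()) {
    lines <- readLines(path)
    body <- which(!startsWith(lines, "#") & nzchar(lines))
    if (length(body) < 1L)
        stop("no content in '", path, "'")
    header <- strsplit(lines[body[1L]], "\t", fixed = TRUE)[[1L]]
    rows <- body[-1L]
    cells <- strsplit(lines[rows], "\t", fixed = TRUE)
    bad <- which(lengths(cells) != length(header))
    if (length(bad))
        stop("malformed record in '", path, "' at line ", rows[bad[1L]],
             ": expected ", length(header), " fields, found ",
             lengths(cells)[bad[1L]])
    df <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
    if (nrow(df) == 0L)
        df <- as.data.frame(matrix(character(), 0L, length(header)),
                            stringsAsFactors = FALSE)
    names(df) <- header
    for (cc in intersect(numericCols, header)) {
        v <- suppressWarnings(as.numeric(df[[cc]]))
        bad <- which(is.na(v) & !df[[cc]] %in% c("NA", ""))
        if (length(bad))
            stop("non-numeric value '", df[[cc]][bad[1L]], "' in column '",
                 cc, "' of '", path, "' at line ", rows[bad[1L]])
        df[[cc]] <- v
    }
    df
}

#' Read / write an expression table
#'
#' Tab-separated with columns \code{gene_id}, \code{log2fc_<cond>},
#' \code{pval_<cond>} (and optionally \code{qval_<cond>}); '#' metadata
#' header lines are written/skipped. Malformed rows are rejected with
#' their line number.
#'
#' @param path file path.
#' @param table expression data.frame.
#' @param meta named list written into the metadata header.
#' @return the data.frame (readers) or the path, invisibly (writers).
#' @export
readExpressionTable <- function(path) {
    df <- .readTSV(path)
    num <- grep("^(log2fc|pval|qval)_", names(df), value = TRUE)
    df <- .readTSV(path, numericCols = num)
    .checkExpressionTable(df)
    df
}

#' @rdname readExpressionTable
#' @export
writeExpressionTable <- function(table, path, meta = list()) {
    .checkExpressionTable(table)
    .writeTSV(table, path, meta)
}

#' Read / write binding-hit tables
#'
#' TSV with columns promoter_id, pwm_id, tf_name, start, end, strand, mss,
#' css (BED6-convertible: promoter_id/start/end/pwm_id/mss/strand).
#' @param hits hit data.frame from [scanPromoters()].
#' @inheritParams readExpressionTable
#' @export
readHits <- function(path) {
    df <- .readTSV(path, numericCols = c("start", "end", "mss", "css"))
    need <- c("promoter_id", "pwm_id", "tf_name", "start", "end", "strand",
              "mss", "css")
    if (!all(need %in% names(df)))
        stop("hit table misses column(s): ",
             paste(setdiff(need, names(df)), collapse = ", "))
    df$start <- as.integer(df$start); df$end <- as.integer(df$end)
    df
}

#' @rdname readHits
#' @export
writeHits <- function(hits, path, meta = list()) .writeTSV(hits, path, meta)

#' Read / write a genes x tissues relative-expression matrix
#'
#' TSV, first column \code{gene_id}, remaining columns one per tissue.
#' @param m numeric matrix with gene rownames.
#' @inheritParams readExpressionTable
#' @export
readTissueMatrix <- function(path) {
    df <- .readTSV(path)
    df <- .readTSV(path, numericCols = setdiff(names(df), "gene_id"))
    if (anyDuplicated(df$gene_id)) stop("duplicate gene ids")
    m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
    rownames(m) <- df$gene_id
    m
}

#' @rdname readTissueMatrix
#' @export
writeTissueMatrix <- function(m, path, meta = list()) {
    df <- data.frame(gene_id = rownames(m), as.data.frame(m),
                     check.names = FALSE, stringsAsFactors = FALSE)
    .writeTSV(df, path, meta)
}

#' Read / write Ct tables
#' @param ct data.frame (gene, timepoint, replicate, ct).
#' @inheritParams readExpressionTable
#' @export
readCtTable <- function(path) {
    df <- .readTSV(path, numericCols = c("timepoint", "replicate", "ct"))
    if (!all(c("gene", "timepoint", "ct") %in% names(df)))
        stop("Ct table needs gene, timepoint, ct columns")
    df
}

#' @rdname readCtTable
#' @export
writeCtTable <- function(ct, path, meta = list()) .writeTSV(ct, path, meta)

#' Read a plain-text gene/factor list (one symbol per line)
#'
#' '#' comment lines and blank lines are skipped.
#' @param path file path.
#' @return character vector.
#' @export
readGeneList <- function(path) {
    x <- trimws(readLines(path))
    x[!startsWith(x, "#") & nzchar(x)]
}

#' @rdname readGeneList
#' @param x character vector of symbols.
#' @param meta metadata header entries.
#' @export
writeGeneList <- function(x, path, meta = list()) {
    writeLines(c(.metaHeader(meta), x), path)
    invisible(path)
}

#' Read promoter FASTA
#'
#' Line-based FASTA parser tolerant of CRLF line endings and arbitrary
#' wrapping; rejects duplicate record ids (with the offending line) and
#' records with empty sequences. The record id is the first whitespace-
#' delimited token of the header.
#'
#' @param path FASTA file path.
#' @return a named \code{DNAStringSet}.
#' @export
readPromoterFasta <- function(path) {
    lines <- sub("\r$", "", readLines(path))
    hdr <- which(startsWith(lines, ">"))
    if (length(hdr) == 0L)
        stop("no FASTA records in '", path, "'")
    ids <- vapply(strsplit(sub("^>", "", lines[hdr]), "\\s+"), `[`,
                  character(1), 1L)
    dup <- which(duplicated(ids))
    if (length(dup))
        stop("duplicated FASTA id '", ids[dup[1L]], "' at line ",
             hdr[dup[1L]])
    bounds <- c(hdr, length(lines) + 1L)
    seqs <- vapply(seq_along(hdr), function(i) {
        block <- lines[seq(hdr[i] + 1L, length.out =
                               bounds[i + 1L] - hdr[i] - 1L)]
        paste(block, collapse = "")
    }, character(1))
    if (any(!nzchar(seqs)))
        stop("empty sequence for record '", ids[!nzchar(seqs)][1L], "'")
    Biostrings::DNAStringSet(stats::setNames(seqs, ids))
}

#' @rdname readPromoterFasta
#' @param promoters named \code{DNAStringSet}.
#' @export
writePromoterFasta <- function(promoters, path) {
    Biostrings::writeXStringSet(promoters, path, width = 60L)
    invisible(path)
}

#' Read / write PWM libraries in TRANSFAC-dialect text
#'
#' Records are delimited by \code{//}; fields used are \code{ID} (matrix
#' id), \code{NA} (factor name), and a \code{P0}-headed block of numbered
#' rows with four values in A C G T order (an optional trailing consensus
#' letter is ignored). Rows may hold counts or frequencies; counts are
#' detected by row sums and normalised (with \code{pseudocount}).
#'
#' @param path file path.
#' @param pseudocount added per cell when normalising count matrices.
#' @return a [PWMList-class].
#' @export
readTransfac <- function(path, pseudocount = 0) {
    lines <- sub("\r$", "", readLines(path))
    pwms <- list()
    id <- NULL; nm <- NULL; rowsBuf <- list(); inMatrix <- FALSE
    flush <- function(lineNo) {
        if (is.null(id)) return()
        if (length(rowsBuf) == 0L)
            stop("matrix '", id, "' has no P0 rows (before line ", lineNo,
                 ")")
        f <- do.call(rbind, rowsBuf)
        pwms[[length(pwms) + 1L]] <<-
            PWM(id, f, tfName = nm %||% id, pseudocount = pseudocount)
        id <<- NULL; nm <<- NULL; rowsBuf <<- list(); inMatrix <<- FALSE
    }
    for (i in seq_along(lines)) {
        ln <- trimws(lines[i])
        if (!nzchar(ln) || startsWith(ln, "VV") || startsWith(ln, "XX"))
            next
        if (ln == "//") { flush(i); next }
        tag <- substr(ln, 1L, 2L)
        rest <- trimws(substr(ln, 3L, nchar(ln)))
        if (tag == "ID") { id <- rest; next }
        if (tag == "NA") { nm <- rest; next }
        if (tag == "P0" || tag == "PO") { inMatrix <- TRUE; next }
        if (inMatrix && grepl("^[0-9]", ln)) {
            parts <- strsplit(ln, "\\s+")[[1L]]
            vals <- suppressWarnings(as.numeric(parts[2:5]))
            if (length(parts) < 5L || anyNA(vals))
                stop("non-numeric matrix cells at line ", i, " of '", path,
                     "'")
            rowsBuf[[length(rowsBuf) + 1L]] <- vals
            next
        }
    }
    flush(length(lines) + 1L)
    PWMList(pwms)
}

#' @rdname readTransfac
#' @param pwms a [PWMList-class].
#' @param meta metadata header entries (written as \code{VV} lines).
#' @export
writeTransfac <- function(pwms, path, meta = list()) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("VV  ", sub("^# ", "", .metaHeader(meta))), con)
    writeLines("//", con)
    for (p in pwms@.Data) {
        f <- pwmFreq(p)
        writeLines(c(paste0("ID  ", pwmId(p)),
                     paste0("NA  ", tfName(p)),
                     paste0("P0  ", paste(sprintf("%12s", DNA_BASES),
                                          collapse = ""))), con)
        cons <- strsplit(consensusWord(p), "")[[1L]]
        for (i in seq_len(nrow(f)))
            writeLines(paste0(sprintf("%02d  ", i),
                              paste(sprintf("%12.10f", f[i, ]),
                                    collapse = " "),
                              "  ", cons[i]), con)
        writeLines(c("XX", "//"), con)
    }
    invisible(path)
}

#' Read / write a tree in Pajek-style .net format
#'
#' Dialect: a \code{*Vertices n} section with lines
#' \code{<index> "<gene>" <size>} (size = the SD vertex weight), then an
#' \code{*Edges} section with \code{<i> <j> <distance>} lines. Round-trips
#' an [MSTGraph-class] with identical topology and weights.
#'
#' @param tree an [MSTGraph-class].
#' @param path file path.
#' @return \code{readPajek}: an \code{MSTGraph}.
#' @export
writePajek <- function(tree, path) {
    v <- tree@vertices
    e <- tree@edges
    idx <- stats::setNames(seq_len(nrow(v)), v$gene)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("*Vertices %d", nrow(v)), con)
    writeLines(sprintf("%d \"%s\" %.15g", idx, v$gene,
                       ifelse(is.na(v$weight), 0, v$weight)), con)
    writeLines("*Edges", con)
    if (nrow(e))
        writeLines(sprintf("%d %d %.15g", idx[e$from], idx[e$to],
                           e$distance), con)
    invisible(path)
}

#' @rdname writePajek
#' @export
readPajek <- function(path) {
    lines <- sub("\r$", "", readLines(path))
    vLine <- grep("^\\*Vertices", lines, ignore.case = TRUE)
    eLine <- grep("^\\*Edges", lines, ignore.case = TRUE)
    if (length(vLine) != 1L || length(eLine) != 1L)
        stop("'", path, "' is not a recognised .net file")
    n <- as.integer(strsplit(lines[vLine], "\\s+")[[1L]][2L])
    vRows <- if (eLine - 1L >= vLine + 1L) lines[seq(vLine + 1L, eLine - 1L)]
             else character(0)
    vRows <- vRows[nzchar(vRows)]
    if (length(vRows) != n)
        stop("vertex count mismatch in '", path, "'")
    m <- regmatches(vRows, regexec("^(\\d+)\\s+\"([^\"]*)\"\\s*(\\S*)",
                                   vRows))
    genes <- vapply(m, `[`, character(1), 3L)
    sizes <- as.numeric(vapply(m, function(x)
        if (nzchar(x[4L])) x[4L] else "0", character(1)))
    eRows <- if (length(lines) >= eLine + 1L)
                 lines[seq(eLine + 1L, length(lines))] else character(0)
    eRows <- eRows[nzchar(eRows) & !startsWith(eRows, "%")]
    edges <- do.call(rbind, lapply(seq_along(eRows), function(k) {
        parts <- strsplit(trimws(eRows[k]), "\\s+")[[1L]]
        if (length(parts) < 3L)
            stop("malformed edge at line ", eLine + k, " of '", path, "'")
        i <- as.integer(parts[1L]); j <- as.integer(parts[2L])
        a <- genes[i]; b <- genes[j]
        data.frame(from = min(a, b), to = max(a, b),
                   distance = as.numeric(parts[3L]),
                   stringsAsFactors = FALSE)
    }))
    if (is.null(edges))
        edges <- data.frame(from = character(), to = character(),
                            distance = numeric(), stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
    new("MSTGraph",
        vertices = data.frame(gene = genes, weight = sizes,
                              stringsAsFactors = FALSE),
        edges = edges, totalWeight = sum(edges$distance), metadata = list())
}

#' Write the density comparison report
#'
#' TSV mirroring the two report sections: factors absent from the control
#' promoters first, then factors shared with the controls, each section
#' sorted by decreasing regulated density. Factors below the report floor
#' are omitted (they remain in the in-memory comparison).
#'
#' @param comparison output of [compareToControls()].
#' @inheritParams readExpressionTable
#' @export
writeDensityReport <- function(comparison, path, meta = list()) {
    rep_ <- comparison[comparison$reported, , drop = FALSE]
    secA <- rep_[rep_$klass == "absent_in_controls", , drop = FALSE]
    secB <- rep_[rep_$klass != "absent_in_controls", , drop = FALSE]
    out <- rbind(secA[order(-secA$density_reg, secA$tf_name), ],
                 secB[order(-secB$density_reg, secB$tf_name), ])
    .writeTSV(out, path, meta)
}

#' Read / write planted ground truth as JSON
#'
#' Serialises every slot of a [PlantedTruth-class] so a synthetic run's
#' ground truth travels with its data files.
#'
#' @param truth a [PlantedTruth-class].
#' @param path JSON file path.
#' @return \code{readPlantedTruth}: the reconstructed object.
#' @export
writePlantedTruth <- function(truth, path) {
    jsonlite::write_json(
        list(tool = paste0("androTF/", pkgVersion()),
             deLabels = lapply(truth@deLabels, as.list),
             plantedSites = truth@plantedSites,
             enrichedTFs = truth@enrichedTFs,
             correlationBlocks = truth@correlationBlocks,
             trueFoldChanges = truth@trueFoldChanges),
        path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' @rdname writePlantedTruth
#' @export
readPlantedTruth <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    sites <- as.data.frame(x$plantedSites, stringsAsFactors = FALSE)
    if (nrow(sites)) sites$start <- as.integer(sites$start)
    folds <- as.data.frame(x$trueFoldChanges, stringsAsFactors = FALSE)
    PlantedTruth(
        deLabels = lapply(x$deLabels, function(v) {
            u <- unlist(v)
            stats::setNames(as.numeric(u), names(u))
        }),
        plantedSites = if (nrow(sites)) sites else
            data.frame(promoter_id = character(), pwm_id = character(),
                       start = integer(), strand = character(),
                       stringsAsFactors = FALSE),
        enrichedTFs = as.character(unlist(x$enrichedTFs)),
        correlationBlocks = lapply(x$correlationBlocks, unlist),
        trueFoldChanges = if (nrow(folds)) folds else
            data.frame(gene = character(), timepoint = numeric(),
                       fold = numeric(), stringsAsFactors = FALSE))
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [pipelineConfig()]
#' defaults.
#' @param path YAML file path.
#' @return a config list (see [pipelineConfig()]).
#' @export
readConfig <- function(path) {
    y <- yaml::read_yaml(path)
    do.call(pipelineConfig, y)
}
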