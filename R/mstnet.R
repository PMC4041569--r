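#' Gene-gene correlation matrix across tissues
#'
#' Pearson (default) or Spearman correlation of the rows of a genes x
#' tissues relative-expression matrix.
#'
#' @param m numeric matrix, genes in rows (rownames required), tissues in
#'   columns; at least 3 tissues and no missing values.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlationMatrix <- function(m, method = c("pearson", "spearman")) {
    method <- match.arg(method)
    m <- as.matrix(m)
    if (is.null(rownames(m)))
        stop("the tissue matrix needs gene rownames")
    if (ncol(m) < 3L)
        stop("need at least 3 tissues")
    if (anyNA(m))
        stop("missing values in the tissue matrix")
    v <- apply(m, 1L, stats::var)
    if (any(v == 0))
        stop("zero-variance expression row(s): ",
             paste(rownames(m)[v == 0], collapse = ", "))
    r <- stats::cor(t(m), method = method)
    diag(r) <- 1
    r
}

#' Transform correlations into distances
#'
#' Default \code{d = sqrt(2 (1 - r))}, the standard correlation metric
#' (satisfies the metric axioms for the Pearson case); alternatively the
#' simpler \code{1 - r}. The choice is recorded in the MST metadata so
#' downstream output states which transform produced the edge lengths.
#'
#' @param r correlation matrix with values in [-1, 1].
#' @param method \code{"sqrt2"} (default) or \code{"oneMinus"}.
#' @return distance matrix with zero diagonal, carrying the transform name
#'   as attribute \code{"distance"}.
#' @export
toDistance <- function(r, method = c("sqrt2", "oneMinus")) {
    method <- match.arg(method)
    r <- as.matrix(r)
    if (any(abs(r) > 1 + 1e-9))
        stop("correlations outside [-1, 1]")
    r[r > 1] <- 1; r[r < -1] <- -1
    d <- switch(method, sqrt2 = sqrt(2 * (1 - r)), oneMinus = 1 - r)
    diag(d) <- 0
    attr(d, "distance") <- method
    d
}

#' Minimum spanning tree of a distance matrix
#'
#' Kruskal's algorithm with deterministic tie-breaking: candidate edges are
#' ordered by (distance, gene_i, gene_j) with gene labels compared
#' lexicographically, so equal-length edges always enter in the same order
#' regardless of input row order.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal and
#'   gene ids as dimnames.
#' @param vertexWeights optional named numeric vector of vertex weights
#'   (typically [vertexSD()] values).
#' @param metadata list stored on the result; the distance transform
#'   attribute of [toDistance()] output is picked up automatically.
#' @return an [MSTGraph-class].
#' @export
buildMST <- function(d, vertexWeights = NULL, metadata = list()) {
    d <- as.matrix(d)
    n <- nrow(d)
    if (n < 2L) stop("need at least 2 vertices")
    if (is.null(rownames(d)))
        stop("the distance matrix needs gene dimnames")
    if (any(abs(d - t(d)) > 1e-9))
        stop("distance matrix must be symmetric")
    if (any(d < 0)) stop("distances must be non-negative")
    if (any(diag(d) != 0)) stop("diagonal must be zero")
    if (is.null(metadata$distance) && !is.null(attr(d, "distance")))
        metadata$distance <- attr(d, "distance")
    labels <- rownames(d)
    ij <- which(upper.tri(d), arr.ind = TRUE)
    # orient each edge so from < to lexicographically
    a <- labels[ij[, 1L]]; b <- labels[ij[, 2L]]
    from <- ifelse(a <= b, a, b); to <- ifelse(a <= b, b, a)
    w <- d[ij]
    ord <- order(w, from, to)
    from <- from[ord]; to <- to[ord]; w <- w[ord]
    parent <- stats::setNames(seq_len(n), labels)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    keep <- logical(length(w))
    taken <- 0L
    for (e in seq_along(w)) {
        ra <- find(which(labels == from[e])); rb <- find(which(labels == to[e]))
        if (ra != rb) {
            parent[rb] <- ra
            keep[e] <- TRUE
            taken <- taken + 1L
            if (taken == n - 1L) break
        }
    }
    if (taken != n - 1L)
        stop("distance matrix does not yield a connected tree")
    vw <- rep(NA_real_, n)
    if (!is.null(vertexWeights)) {
        if (is.null(names(vertexWeights)) ||
            !all(labels %in% names(vertexWeights)))
            stop("'vertexWeights' must be named for every vertex")
        vw <- as.numeric(vertexWeights[labels])
    }
    edges <- data.frame(from = from[keep], to = to[keep],
                        distance = w[keep], stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
    new("MSTGraph",
        vertices = data.frame(gene = labels, weight = vw,
                              stringsAsFactors = FALSE),
        edges = edges, totalWeight = sum(w[keep]), metadata = metadata)
}

#' Per-gene standard deviation across tissues
#'
#' Sample standard deviation (n - 1 denominator) of each gene's relative
#' expression row; used as the vertex weight in the MST display.
#'
#' @param m genes x tissues matrix with gene rownames.
#' @return named numeric vector of SDs.
#' @export
vertexSD <- function(m) {
    m <- as.matrix(m)
    apply(m, 1L, stats::sd)
}

#' Rank tree vertices by centrality
#'
#' Degree centrality by default (the hub report of the tree); betweenness
#' centrality (shortest-path count through each vertex, unweighted paths)
#' is available by flag. Ties are broken by gene id.
#'
#' @param tree an [MSTGraph-class].
#' @param measure \code{"degree"} (default) or \code{"betweenness"}.
#' @return data.frame (gene, degree, score, rank, hub) ordered by rank; the
#'   top vertex is flagged as the hub.
#' @export
mstCentrality <- function(tree, measure = c("degree", "betweenness")) {
    measure <- match.arg(measure)
    v <- tree@vertices$gene
    e <- tree@edges
    deg <- table(factor(c(e$from, e$to), levels = v))
    score <- as.numeric(deg)
    if (measure == "betweenness") {
        # exact betweenness in a tree: for each edge removal, the vertex
        # lies on paths between the two sides it connects
        adj <- stats::setNames(vector("list", length(v)), v)
        for (i in seq_len(nrow(e))) {
            adj[[e$from[i]]] <- c(adj[[e$from[i]]], e$to[i])
            adj[[e$to[i]]] <- c(adj[[e$to[i]]], e$from[i])
        }
        subtreeSize <- function(root, blocked) {
            size <- 0L; stack <- root; seen <- blocked
            while (length(stack)) {
                x <- stack[[1L]]; stack <- stack[-1L]
                if (x %in% seen) next
                seen <- c(seen, x); size <- size + 1L
                stack <- c(stack, adj[[x]])
            }
            size
        }
        n <- length(v)
        score <- vapply(v, function(g) {
            nb <- adj[[g]]
            if (length(nb) < 2L) return(0)
            sizes <- vapply(nb, function(x) subtreeSize(x, g), integer(1))
            (sum(sizes)^2 - sum(sizes^2)) / 2
        }, numeric(1))
    }
    ord <- order(-score, v)
    out <- data.frame(gene = v[ord], degree = as.integer(deg)[ord],
                      score = score[ord], rank = seq_along(v),
                      stringsAsFactors = FALSE)
    out$hub <- out$rank == 1L
    rownames(out) <- NULL
    out
}
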