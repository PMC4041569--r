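#' Delta-delta-Ct relative fold changes
#'
#' Livak quantification: replicate Ct values are averaged on the Ct scale
#' per (gene, timepoint); \eqn{\Delta Ct = Ct_{gene} - Ct_{reference}} per
#' timepoint; \eqn{\Delta\Delta Ct = \Delta Ct(t) - \Delta Ct(calibrator)};
#' fold change \eqn{= 2^{-\Delta\Delta Ct}}. Replicate SDs are propagated
#' in quadrature onto the \eqn{\Delta\Delta Ct} (log2) scale and reported
#' alongside fold-change bounds.
#'
#' @param ct data.frame with columns gene, timepoint, replicate, ct.
#' @param referenceGene housekeeping gene; must be present at every
#'   timepoint where any target is measured.
#' @param calibratorTimepoint the timepoint folds are referenced to
#'   (default 0).
#' @return data.frame (gene, timepoint, fold, sd_log2, fold_lo, fold_hi);
#'   the reference gene's own fold is exactly 1 at every timepoint.
#' @examples
#' ct <- data.frame(gene = rep(c("T", "G"), each = 4),
#'                  timepoint = rep(c(0, 0, 3, 3), 2), replicate = 1,
#'                  ct = c(24, 24, 25, 25, 20, 20, 20, 20))
#' ddctFoldChange(ct, "G")  # target fold at day 3 is 0.5
#' @export
ddctFoldChange <- function(ct, referenceGene, calibratorTimepoint = 0) {
    need <- c("gene", "timepoint", "ct")
    if (!all(need %in% names(ct)))
        stop("Ct table needs columns: ", paste(need, collapse = ", "))
    if (any(ct$ct <= 0)) stop("Ct values must be positive")
    if (!referenceGene %in% ct$gene)
        stop("reference gene '", referenceGene, "' missing from the table")
    agg <- function(f) tapply(ct$ct, list(ct$gene, ct$timepoint), f)
    mu <- agg(mean)
    sd0 <- agg(function(x) if (length(x) > 1L) stats::sd(x) else 0)
    tps <- as.numeric(colnames(mu))
    if (!as.character(calibratorTimepoint) %in% colnames(mu))
        stop("calibrator timepoint ", calibratorTimepoint, " not measured")
    if (anyNA(mu[referenceGene, ]))
        stop("reference gene missing at timepoint(s): ",
             paste(tps[is.na(mu[referenceGene, ])], collapse = ", "))
    genes <- rownames(mu)
    cal <- as.character(calibratorTimepoint)
    out <- do.call(rbind, lapply(genes, function(g) {
        ok <- !is.na(mu[g, ])
        dct <- mu[g, ok] - mu[referenceGene, ok]
        sdd <- sqrt(sd0[g, ok]^2 + sd0[referenceGene, ok]^2)
        if (is.na(mu[g, cal]))
            stop("gene '", g, "' not measured at the calibrator timepoint")
        ddct <- dct - dct[cal]
        data.frame(gene = g, timepoint = tps[ok],
                   fold = 2^(-ddct), sd_log2 = sdd,
                   fold_lo = 2^(-(ddct + sdd)), fold_hi = 2^(-(ddct - sdd)),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Fourth-order polynomial trend curve
#'
#' Ordinary least-squares fit of a degree-4 polynomial to fold-change
#' kinetics, the trend-line representation used to compare expression
#' time courses.
#'
#' @param timepoints numeric x values; at least 5 distinct values are
#'   required (the fit is underdetermined otherwise).
#' @param folds numeric response of the same length.
#' @return list with \code{coefficients} (c0..c4), \code{fitted} values,
#'   \code{rss} (residual sum of squares) and the underlying \code{lm}
#'   fit.
#' @export
quarticTrend <- function(timepoints, folds) {
    if (length(timepoints) != length(folds))
        stop("'timepoints' and 'folds' must have equal length")
    if (length(unique(timepoints)) < 5L)
        stop("need at least 5 distinct timepoints for a quartic fit")
    fit <- stats::lm(folds ~ timepoints + I(timepoints^2) +
                         I(timepoints^3) + I(timepoints^4))
    coefs <- stats::setNames(as.numeric(stats::coef(fit)),
                             paste0("c", 0:4))
    list(coefficients = coefs,
         fitted = as.numeric(stats::fitted(fit)),
         rss = sum(stats::residuals(fit)^2),
         model = fit)
}
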