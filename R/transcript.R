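#' @importFrom stats p.adjust pf ptukey
#' @importFrom SummarizedExperiment assay colData
NULL

.countsMatrix <- function(counts) {
    if (is(counts, "SummarizedExperiment")) counts <- assay(counts)
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
    counts
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors computed as the median, over genes with
#' non-zero counts in every sample, of the ratio of the gene's count to its
#' across-sample geometric mean; factors are rescaled to have geometric mean
#' one. This is the classic count-normalisation used for RNA-seq depth
#' correction.
#'
#' @param counts Non-negative integer matrix (genes x samples) or a
#'   [SummarizedExperiment::SummarizedExperiment].
#'
#' @return Named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- cbind(s1 = c(100, 10, 4), s2 = c(200, 20, 8))
#' sizeFactorsMedianRatio(m)  # proportional to 1:2
#' @export
sizeFactorsMedianRatio <- function(counts) {
    counts <- .countsMatrix(counts)
    eligible <- rowSums(counts > 0) == ncol(counts)
    if (!any(eligible))
        stop("no gene has non-zero counts in every sample; ",
             "size factors undefined", call. = FALSE)
    logc <- log(counts[eligible, , drop = FALSE])
    logGeo <- rowMeans(logc)
    sf <- exp(apply(logc - logGeo, 2L, median))
    sf <- sf / exp(mean(log(sf)))
    if (is.null(names(sf)))
        names(sf) <- colnames(counts)
    sf
}

#' Normalize counts by size factors
#'
#' @param counts Counts matrix (genes x samples) or SummarizedExperiment.
#' @param sizeFactors Per-sample factors from [sizeFactorsMedianRatio()]
#'   (default: computed from `counts`).
#' @return Matrix of normalized expression values.
#' @export
normalizeCounts <- function(counts, sizeFactors = sizeFactorsMedianRatio(counts)) {
    counts <- .countsMatrix(counts)
    sweep(counts, 2L, sizeFactors, "/")
}

#' Expression floor filter
#'
#' Retains only genes whose normalized expression is at or above `floor` in
#' every sample of every line (inclusive), removing genes too weakly
#' expressed for a meaningful differential test.
#'
#' @param norm Normalized expression matrix (genes x samples).
#' @param floor Minimum normalized level (default 0.5, roughly 0.05 RPKM at
#'   typical library sizes).
#'
#' @return Character vector of retained gene ids.
#' @export
filterExpressed <- function(norm, floor = 0.5) {
    norm <- .countsMatrix(norm)
    rownames(norm)[rowSums(norm >= floor) == ncol(norm)]
}

.geneMatrix <- function(x, cols) {
    if (is.null(dim(x)))
        x <- matrix(x, nrow = 1L, dimnames = list(NULL, cols))
    x
}

# Vectorised one-way ANOVA + Tukey HSD over all genes at once.
# Y: log2 matrix genes x samples; groups: factor over columns.
.anovaTukey <- function(Y, groups, focal, comparators) {
    lev <- levels(groups)
    k <- length(lev)
    ni <- table(groups)
    n <- ncol(Y)
    gm <- .geneMatrix(vapply(lev, function(g)
        rowMeans(Y[, groups == g, drop = FALSE]), numeric(nrow(Y))), lev)
    grand <- rowMeans(Y)
    ssb <- as.vector(gm^2 %*% as.numeric(ni)) - n * grand^2
    ssw <- rowSums(Y^2) - as.vector(gm^2 %*% as.numeric(ni))
    ssw <- pmax(ssw, 0); ssb <- pmax(ssb, 0)
    dfb <- k - 1L
    dfw <- n - k
    mse <- ssw / dfw
    f <- (ssb / dfb) / mse
    pAnova <- pf(f, dfb, dfw, lower.tail = FALSE)
    tukeyP <- function(cmp) {
        d <- abs(gm[, focal] - gm[, cmp])
        se <- sqrt(mse / 2 * (1 / ni[[focal]] + 1 / ni[[cmp]]))
        q <- d / se
        p <- ptukey(q, nmeans = k, df = dfw, lower.tail = FALSE)
        # degenerate genes: no within-group variance
        zero <- mse == 0
        p[zero & d == 0] <- 1
        p[zero & d > 0] <- .Machine$double.xmin
        p
    }
    pAnova[mse == 0 & ssb == 0] <- 1
    pAnova[mse == 0 & ssb > 0] <- .Machine$double.xmin
    list(pAnova = pAnova, mse = mse,
         pTukey = .geneMatrix(vapply(comparators, tukeyP, numeric(nrow(Y))),
                              comparators),
         groupMeansLog = gm)
}

#' Differential-expression candidate filter against two comparator lines
#'
#' Implements the resistance-candidate selection: for each gene a one-way
#' ANOVA across the three lines on `log2(normalized + 1)` values, Tukey HSD
#' post hoc p-values for the focal line versus each comparator,
#' Benjamini-Hochberg correction across genes (by default applied separately
#' within each pairwise comparison), and fold changes computed on the linear
#' normalized group means. A gene is a candidate when its fold change is at
#' least `fcMin` (in the same direction) versus \emph{both} comparators and
#' both corrected p-values are at or below `alpha`.
#'
#' With `correction = "anova-bh"` the BH correction is instead applied to the
#' ANOVA p-values across genes and the Tukey p-values are used uncorrected;
#' the reported `p_adj` columns then carry the maximum of the adjusted ANOVA
#' p and the raw Tukey p for each comparison.
#'
#' @param norm Normalized expression matrix (genes x samples), e.g. from
#'   [normalizeCounts()] restricted to [filterExpressed()] genes.
#' @param groups Factor or character vector assigning each column to a line.
#' @param focal Name of the focal (resistant) line.
#' @param comparators Character vector of the two comparator (susceptible)
#'   lines.
#' @param fcMin Fold-change threshold on the linear scale (default 3;
#'   inclusive, either direction).
#' @param alpha Corrected p-value threshold (default 0.001; inclusive).
#' @param correction `"tukey-bh"` (default) or `"anova-bh"`, see Details.
#'
#' @return Data frame with one row per gene: group mean columns
#'   (`mean_<group>`), `fc_vs_c1`, `fc_vs_c2`, `p_adj_c1`, `p_adj_c2`,
#'   `p_anova`, `direction` (over/under/none), `candidate`, `flag`.
#' @export
deCandidates <- function(norm, groups, focal, comparators,
                         fcMin = 3, alpha = 0.001,
                         correction = c("tukey-bh", "anova-bh")) {
    correction <- match.arg(correction)
    norm <- .countsMatrix(norm)
    groups <- as.factor(as.character(groups))
    if (length(comparators) != 2L)
        stop("exactly two comparator lines are required", call. = FALSE)
    lev <- c(focal, comparators)
    if (!all(lev %in% levels(groups)))
        stop("focal/comparator lines not all present in 'groups'", call. = FALSE)
    keep <- groups %in% lev
    norm <- norm[, keep, drop = FALSE]
    groups <- factor(as.character(groups[keep]), levels = lev)
    if (any(table(groups) < 2L))
        stop("each line needs at least 2 replicates", call. = FALSE)

    Y <- log2(norm + 1)
    at <- .anovaTukey(Y, groups, focal, comparators)

    linMeans <- .geneMatrix(vapply(lev, function(g)
        rowMeans(norm[, groups == g, drop = FALSE]), numeric(nrow(norm))), lev)
    fc <- .geneMatrix(vapply(comparators, function(cmp) {
        num <- linMeans[, focal]; den <- linMeans[, cmp]
        ifelse(den > 0, num / den, ifelse(num > 0, Inf, NA_real_))
    }, numeric(nrow(norm))), comparators)

    if (correction == "tukey-bh") {
        pAdj <- .geneMatrix(apply(at$pTukey, 2L, p.adjust, method = "BH"),
                            comparators)
    } else {
        adjA <- p.adjust(at$pAnova, method = "BH")
        pAdj <- .geneMatrix(vapply(seq_len(ncol(at$pTukey)), function(j)
            pmax(adjA, at$pTukey[, j]), numeric(nrow(norm))), comparators)
    }

    over <- fc[, 1L] >= fcMin & fc[, 2L] >= fcMin
    under <- fc[, 1L] <= 1 / fcMin & fc[, 2L] <= 1 / fcMin
    direction <- ifelse(is.na(over) | is.na(under), "none",
                        ifelse(over, "over", ifelse(under, "under", "none")))
    candidate <- direction != "none" &
        pAdj[, 1L] <= alpha & pAdj[, 2L] <= alpha
    candidate[is.na(candidate)] <- FALSE

    res <- data.frame(gene_id = rownames(norm), row.names = NULL)
    for (g in lev) res[[paste0("mean_", g)]] <- linMeans[, g]
    res$fc_vs_c1 <- fc[, 1L]
    res$fc_vs_c2 <- fc[, 2L]
    res$p_adj_c1 <- pAdj[, 1L]
    res$p_adj_c2 <- pAdj[, 2L]
    res$p_anova <- at$pAnova
    res$direction <- direction
    res$candidate <- candidate
    res$flag <- ifelse(at$mse == 0 & res$p_anova < 1, "exact-separation",
                       NA_character_)
    res
}
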