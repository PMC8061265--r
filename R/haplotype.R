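#' @importFrom stats aggregate
NULL

.classifyOne <- function(folds, threshold) {
    genes <- cceClusterGenes()
    present <- genes[genes %in% names(folds) & !is.na(folds[genes])]
    if (length(present) == 0L)
        stop("no cluster-gene folds available for classification", call. = FALSE)
    hi <- folds[present] >= threshold
    positive <- any(hi)
    partial <- length(present) < 3L
    haplotype <- if (!positive) {
        "negative"
    } else if (partial) {
        "other"
    } else if (all(folds[genes[1:3]] >= threshold)) {
        "A"
    } else if (folds[genes[1L]] >= threshold && folds[genes[2L]] >= threshold &&
               folds[genes[3L]] < threshold) {
        "B"
    } else {
        "other"
    }
    list(positive = positive, haplotype = haplotype,
         flag = if (partial) "partial-profile" else NA_character_)
}

#' Positivity and structural-haplotype calls from per-gene copy numbers
#'
#' An individual is positive for the amplification when any of the three
#' assayed cluster genes shows a copy number at or above `threshold` relative
#' to the susceptible calibrator line (default 2.5-fold, chosen above the
#' <2-fold technical variation of single-mosquito qPCR). Positive
#' individuals are assigned a structural haplotype: \strong{A} if all three
#' cluster genes are amplified, \strong{B} if AAEL019678 and AAEL023844 are
#' amplified but AAEL005113 (CCEAE1A) is not, and \strong{other} for any
#' remaining positive pattern (e.g. AAEL023844 alone, compatible with further
#' structural haplotypes). Individuals with a partial profile (a missing
#' cluster gene) are still called positive/negative from the genes present,
#' but their haplotype is reported as "other" with a `"partial-profile"` flag.
#'
#' @param profiles Data frame with one row per individual: columns
#'   `individual_id`, optionally `population_id`, and one numeric fold column
#'   per cluster gene (named by gene id; see [cceClusterGenes()]). Use
#'   [pivotProfiles()] to build it from a long quantification table.
#' @param threshold Positivity threshold on the fold scale (inclusive;
#'   default 2.5, must exceed 1).
#'
#' @return The input data frame with added columns `positive` (logical),
#'   `haplotype` (factor A/B/other/negative) and `flag`.
#' @examples
#' p <- data.frame(individual_id = c("m1", "m2"),
#'                 AAEL019678 = c(30, 1), AAEL023844 = c(32, 1.2),
#'                 AAEL005113 = c(1, 0.9))
#' classifyHaplotypes(p)
#' @export
classifyHaplotypes <- function(profiles, threshold = 2.5) {
    stopifnot(is.data.frame(profiles), "individual_id" %in% names(profiles))
    if (threshold <= 1)
        stop("positivity threshold must exceed 1", call. = FALSE)
    genes <- intersect(cceClusterGenes(), names(profiles))
    if (length(genes) == 0L)
        stop("no cluster-gene fold columns found (expected any of ",
             paste(cceClusterGenes(), collapse = ", "), ")", call. = FALSE)
    if (any(unlist(profiles[genes]) < 0, na.rm = TRUE))
        stop("folds must be >= 0", call. = FALSE)
    calls <- lapply(seq_len(nrow(profiles)), function(i) {
        folds <- unlist(profiles[i, genes, drop = FALSE])
        .classifyOne(folds, threshold)
    })
    profiles$positive <- vapply(calls, `[[`, TRUE, "positive")
    profiles$haplotype <- factor(vapply(calls, `[[`, "", "haplotype"),
                                 levels = c("A", "B", "other", "negative"))
    profiles$flag <- vapply(calls, `[[`, "", "flag")
    profiles
}

#' Pivot a long quantification table to per-individual profiles
#'
#' Reshapes the output of [quantifyCnv()] (or the ddPCR fold table) from long
#' (`sample_id`, `gene_id`, `fold`) to one row per individual with one fold
#' column per gene, optionally joining a population map.
#'
#' @param quant Data frame with columns `sample_id`, `gene_id`, `fold`.
#' @param populationMap Optional data frame with columns `individual_id`,
#'   `population_id`.
#'
#' @return Wide data frame suitable for [classifyHaplotypes()].
#' @export
pivotProfiles <- function(quant, populationMap = NULL) {
    stopifnot(all(c("sample_id", "gene_id", "fold") %in% names(quant)))
    wide <- reshape(quant[c("sample_id", "gene_id", "fold")],
                    idvar = "sample_id", timevar = "gene_id",
                    direction = "wide")
    names(wide) <- sub("^fold\\.", "", names(wide))
    names(wide)[1L] <- "individual_id"
    rownames(wide) <- NULL
    if (!is.null(populationMap)) {
        stopifnot(all(c("individual_id", "population_id") %in% names(populationMap)))
        wide <- merge(populationMap, wide, by = "individual_id", sort = FALSE)
    }
    wide
}

#' Population-level prevalence and haplotype-frequency summaries
#'
#' Summarises haplotype calls per population: the number genotyped, the
#' number and percentage positive (prevalence), the frequency of each
#' haplotype as a percentage of all individuals, the share of haplotypes A
#' and B among positive individuals, and the mean fold of each cluster gene
#' over positive individuals only. Haplotype percentages over all individuals
#' sum to the prevalence.
#'
#' @param calls Data frame from [classifyHaplotypes()]; a `population_id`
#'   column groups individuals (absent = one population `"all"`).
#'
#' @return Data frame with one row per population: `population_id`, `n`,
#'   `n_positive`, `prevalence`, `freq_A`, `freq_B`, `freq_other` (percent of
#'   all individuals), `share_A_among_positive`, `share_B_among_positive`
#'   (percent of positives, `NA` when none), and `mean_fold_<gene>` columns.
#' @examples
#' p <- data.frame(individual_id = paste0("m", 1:4),
#'                 AAEL019678 = c(30, 5, 1, 1), AAEL023844 = c(32, 5, 1, 1),
#'                 AAEL005113 = c(1, 5, 1, 1))
#' summarizePopulations(classifyHaplotypes(p))
#' @export
summarizePopulations <- function(calls) {
    stopifnot(is.data.frame(calls),
              all(c("positive", "haplotype") %in% names(calls)))
    if (nrow(calls) == 0L)
        stop("empty population: no haplotype calls to summarise", call. = FALSE)
    if (!"population_id" %in% names(calls))
        calls$population_id <- "all"
    genes <- intersect(cceClusterGenes(), names(calls))
    res <- lapply(split(calls, calls$population_id), function(d) {
        n <- nrow(d)
        nPos <- sum(d$positive)
        nHap <- table(d$haplotype)
        row <- data.frame(
            population_id = d$population_id[1L],
            n = n,
            n_positive = nPos,
            prevalence = 100 * nPos / n,
            freq_A = 100 * nHap[["A"]] / n,
            freq_B = 100 * nHap[["B"]] / n,
            freq_other = 100 * nHap[["other"]] / n,
            share_A_among_positive = if (nPos) 100 * nHap[["A"]] / nPos else NA_real_,
            share_B_among_positive = if (nPos) 100 * nHap[["B"]] / nPos else NA_real_)
        for (g in genes)
            row[[paste0("mean_fold_", g)]] <-
                if (nPos) mean(d[[g]][d$positive], na.rm = TRUE) else NA_real_
        row
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out[order(out$population_id), , drop = FALSE]
}
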