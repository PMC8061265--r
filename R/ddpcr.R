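#' @importFrom stats qnorm cor.test
NULL

.dropletCounts <- function(x, what = "droplet count") {
    if (is.data.frame(x)) x <- as.list(x[1L, , drop = FALSE])
    if (is.list(x)) {
        names(x) <- sub("^n_", "n", names(x))
        pos <- x[["nPositive"]]; neg <- x[["nNegative"]]
    } else if (is.numeric(x) && length(x) == 2L) {
        pos <- x[[1L]]; neg <- x[[2L]]
    } else {
        stop("cannot interpret ", what,
             ": expected list(nPositive=, nNegative=) or length-2 numeric",
             call. = FALSE)
    }
    if (is.null(pos) || is.null(neg) || any(pos < 0) || any(neg < 0) ||
        pos != round(pos) || neg != round(neg))
        stop(what, ": positive and negative counts must be non-negative integers",
             call. = FALSE)
    c(pos = as.numeric(pos), neg = as.numeric(neg))
}

#' Estimate mean copies per droplet from ddPCR partition counts
#'
#' Under random partitioning of template into droplets, the number of copies
#' per droplet is Poisson and the negative fraction estimates the zero class:
#' `lambda = -ln(nNegative / (nPositive + nNegative))`. The confidence
#' interval is a Wilson score interval on the negative fraction transformed
#' through `-ln` (endpoints swap because the transform is decreasing).
#'
#' @param nPositive,nNegative Droplet counts (integers; total > 0,
#'   `nNegative >= 1` since a fully saturated well cannot be quantified).
#' @param conf Confidence level (default 0.95).
#'
#' @return A [PoissonEstimate-class] object.
#' @examples
#' estimateLambda(12642, 7358)  # lambda ~ 1.0 copies/droplet
#' @export
estimateLambda <- function(nPositive, nNegative, conf = 0.95) {
    cnt <- .dropletCounts(list(nPositive = nPositive, nNegative = nNegative))
    n <- cnt["pos"] + cnt["neg"]
    if (n == 0)
        stop("empty well: no droplets counted", call. = FALSE)
    if (cnt["neg"] == 0)
        stop("saturated well: no negative droplets, ",
             "sample too concentrated to quantify", call. = FALSE)
    f <- cnt["neg"] / n
    lambda <- -log(f)
    z <- qnorm(1 - (1 - conf) / 2)
    centre <- (f + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(f * (1 - f) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    fLow <- max(centre - half, .Machine$double.xmin)
    fHigh <- min(centre + half, 1)
    new("PoissonEstimate", lambda = unname(lambda),
        ciLow = unname(-log(fHigh)), ciHigh = unname(-log(fLow)),
        nDroplets = as.integer(n))
}

#' Relative copy number from four ddPCR wells
#'
#' Estimates the fold change of a target gene versus a single-copy control
#' gene in a sample relative to the calibrator:
#' `fold = (lambda_target / lambda_control)_sample /
#' (lambda_target / lambda_control)_calibrator`. Normalising by the control
#' gene cancels differences in loaded gDNA quantity.
#'
#' @param sampleTarget,sampleControl,calibratorTarget,calibratorControl
#'   Droplet counts for each well, each a `list(nPositive=, nNegative=)`
#'   (or length-2 numeric `c(positive, negative)`).
#'
#' @return Single numeric fold.
#' @examples
#' cal <- list(nPositive = 7869, nNegative = 12131)   # lambda 0.5
#' smp <- list(nPositive = 17293, nNegative = 2707)   # lambda 2.0
#' cnvFromDroplets(smp, cal, cal, cal)                # ~4
#' @export
cnvFromDroplets <- function(sampleTarget, sampleControl,
                            calibratorTarget, calibratorControl) {
    lam <- vapply(list(st = sampleTarget, sc = sampleControl,
                       ct = calibratorTarget, cc = calibratorControl),
                  function(w) lambdaEstimate(estimateLambda(
                      .dropletCounts(w)["pos"], .dropletCounts(w)["neg"])), 0)
    if (lam[["sc"]] == 0 || lam[["cc"]] == 0)
        stop("no control-gene signal (lambda = 0); cannot normalise",
             call. = FALSE)
    if (lam[["ct"]] == 0)
        stop("calibrator target well has no signal; fold undefined",
             call. = FALSE)
    unname((lam[["st"]] / lam[["sc"]]) / (lam[["ct"]] / lam[["cc"]]))
}

#' Cross-platform concordance of copy-number estimates
#'
#' Pearson product-moment correlation between paired fold estimates from two
#' platforms (e.g. SYBR qPCR vs ddPCR, or qPCR vs the TaqMan duplex assay).
#' Folds span more than an order of magnitude across individuals, so the
#' correlation is computed on log2-transformed folds to avoid leverage from
#' the highest-copy individuals.
#'
#' @param foldsA,foldsB Positive numeric vectors of paired folds (same
#'   individuals in the same order; length >= 3).
#'
#' @return List with elements `r` (correlation), `p.value` (two-sided),
#'   `n`, and `conf.int`.
#' @examples
#' a <- c(3, 8, 20, 45, 80)
#' platformConcordance(a, a * exp(rnorm(5, 0, 0.1)))
#' @export
platformConcordance <- function(foldsA, foldsB) {
    if (length(foldsA) != length(foldsB))
        stop("fold vectors must be paired (equal length)", call. = FALSE)
    if (length(foldsA) < 3L)
        stop("need at least 3 pairs for a correlation", call. = FALSE)
    if (any(foldsA <= 0) || any(foldsB <= 0))
        stop("folds must be positive for the log2 transform", call. = FALSE)
    ct <- cor.test(log2(foldsA), log2(foldsB), method = "pearson")
    list(r = unname(ct$estimate), p.value = ct$p.value,
         n = length(foldsA), conf.int = ct$conf.int)
}
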