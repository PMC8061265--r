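#' @importFrom stats lm coef residuals median sd setNames
NULL

.checkEfficiency <- function(e, what = "efficiency") {
    if (any(!is.finite(e)) || any(e <= 1) || any(e > 2.2))
        stop(sprintf("invalid %s: must lie in (1, 2.2], got %s",
                     what, paste(format(e), collapse = ", ")), call. = FALSE)
    invisible(e)
}

#' Fit a qPCR standard curve and estimate amplification efficiency
#'
#' Fits Cq against log10 dilution by least squares and converts the slope to
#' the per-cycle amplification efficiency `E = 10^(-1/slope)`. A perfectly
#' doubling assay has slope -log2(10) = -3.3219 cycles per decade and E = 2.
#'
#' @param log10Dilution Numeric vector of log10 dilutions (<= 0; 0 is the
#'   undiluted pool). At least 3 distinct levels are required.
#' @param cq Numeric vector of quantification cycles, parallel to
#'   `log10Dilution`. Several replicate Cq per level are allowed.
#' @param geneId Optional assay identifier stored in the result.
#'
#' @return An [EfficiencyEstimate-class] object.
#' @examples
#' fit <- fitStandardCurve(c(0, -1, -2), c(20, 23.3219, 26.6439))
#' efficiency(fit)  # 2.0
#' @export
fitStandardCurve <- function(log10Dilution, cq, geneId = NA_character_) {
    ok <- is.finite(log10Dilution) & is.finite(cq)
    log10Dilution <- log10Dilution[ok]; cq <- cq[ok]
    if (length(unique(log10Dilution)) < 3L)
        stop("insufficient standard curve: need >= 3 distinct dilution levels",
             call. = FALSE)
    fit <- lm(cq ~ log10Dilution)
    slope <- unname(coef(fit)[2L])
    if (!is.finite(slope) || slope >= 0)
        stop("inverted dilution series: fitted slope is non-negative ",
             "(Cq must increase as template is diluted)", call. = FALSE)
    e <- 10^(-1 / slope)
    .checkEfficiency(e, "fitted efficiency")
    sst <- sum((cq - mean(cq))^2)
    r2 <- if (sst > 0) max(0, 1 - sum(residuals(fit)^2) / sst) else 1
    new("EfficiencyEstimate", geneId = geneId, slope = slope,
        efficiency = e, rSquared = r2)
}

#' Efficiency-corrected relative fold (Pfaffl model)
#'
#' Computes the relative quantity of a target gene versus a reference gene
#' between a sample and the calibrator:
#' `fold = E_target^dCq_target / E_reference^dCq_reference`, where each
#' `dCq = Cq(calibrator) - Cq(sample)`. With both efficiencies equal to 2 this
#' reduces to the classic `2^-ddCq`.
#'
#' @param eTarget,eReference Amplification efficiencies in (1, 2.2].
#' @param dcqTarget,dcqReference Cq shifts (calibrator minus sample), cycles.
#'
#' @return Numeric fold change(s), vectorised over the Cq shifts.
#' @examples
#' pfafflFold(2, 5, 2, 0)   # 32
#' pfafflFold(1.9, 3, 2, 1) # 3.4295
#' @export
pfafflFold <- function(eTarget, dcqTarget, eReference, dcqReference) {
    .checkEfficiency(eTarget, "target efficiency")
    .checkEfficiency(eReference, "reference efficiency")
    eTarget^dcqTarget / eReference^dcqReference
}

#' Combine per-reference fold estimates
#'
#' When several single-copy reference genes are used for normalisation, the
#' per-reference fold estimates are combined by their geometric mean.
#'
#' @param folds Numeric vector of positive per-reference folds.
#' @return Single numeric fold.
#' @examples
#' combineReferences(c(4, 9))  # 6
#' @export
combineReferences <- function(folds) {
    folds <- unlist(folds, use.names = FALSE)
    if (length(folds) == 0L)
        stop("no reference folds to combine", call. = FALSE)
    if (any(!is.finite(folds)) || any(folds <= 0))
        stop("reference folds must be positive and finite", call. = FALSE)
    exp(mean(log(folds)))
}

.meanCqTable <- function(measurements) {
    det <- measurements[is.finite(measurements$cq), , drop = FALSE]
    if (nrow(det) == 0L)
        return(data.frame(sample_id = character(), gene_id = character(),
                          cq = numeric(), n = integer()))
    agg <- aggregate(cq ~ sample_id + gene_id, data = det, FUN = mean)
    n <- aggregate(cq ~ sample_id + gene_id, data = det, FUN = length)
    agg$n <- n$cq
    agg
}

.efficiencyLookup <- function(efficiencies, genes) {
    if (is.null(efficiencies)) {
        message("no standard-curve efficiencies supplied; ",
                "assuming perfect doubling (E = 2.0) for all assays")
        return(setNames(rep(2.0, length(genes)), genes))
    }
    if (is.list(efficiencies) && all(vapply(efficiencies, is, TRUE, "EfficiencyEstimate")))
        efficiencies <- setNames(vapply(efficiencies, efficiency, 0),
                                 vapply(efficiencies, function(x) x@geneId, ""))
    if (is(efficiencies, "EfficiencyEstimate"))
        efficiencies <- setNames(efficiency(efficiencies), efficiencies@geneId)
    miss <- setdiff(genes, names(efficiencies))
    if (length(miss)) {
        message("no efficiency for ", paste(miss, collapse = ", "),
                "; assuming E = 2.0")
        efficiencies[miss] <- 2.0
    }
    .checkEfficiency(efficiencies[genes])
    efficiencies[genes]
}

#' Relative copy-number quantification by efficiency-corrected delta-delta-Cq
#'
#' Runs the full relative-quantification pipeline on a table of Cq
#' measurements: technical replicates are averaged on the Cq scale, a per-gene
#' calibrator Cq is taken as the mean over the calibrator samples, each
#' sample x target fold is computed with [pfafflFold()] against every
#' reference gene, and per-reference folds are combined with
#' [combineReferences()]. Copy numbers are expressed relative to the
#' calibrator (the fully susceptible line).
#'
#' Undetermined Cq replicates are dropped; a target with no determined Cq in a
#' non-calibrator sample is reported as fold 0 with flag
#' `"no-target-amplification"`. A sample with no determined Cq for any
#' reference gene is skipped with a warning.
#'
#' @param measurements Data frame with columns `sample_id`, `gene_id`,
#'   `replicate`, `cq` (`NA` = undetermined), as read by [readCqTable()].
#' @param efficiencies Named numeric vector of per-gene efficiencies, a list
#'   of [EfficiencyEstimate-class] objects, or `NULL` to assume E = 2 for all
#'   assays (announced with a message).
#' @param calibratorSamples Character vector of calibrator sample ids
#'   (non-empty; present in `measurements`).
#' @param targets,references Character vectors of target and reference gene
#'   ids.
#'
#' @return Data frame with columns `sample_id`, `gene_id`, `fold`,
#'   `n_replicates`, `cv` (coefficient of variation across replicate-level
#'   folds; `NA` for single replicates) and `flag`.
#' @examples
#' spec <- qpcrSimSpec(truths = rbind(s1 = c(T1 = 8, R1 = 1)),
#'                     references = "R1", calibrators = "cal",
#'                     sigmaCq = 0, seed = 1)
#' m <- simulateQpcr(spec)
#' quantifyCnv(m, NULL, "cal", "T1", "R1")
#' @export
quantifyCnv <- function(measurements, efficiencies = NULL, calibratorSamples,
                        targets, references) {
    stopifnot(is.data.frame(measurements),
              all(c("sample_id", "gene_id", "cq") %in% names(measurements)))
    if (length(calibratorSamples) == 0L)
        stop("calibrator sample set must be non-empty", call. = FALSE)
    if (!any(measurements$sample_id %in% calibratorSamples))
        stop("no measurements found for any calibrator sample", call. = FALSE)
    genes <- union(targets, references)
    eff <- .efficiencyLookup(efficiencies, genes)

    means <- .meanCqTable(measurements)
    calMeans <- means[means$sample_id %in% calibratorSamples, , drop = FALSE]
    calCq <- vapply(genes, function(g) {
        v <- calMeans$cq[calMeans$gene_id == g]
        if (length(v) == 0L) NA_real_ else mean(v)
    }, 0)
    if (any(is.na(calCq)))
        stop("calibrator samples lack determined Cq for: ",
             paste(genes[is.na(calCq)], collapse = ", "), call. = FALSE)

    samples <- unique(measurements$sample_id)
    out <- vector("list", length(samples) * length(targets))
    k <- 0L
    for (s in samples) {
        refCq <- setNames(vapply(references, function(r) {
            v <- means$cq[means$sample_id == s & means$gene_id == r]
            if (length(v)) v else NA_real_
        }, 0), references)
        availRefs <- references[!is.na(refCq)]
        if (length(availRefs) == 0L) {
            warning("sample '", s, "' has no determined reference Cq; skipped",
                    call. = FALSE)
            next
        }
        for (tg in targets) {
            k <- k + 1L
            tgRows <- measurements$sample_id == s & measurements$gene_id == tg &
                is.finite(measurements$cq)
            tgCqs <- measurements$cq[tgRows]
            if (length(tgCqs) == 0L) {
                out[[k]] <- data.frame(sample_id = s, gene_id = tg, fold = 0,
                                       n_replicates = 0L, cv = NA_real_,
                                       flag = "no-target-amplification")
                next
            }
            foldOf <- function(cqT) {
                perRef <- vapply(availRefs, function(r)
                    pfafflFold(eff[[tg]], calCq[[tg]] - cqT,
                               eff[[r]], calCq[[r]] - refCq[[r]]), 0)
                combineReferences(perRef)
            }
            fold <- foldOf(mean(tgCqs))
            repFolds <- vapply(tgCqs, foldOf, 0)
            cv <- if (length(repFolds) > 1L) sd(repFolds) / mean(repFolds) else NA_real_
            out[[k]] <- data.frame(sample_id = s, gene_id = tg, fold = fold,
                                   n_replicates = length(tgCqs), cv = cv,
                                   flag = NA_character_)
        }
    }
    res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
    rownames(res) <- NULL
    res
}

#' Copy number from a dual-colour TaqMan duplex well
#'
#' Quantifies target (FAM probe) versus control (HEX probe) amplified in the
#' same well, relative to a calibrator well, using [pfafflFold()]. An
#' undetermined FAM Cq with a determined HEX Cq is biologically "no target
#' amplification" and is reported as fold 0 with a flag; an undetermined HEX
#' Cq means the well failed and is an error.
#'
#' @param famCq,hexCq Sample Cq of the FAM (target) and HEX (control) probes;
#'   `NA` = undetermined.
#' @param eFam,eHex Amplification efficiencies of the two assays.
#' @param calibratorFamCq,calibratorHexCq Calibrator-well Cq values.
#'
#' @return Data frame with columns `fold` and `flag`, one row per well.
#' @examples
#' duplexQuantify(25, 30, 2, 2, 30, 30)  # fold 32
#' @export
duplexQuantify <- function(famCq, hexCq, eFam, eHex,
                           calibratorFamCq, calibratorHexCq) {
    n <- max(length(famCq), length(hexCq))
    famCq <- rep_len(famCq, n); hexCq <- rep_len(hexCq, n)
    if (any(is.na(hexCq)))
        stop("failed well: undetermined HEX (control) Cq", call. = FALSE)
    if (any(is.na(c(calibratorFamCq, calibratorHexCq))))
        stop("calibrator Cq must be determined", call. = FALSE)
    fold <- rep(NA_real_, n)
    flag <- rep(NA_character_, n)
    noTarget <- is.na(famCq)
    fold[noTarget] <- 0
    flag[noTarget] <- "no-target-amplification"
    if (any(!noTarget))
        fold[!noTarget] <- pfafflFold(eFam, calibratorFamCq - famCq[!noTarget],
                                      eHex, calibratorHexCq - hexCq[!noTarget])
    data.frame(fold = fold, flag = flag)
}

#' Call a quantification cycle from a raw amplification trace
#'
#' Baseline-corrects a per-cycle fluorescence trace (mean of the baseline
#' window subtracted) and reports the fractional cycle at which the trace
#' first crosses the detection threshold going upward, by linear
#' interpolation between the bracketing cycles. The automatic threshold is
#' the baseline mean plus 10 baseline standard deviations.
#'
#' @param trace Numeric vector of fluorescence per cycle (>= 40 cycles).
#' @param baselineWindow Length-2 integer vector of cycles delimiting the
#'   baseline (default cycles 3 to 15, before the exponential phase).
#' @param threshold Fluorescence threshold on the raw scale, or `NULL` for
#'   the automatic threshold. A threshold not exceeding the baseline noise
#'   band is an error.
#'
#' @return Fractional cycle (Cq), or `NA` if the threshold is never crossed.
#' @examples
#' tr <- c(rep(0.01, 23), 0.6, 1.6, rep(2.5, 15))
#' callCq(tr, threshold = 1.0)  # 24.4
#' @export
callCq <- function(trace, baselineWindow = c(3L, 15L), threshold = NULL) {
    if (length(trace) < 40L)
        stop("amplification trace must cover at least 40 cycles", call. = FALSE)
    bw <- seq.int(baselineWindow[1L], baselineWindow[2L])
    base <- trace[bw]
    m <- mean(base)
    s <- sd(base)
    if (!is.finite(s) || s == 0)
        s <- .Machine$double.eps * max(abs(trace), 1)
    if (is.null(threshold)) {
        threshold <- m + 10 * s
    } else if (threshold <= m + s) {
        stop("invalid threshold: at or below baseline noise (",
             format(m + s), ")", call. = FALSE)
    }
    above <- trace >= threshold
    cross <- which(!above[-length(above)] & above[-1L])
    if (length(cross) == 0L)
        return(NA_real_)
    i <- cross[1L] + 1L  # first cycle at/above threshold
    (i - 1L) + (threshold - trace[i - 1L]) / (trace[i] - trace[i - 1L])
}
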