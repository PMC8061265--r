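#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom stats median
NULL

#' Normalize a depth track by the mean coverage of a baseline contig
#'
#' Divides every window depth by the unweighted arithmetic mean of the window
#' depths on a baseline contig (a chromosome-1 surrogate carrying no copy
#' number change), removing library-size differences between sequencing runs.
#'
#' @param track [DepthTrack] to normalize.
#' @param baseline [DepthTrack] of the baseline contig from the same library.
#'
#' @return A [DepthTrack] of normalized depths (unitless; ~1 at diploid
#'   coverage).
#' @examples
#' tr <- DepthTrack("chr2", c(0, 1000), c(1000, 2000), c(2000, 40))
#' bl <- DepthTrack("chr1", c(0, 1000), c(1000, 2000), c(40, 40))
#' depth(normalizeDepth(tr, bl))  # 50, 1
#' @export
normalizeDepth <- function(track, baseline) {
    stopifnot(is(track, "DepthTrack"), is(baseline, "DepthTrack"))
    m <- mean(depth(baseline))
    if (!is.finite(m) || m <= 0)
        stop("baseline contig has zero mean depth; cannot normalize",
             call. = FALSE)
    .DepthTrackFromGRanges(granges(track), depth(track) / m)
}

#' Case/control ratio track with repeat masking
#'
#' Computes the per-window ratio of normalized case depth to normalized
#' control depth on an identical window grid. Windows where the control drops
#' below `maskFloor` (inclusive floor: a control exactly at the floor is
#' kept) are masked rather than given a ratio: such windows are dominated by
#' repeated elements and unresolved assembly, where the ratio is meaningless.
#'
#' @param caseNorm,controlNorm Normalized [DepthTrack] objects (see
#'   [normalizeDepth()]) on identical grids.
#' @param maskFloor Normalized control depth below which a window is masked
#'   (default 0.25).
#'
#' @return A [RatioTrack].
#' @export
ratioTrack <- function(caseNorm, controlNorm, maskFloor = 0.25) {
    stopifnot(is(caseNorm, "DepthTrack"), is(controlNorm, "DepthTrack"))
    if (length(caseNorm) != length(controlNorm) ||
        !all(start(caseNorm) == start(controlNorm)) ||
        !all(width(caseNorm) == width(controlNorm)) ||
        as.character(seqnames(caseNorm))[1L] != as.character(seqnames(controlNorm))[1L])
        stop("case and control tracks are not on the same window grid",
             call. = FALSE)
    ctrl <- depth(controlNorm)
    msk <- ctrl < maskFloor
    r <- ifelse(msk, NA_real_, depth(caseNorm) / ctrl)
    gr <- granges(caseNorm)
    mcols(gr)$ratio <- r
    mcols(gr)$masked <- msk
    new("RatioTrack", gr)
}

#' Call amplified segments from a ratio track
#'
#' Finds maximal runs of unmasked windows with ratio at or above `foldMin`.
#' Runs may be interrupted by stretches of up to `maxMaskGap` consecutive
#' masked windows (repeat gaps inside the amplification); such runs are
#' merged across the gap and the number of internal masked windows is
#' recorded. Runs with fewer than `minWindows` unmasked member windows are
#' discarded. The reported fold of a region is the median ratio of its
#' unmasked member windows, robust to residual repeat windows.
#'
#' @param ratios A [RatioTrack].
#' @param foldMin Minimum window ratio for membership (default 5; well below
#'   a ~50-fold amplification but above heterozygous copy-number noise in
#'   pooled data).
#' @param minWindows Minimum number of unmasked windows per region
#'   (default 5).
#' @param maxMaskGap Maximum run of consecutive masked windows bridged
#'   inside a region (default 10).
#'
#' @return A [GenomicRanges::GRanges] of regions sorted by position with
#'   metadata columns `fold` (median window ratio), `n_windows` (unmasked
#'   members) and `n_masked_internal`; empty when nothing is called.
#' @export
callAmplifiedRegions <- function(ratios, foldMin = 5, minWindows = 5,
                                 maxMaskGap = 10) {
    stopifnot(is(ratios, "RatioTrack"))
    msk <- masked(ratios)
    r <- ratio(ratios)
    eligible <- !msk & r >= foldMin
    idx <- which(eligible)
    empty <- GRanges(fold = numeric(), n_windows = integer(),
                     n_masked_internal = integer())
    if (length(idx) == 0L)
        return(empty)
    # merge adjacent eligible windows when everything between them is masked
    # and the gap is short enough
    cumMaskOnly <- cumsum(!msk & !eligible)  # non-masked, non-eligible windows
    newGroup <- c(TRUE, vapply(seq_along(idx)[-1L], function(k) {
        i <- idx[k - 1L]; j <- idx[k]
        gap <- j - i - 1L
        if (gap == 0L) return(FALSE)
        if (gap > maxMaskGap) return(TRUE)
        # any ineligible-but-unmasked window in between breaks the run
        (cumMaskOnly[j - 1L] - cumMaskOnly[i]) > 0L
    }, TRUE))
    grp <- cumsum(newGroup)
    regions <- lapply(split(idx, grp), function(members) {
        if (length(members) < minWindows) return(NULL)
        first <- members[1L]; last <- members[length(members)]
        span <- first:last
        GRanges(seqnames = as.character(seqnames(ratios))[1L],
                ranges = IRanges(start = start(ratios)[first],
                                 end = end(ratios)[last]),
                fold = median(r[members]),
                n_windows = length(members),
                n_masked_internal = sum(msk[span]))
    })
    regions <- regions[!vapply(regions, is.null, TRUE)]
    if (length(regions) == 0L)
        return(empty)
    out <- do.call(c, unname(regions))
    sort(out)
}

#' Genes spanned by an amplified region
#'
#' Reports the gene identifiers whose annotated intervals overlap a called
#' region by at least one base pair, in positional order. Coordinates are
#' half-open as in BED, so a gene ending exactly where the region starts does
#' not overlap.
#'
#' @param region A single-range [GenomicRanges::GRanges] (e.g. one row of
#'   [callAmplifiedRegions()] output).
#' @param genes A [GenomicRanges::GRanges] of gene intervals with a `name`
#'   metadata column, as read by [readGeneBed()].
#'
#' @return Character vector of gene ids, possibly empty.
#' @export
annotateRegion <- function(region, genes) {
    stopifnot(is(region, "GRanges"), length(region) == 1L,
              is(genes, "GRanges"))
    if (is.null(mcols(genes)$name))
        stop("gene annotation lacks a 'name' column", call. = FALSE)
    hits <- findOverlaps(genes, region, minoverlap = 1L)
    g <- genes[queryHits(hits)]
    as.character(mcols(g)$name[order(start(g))])
}
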