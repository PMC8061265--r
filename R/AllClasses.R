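#' @importFrom GenomicRanges GRanges granges start end width seqnames mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame isSorted
#' @importFrom GenomeInfoDb seqnames seqlevels
NULL

## ---------------------------------------------------------------------------
## DepthTrack: a tiling, windowed read-depth track on a single contig
## ---------------------------------------------------------------------------

#' Windowed read-depth track
#'
#' A `DepthTrack` is a [GenomicRanges::GRanges] restricted to a single contig
#' whose ranges tile the covered interval without gaps or overlaps (fixed
#' window width except for a possibly shorter terminal window) and whose
#' `depth` metadata column holds the mean read depth per window.
#'
#' @param contig Contig (chromosome) name, single character.
#' @param start,end Integer vectors of 0-based half-open window coordinates,
#'   as in BedGraph.
#' @param depth Numeric vector of non-negative, finite mean depths.
#'
#' @return A `DepthTrack` object.
#' @examples
#' DepthTrack("chr2", start = c(0, 1000), end = c(1000, 2000), depth = c(40, 38))
#' @seealso [normalizeDepth()], [ratioTrack()], [readDepthTrack()]
#' @aliases DepthTrack-class
#' @export
DepthTrack <- function(contig, start, end, depth) {
    stopifnot(length(start) == length(end), length(depth) == length(start))
    gr <- GRanges(seqnames = contig,
                  ranges = IRanges(start = as.integer(start) + 1L,
                                   end = as.integer(end)))
    mcols(gr)$depth <- as.numeric(depth)
    new("DepthTrack", gr)
}

setClass("DepthTrack", contains = "GRanges")

.validDepthTrack <- function(object) {
    msg <- character()
    if (length(object) == 0L)
        return("track has no windows")
    if (length(unique(as.character(seqnames(object)))) != 1L)
        msg <- c(msg, "track must cover a single contig")
    d <- mcols(object)$depth
    if (is.null(d))
        msg <- c(msg, "missing 'depth' metadata column")
    else if (!is.numeric(d) || any(!is.finite(d)) || any(d < 0))
        msg <- c(msg, "depth must be finite and >= 0")
    s <- start(object); e <- end(object)
    if (is.unsorted(s, strictly = TRUE))
        msg <- c(msg, "windows must be sorted by start")
    else if (length(object) > 1L) {
        if (any(s[-1L] != e[-length(object)] + 1L))
            msg <- c(msg, "windows must tile without gaps or overlaps")
        w <- width(object)
        if (length(unique(w[-length(w)])) > 1L ||
            (length(w) > 1L && w[length(w)] > w[1L]))
            msg <- c(msg, "windows must have fixed width (terminal window may be shorter)")
    }
    if (length(msg)) msg else TRUE
}
setValidity("DepthTrack", .validDepthTrack)

#' @describeIn DepthTrack Mean window depths.
#' @param x,object A `DepthTrack`.
#' @export
setGeneric("depth", function(x) standardGeneric("depth"))

#' @rdname DepthTrack
#' @export
setMethod("depth", "DepthTrack", function(x) mcols(x)$depth)

#' @rdname DepthTrack
#' @export
setMethod("show", "DepthTrack", function(object) {
    cat(sprintf("DepthTrack on %s: %d windows of %d bp, mean depth %.2f\n",
                as.character(seqnames(object))[1L], length(object),
                width(object)[1L], mean(depth(object))))
    callNextMethod()
})

# Internal: wrap an already-1-based GRanges with a depth mcol.
.DepthTrackFromGRanges <- function(gr, depth) {
    mcols(gr) <- NULL
    mcols(gr)$depth <- as.numeric(depth)
    new("DepthTrack", gr)
}

## ---------------------------------------------------------------------------
## RatioTrack: case/control normalized coverage ratio with repeat masking
## ---------------------------------------------------------------------------

#' Case/control coverage-ratio track
#'
#' A `RatioTrack` shares the window grid of the [DepthTrack] objects it was
#' derived from and carries two metadata columns: `ratio`, the case/control
#' normalized depth ratio, and `masked`, a logical flag marking windows where
#' the control depth fell below the masking floor (repeat or assembly
#' artifacts). Masked windows carry `NA` ratios.
#'
#' @aliases RatioTrack-class ratio masked
#' @seealso [ratioTrack()], [callAmplifiedRegions()]
#' @name RatioTrack
NULL

setClass("RatioTrack", contains = "GRanges")

.validRatioTrack <- function(object) {
    msg <- character()
    r <- mcols(object)$ratio
    m <- mcols(object)$masked
    if (is.null(r) || is.null(m))
        return("RatioTrack needs 'ratio' and 'masked' metadata columns")
    if (!is.logical(m) || any(is.na(m)))
        msg <- c(msg, "'masked' must be logical without NA")
    else {
        if (any(!is.na(r[m])))
            msg <- c(msg, "masked windows must not carry a ratio")
        if (any(is.na(r[!m])) || any(r[!m] < 0))
            msg <- c(msg, "unmasked ratios must be finite and >= 0")
    }
    if (length(msg)) msg else TRUE
}
setValidity("RatioTrack", .validRatioTrack)

#' @rdname RatioTrack
#' @param x,object A `RatioTrack`.
#' @export
setGeneric("ratio", function(x) standardGeneric("ratio"))

#' @rdname RatioTrack
#' @export
setMethod("ratio", "RatioTrack", function(x) mcols(x)$ratio)

#' @rdname RatioTrack
#' @export
setGeneric("masked", function(x) standardGeneric("masked"))

#' @rdname RatioTrack
#' @export
setMethod("masked", "RatioTrack", function(x) mcols(x)$masked)

#' @rdname RatioTrack
#' @export
setMethod("show", "RatioTrack", function(object) {
    cat(sprintf("RatioTrack on %s: %d windows (%d masked), median unmasked ratio %.3f\n",
                as.character(seqnames(object))[1L], length(object),
                sum(masked(object)),
                stats::median(ratio(object)[!masked(object)])))
    callNextMethod()
})

## ---------------------------------------------------------------------------
## EfficiencyEstimate: amplification efficiency fitted from a dilution series
## ---------------------------------------------------------------------------

#' Amplification-efficiency estimate from a standard curve
#'
#' Holds the least-squares fit of Cq against log10 dilution for one assay:
#' the slope (cycles per decade), the amplification efficiency
#' `E = 10^(-1/slope)` (fold amplification per cycle; 2 is perfect doubling)
#' and the coefficient of determination of the fit.
#'
#' @slot geneId Assay/gene identifier.
#' @slot slope Fitted slope in cycles per log10 dilution unit (negative).
#' @slot efficiency Fold amplification per cycle, in (1, 2.2].
#' @slot rSquared R-squared of the linear fit.
#'
#' @aliases EfficiencyEstimate-class efficiency
#' @seealso [fitStandardCurve()]
#' @export
setClass("EfficiencyEstimate",
         representation(geneId = "character", slope = "numeric",
                        efficiency = "numeric", rSquared = "numeric"))

setValidity("EfficiencyEstimate", function(object) {
    msg <- character()
    if (length(object@slope) != 1L || !is.finite(object@slope) || object@slope >= 0)
        msg <- c(msg, "slope must be a single negative number")
    if (length(object@efficiency) != 1L || !is.finite(object@efficiency) ||
        object@efficiency <= 1 || object@efficiency > 2.2)
        msg <- c(msg, "efficiency must lie in (1, 2.2]")
    if (length(object@rSquared) != 1L || is.na(object@rSquared) ||
        object@rSquared < 0 || object@rSquared > 1 + 1e-12)
        msg <- c(msg, "rSquared must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @rdname EfficiencyEstimate-class
#' @param x,object An `EfficiencyEstimate`.
#' @export
setGeneric("efficiency", function(x) standardGeneric("efficiency"))

#' @rdname EfficiencyEstimate-class
#' @export
setMethod("efficiency", "EfficiencyEstimate", function(x) x@efficiency)

#' @rdname EfficiencyEstimate-class
#' @export
setMethod("show", "EfficiencyEstimate", function(object) {
    cat(sprintf("EfficiencyEstimate for %s: slope %.4f cycles/decade, E = %.4f (%.1f%%), R^2 = %.4f\n",
                object@geneId, object@slope, object@efficiency,
                100 * (object@efficiency - 1), object@rSquared))
})

## ---------------------------------------------------------------------------
## PoissonEstimate: ddPCR mean copies per droplet
## ---------------------------------------------------------------------------

#' Poisson occupancy estimate from droplet partition counts
#'
#' Mean template copies per droplet, `lambda = -ln(negative fraction)`, with a
#' 95% confidence interval obtained by transforming a Wilson score interval on
#' the negative-droplet fraction.
#'
#' @slot lambda Mean copies per droplet.
#' @slot ciLow,ciHigh Confidence bounds (copies per droplet).
#' @slot nDroplets Total accepted droplets.
#'
#' @aliases PoissonEstimate-class lambdaEstimate
#' @seealso [estimateLambda()]
#' @export
setClass("PoissonEstimate",
         representation(lambda = "numeric", ciLow = "numeric",
                        ciHigh = "numeric", nDroplets = "integer"))

setValidity("PoissonEstimate", function(object) {
    if (!(object@ciLow <= object@lambda + 1e-12 &&
          object@lambda <= object@ciHigh + 1e-12))
        "confidence interval must bracket lambda" else TRUE
})

#' @rdname PoissonEstimate-class
#' @param x,object A `PoissonEstimate`.
#' @export
setGeneric("lambdaEstimate", function(x) standardGeneric("lambdaEstimate"))

#' @rdname PoissonEstimate-class
#' @export
setMethod("lambdaEstimate", "PoissonEstimate", function(x) x@lambda)

#' @rdname PoissonEstimate-class
#' @export
setMethod("show", "PoissonEstimate", function(object) {
    cat(sprintf("PoissonEstimate: lambda = %.4f copies/droplet [%.4f, %.4f], n = %d droplets\n",
                object@lambda, object@ciLow, object@ciHigh, object@nDroplets))
})
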