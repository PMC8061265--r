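#' @importFrom utils read.delim write.table
#' @importFrom rtracklayer import
NULL

.requireColumns <- function(df, cols, path) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
        stop("'", path, "': missing required column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    invisible(df)
}

.readDelim <- function(path, sep = "\t") {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
               check.names = FALSE)
}

#' Read a Cq measurement table
#'
#' Reads a delimited table of raw qPCR observations with columns
#' `sample_id`, `gene_id`, `gene_role`, `dye`, `replicate`, `cq` and optional
#' `template_conc`. The tokens `"Undetermined"`, `"NA"` and empty cells map
#' to an undetermined Cq (`NA`). Duplicate
#' (sample, gene, replicate, dye) combinations are rejected.
#'
#' @param path Path to a UTF-8 delimited text file with a header.
#' @param sep Field separator (default tab).
#' @return Data frame of typed Cq measurements.
#' @export
readCqTable <- function(path, sep = "\t") {
    df <- .readDelim(path, sep)
    .requireColumns(df, c("sample_id", "gene_id", "gene_role", "dye",
                          "replicate", "cq"), path)
    cqRaw <- trimws(as.character(df$cq))
    undet <- is.na(cqRaw) |
        cqRaw %in% c("Undetermined", "undetermined", "NA", "")
    cq <- suppressWarnings(as.numeric(cqRaw))
    if (any(!undet & is.na(cq)))
        stop("'", path, "': unparseable cq value(s) at data line(s) ",
             paste(utils::head(which(!undet & is.na(cq)), 5), collapse = ", "),
             call. = FALSE)
    if (any(!is.na(cq) & cq <= 0))
        stop("'", path, "': determined cq values must be positive",
             call. = FALSE)
    df$cq <- cq
    key <- paste(df$sample_id, df$gene_id, df$replicate, df$dye, sep = "\r")
    if (anyDuplicated(key))
        stop("'", path, "': duplicate (sample_id, gene_id, replicate, dye) ",
             "at data line(s) ",
             paste(utils::head(which(duplicated(key)), 5), collapse = ", "),
             call. = FALSE)
    df
}

#' Read a dilution-series (standard-curve) table
#'
#' @param path Delimited file with columns `gene_id`, `log10_dilution`, `cq`.
#' @param sep Field separator (default tab).
#' @return Data frame.
#' @seealso [fitStandardCurve()]
#' @export
readStandardCurve <- function(path, sep = "\t") {
    df <- .readDelim(path, sep)
    .requireColumns(df, c("gene_id", "log10_dilution", "cq"), path)
    df$log10_dilution <- as.numeric(df$log10_dilution)
    df$cq <- as.numeric(df$cq)
    df
}

#' Read a ddPCR droplet-count table
#'
#' @param path Delimited file with columns `sample_id`, `gene_id`,
#'   `n_positive`, `n_negative`.
#' @param sep Field separator (default tab).
#' @return Data frame of integer droplet counts.
#' @export
readDropletTable <- function(path, sep = "\t") {
    df <- .readDelim(path, sep)
    .requireColumns(df, c("sample_id", "gene_id", "n_positive", "n_negative"),
                    path)
    df$n_positive <- as.integer(df$n_positive)
    df$n_negative <- as.integer(df$n_negative)
    if (any(is.na(df$n_positive)) || any(is.na(df$n_negative)) ||
        any(df$n_positive < 0) || any(df$n_negative < 0))
        stop("'", path, "': droplet counts must be non-negative integers",
             call. = FALSE)
    df
}

#' Read a windowed depth track
#'
#' Reads per-window coverage from BedGraph (4 columns, optional `track`
#' line) or a headered delimited file with columns `contig`, `start`, `end`,
#' `depth` (both 0-based half-open). Windows must be sorted and tiling;
#' overlapping or unsorted input is rejected unless `sortWindows = TRUE`.
#'
#' @param path Input file.
#' @param format `"auto"` (default), `"bedgraph"` or `"tsv"`.
#' @param sortWindows Sort windows by start before validation.
#' @return A [DepthTrack].
#' @export
readDepthTrack <- function(path, format = c("auto", "bedgraph", "tsv"),
                           sortWindows = FALSE) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    if (format == "auto") {
        first <- readLines(path, n = 1L)
        fields <- strsplit(first, "[\t ,]+")[[1L]]
        format <- if (grepl("^track", first) ||
                      (length(fields) == 4L &&
                       !any(is.na(suppressWarnings(as.numeric(fields[2:4]))))))
            "bedgraph" else "tsv"
    }
    if (format == "bedgraph") {
        gr <- import(path, format = "bedGraph")
        df <- data.frame(contig = as.character(seqnames(gr)),
                         start = start(gr) - 1L, end = end(gr),
                         depth = mcols(gr)$score)
    } else {
        df <- .readDelim(path)
        .requireColumns(df, c("contig", "start", "end", "depth"), path)
    }
    if (length(unique(df$contig)) != 1L)
        stop("'", path, "': depth track must cover a single contig",
             call. = FALSE)
    if (sortWindows)
        df <- df[order(df$start), , drop = FALSE]
    tryCatch(
        DepthTrack(df$contig[1L], df$start, df$end, df$depth),
        error = function(e)
            stop("'", path, "': invalid depth track: ", conditionMessage(e),
                 call. = FALSE))
}

#' Read a BED gene-annotation file
#'
#' @param path BED file (>= 4 columns; the name field holds gene ids).
#' @return A [GenomicRanges::GRanges] with a `name` metadata column.
#' @export
readGeneBed <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    gr <- tryCatch(import(path, format = "bed"),
                   error = function(e)
                       stop("'", path, "': malformed BED: ",
                            conditionMessage(e), call. = FALSE))
    if (is.null(mcols(gr)$name))
        stop("'", path, "': BED file lacks a name column (need BED4+)",
             call. = FALSE)
    gr
}

#' Write called amplified regions as BED4+2
#'
#' Writes one line per region with columns contig, start, end (0-based
#' half-open), name, fold (3 decimals) and number of member windows,
#' preceded by a single `#`-comment header line. Output ordering is the
#' positional order of the input and rewriting the same regions is
#' byte-identical.
#'
#' @param regions Output of [callAmplifiedRegions()].
#' @param path Output file.
#' @return Invisibly, the output path.
#' @export
writeRegionsBed <- function(regions, path) {
    header <- "#contig\tstart\tend\tname\tfold\tn_windows"
    lines <- character()
    if (length(regions)) {
        regions <- sort(regions)
        lines <- sprintf("%s\t%d\t%d\t%s\t%.3f\t%d",
                         as.character(seqnames(regions)),
                         start(regions) - 1L, end(regions),
                         sprintf("amp_%d", seq_along(regions)),
                         mcols(regions)$fold, mcols(regions)$n_windows)
    }
    writeLines(c(header, lines), path)
    invisible(path)
}

#' Write a relative-quantity table
#'
#' @param quant Data frame from [quantifyCnv()].
#' @param path Output file (tab-separated, with header).
#' @return Invisibly, the output path.
#' @export
writeRelativeQuantities <- function(quant, path) {
    write.table(quant, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a depth track as BedGraph
#'
#' @param track A [DepthTrack].
#' @param path Output file.
#' @return Invisibly, the output path.
#' @export
writeDepthTrack <- function(track, path) {
    stopifnot(is(track, "DepthTrack"))
    lines <- sprintf("%s\t%d\t%d\t%s",
                     as.character(seqnames(track)), start(track) - 1L,
                     end(track), format(depth(track), trim = TRUE,
                                        scientific = FALSE))
    writeLines(lines, path)
    invisible(path)
}

#' Read a counts matrix (genes x samples)
#'
#' @param path Delimited file whose first column holds gene ids and whose
#'   header names the samples.
#' @param sep Field separator (default tab).
#' @return Integer matrix with gene rownames.
#' @export
readCountsMatrix <- function(path, sep = "\t") {
    df <- .readDelim(path, sep)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    storage.mode(m) <- "numeric"
    if (any(is.na(m)) || any(m < 0))
        stop("'", path, "': counts must be non-negative numbers", call. = FALSE)
    m
}

#' Read a sample sheet
#'
#' @param path Delimited file with columns `sample_id`, `group`,
#'   `replicate`.
#' @param sep Field separator (default tab).
#' @return Data frame.
#' @export
readSampleSheet <- function(path, sep = "\t") {
    df <- .readDelim(path, sep)
    .requireColumns(df, c("sample_id", "group", "replicate"), path)
    df
}
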