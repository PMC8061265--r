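#' @importFrom stats rnorm rbinom rpois rnbinom rlnorm runif
#' @importFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors metadata
NULL

## ---------------------------------------------------------------------------
## Simulation specifications
## ---------------------------------------------------------------------------

#' Specification of a simulated qPCR run
#'
#' Describes the generative model inverted by [quantifyCnv()]: every
#' replicate Cq is `baselineCq(gene) - log(truth) / log(E(gene)) + N(0,
#' sigmaCq)`, where `truth` is the sample's true fold versus the calibrator.
#' Calibrator samples (truth 1 for every gene) are appended automatically.
#'
#' @param truths Numeric matrix of true folds, samples in rows (rownames =
#'   sample ids), genes in columns (colnames = gene ids, including the
#'   reference genes at truth 1).
#' @param references Character vector of reference gene ids (columns of
#'   `truths`).
#' @param calibrators Character vector of calibrator sample ids to generate
#'   (truth 1 for every gene).
#' @param efficiencies Named per-gene amplification efficiencies (default 2.0
#'   for every gene).
#' @param baselineCq Named per-gene calibrator Cq at nominal template
#'   (default 30 cycles, typical of 0.5 ng/ul gDNA).
#' @param sigmaCq Gaussian cycle noise SD (cycles).
#' @param replicates Technical replicates per well.
#' @param seed Integer seed pinning the run.
#'
#' @return A `qpcrSimSpec` list.
#' @seealso [simulateQpcr()]
#' @export
qpcrSimSpec <- function(truths, references, calibrators,
                        efficiencies = NULL, baselineCq = NULL,
                        sigmaCq = 0.15, replicates = 2L, seed = 1L) {
    truths <- as.matrix(truths)
    if (is.null(rownames(truths)))
        rownames(truths) <- paste0("sample", seq_len(nrow(truths)))
    genes <- colnames(truths)
    if (is.null(genes))
        stop("truths must have gene ids as column names", call. = FALSE)
    if (any(truths <= 0))
        stop("true folds must be positive", call. = FALSE)
    if (sigmaCq < 0)
        stop("sigmaCq must be >= 0", call. = FALSE)
    if (!all(references %in% genes))
        stop("reference genes missing from truths", call. = FALSE)
    if (is.null(efficiencies))
        efficiencies <- setNames(rep(2.0, length(genes)), genes)
    .checkEfficiency(efficiencies[genes])
    if (is.null(baselineCq))
        baselineCq <- setNames(rep(30, length(genes)), genes)
    structure(list(truths = truths, references = references,
                   targets = setdiff(genes, references),
                   calibrators = calibrators,
                   efficiencies = efficiencies[genes],
                   baselineCq = baselineCq[genes],
                   sigmaCq = sigmaCq, replicates = as.integer(replicates),
                   seed = as.integer(seed)),
              class = "qpcrSimSpec")
}

#' Specification of a simulated pool-seq depth experiment
#'
#' @param contig,contigLength Name and length (bp) of the contig carrying the
#'   amplification.
#' @param window Window width (bp).
#' @param mu Mean per-window read depth of the control library.
#' @param segments Data frame of planted amplified segments with columns
#'   `start`, `end` (0-based half-open, bp) and `fold`.
#' @param maskSegments Data frame of repeat-masked segments (`start`, `end`)
#'   where both libraries collapse to 5% of `mu`.
#' @param baselineContig,baselineLength,baselineMu Baseline (chromosome-1
#'   surrogate) contig used for depth normalisation.
#' @param seed Integer seed.
#' @return A `depthSimSpec` list.
#' @seealso [simulateDepth()]
#' @export
depthSimSpec <- function(contig = "chr2", contigLength = 1e6L, window = 1000L,
                         mu = 40, segments = NULL, maskSegments = NULL,
                         baselineContig = "chr1", baselineLength = 1e6L,
                         baselineMu = 40, seed = 1L) {
    if (is.null(segments))
        segments <- data.frame(start = integer(), end = integer(),
                               fold = numeric())
    if (is.null(maskSegments))
        maskSegments <- data.frame(start = integer(), end = integer())
    stopifnot(all(segments$fold > 0),
              all(segments$end <= contigLength), all(segments$start >= 0))
    structure(list(contig = contig, contigLength = as.integer(contigLength),
                   window = as.integer(window), mu = mu, segments = segments,
                   maskSegments = maskSegments,
                   baselineContig = baselineContig,
                   baselineLength = as.integer(baselineLength),
                   baselineMu = baselineMu, seed = as.integer(seed)),
              class = "depthSimSpec")
}

#' Specification of a simulated three-line RNA-seq experiment
#'
#' @param nGenes Number of genes.
#' @param groups Names of the three lines (focal first by convention).
#' @param replicates Libraries per line.
#' @param baselineMeanlog,baselineSdlog Log-normal parameters of per-gene
#'   baseline expression means.
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param planted Data frame of planted effects: `gene_id`, `family`, one
#'   `fold_<group>` column per group, optional `baseline`.
#' @param librarySdlog Log-normal SD of the per-sample depth (size) factors.
#' @param seed Integer seed.
#' @return A `transcriptomeSimSpec` list.
#' @seealso [simulateCounts()]
#' @export
transcriptomeSimSpec <- function(nGenes = 12000L,
                                 groups = c("focal", "comparator_1",
                                            "comparator_2"),
                                 replicates = 4L,
                                 baselineMeanlog = log(50),
                                 baselineSdlog = 2,
                                 dispersion = 0.01,
                                 planted = NULL,
                                 librarySdlog = 0.15,
                                 seed = 1L) {
    if (is.null(planted))
        planted <- data.frame(gene_id = character(), family = character())
    foldCols <- paste0("fold_", groups)
    for (fc in foldCols)
        if (!fc %in% names(planted)) planted[[fc]] <- rep(1, nrow(planted))
    stopifnot(all(unlist(planted[foldCols]) > 0), dispersion >= 0)
    structure(list(nGenes = as.integer(nGenes), groups = groups,
                   replicates = as.integer(replicates),
                   baselineMeanlog = baselineMeanlog,
                   baselineSdlog = baselineSdlog,
                   dispersion = dispersion, planted = planted,
                   librarySdlog = librarySdlog, seed = as.integer(seed)),
              class = "transcriptomeSimSpec")
}

#' Specification of a simulated mosquito population
#'
#' @param nIndividuals Individuals genotyped.
#' @param freqA,freqB Haplotype frequencies (proportions of individuals
#'   carrying haplotype A or B; `freqA + freqB <= 1`).
#' @param copyRange Two-element range of true copy numbers for amplified
#'   genes; draws are log-uniform over it.
#' @param measurementCV Coefficient of variation of single-mosquito qPCR
#'   measurement noise (multiplicative for amplified genes, Gaussian around
#'   1 for single-copy genes).
#' @param populationId Population label in the output.
#' @param seed Integer seed.
#' @return A `populationSimSpec` list.
#' @seealso [simulatePopulation()]
#' @export
populationSimSpec <- function(nIndividuals = 302L, freqA = 0.1, freqB = 0.2,
                              copyRange = c(3, 80), measurementCV = 0.2,
                              populationId = "simpop", seed = 1L) {
    stopifnot(freqA >= 0, freqB >= 0, freqA + freqB <= 1,
              length(copyRange) == 2L, copyRange[1L] > 0,
              copyRange[2L] >= copyRange[1L], measurementCV >= 0)
    structure(list(nIndividuals = as.integer(nIndividuals), freqA = freqA,
                   freqB = freqB, copyRange = copyRange,
                   measurementCV = measurementCV,
                   populationId = populationId, seed = as.integer(seed)),
              class = "populationSimSpec")
}

## ---------------------------------------------------------------------------
## Generators
## ---------------------------------------------------------------------------

#' Simulate a qPCR Cq table
#'
#' Generates per-replicate Cq values from true relative copy numbers under
#' per-gene amplification efficiencies and Gaussian cycle noise (see
#' [qpcrSimSpec()]). Deterministic for a fixed spec (seed included); at
#' `sigmaCq = 0`, [quantifyCnv()] recovers the generating truths exactly.
#'
#' @param spec A [qpcrSimSpec()] object.
#' @return Data frame with columns `sample_id`, `gene_id`, `gene_role`,
#'   `dye`, `replicate`, `cq`.
#' @export
simulateQpcr <- function(spec) {
    stopifnot(inherits(spec, "qpcrSimSpec"))
    truths <- spec$truths
    cal <- matrix(1, nrow = length(spec$calibrators), ncol = ncol(truths),
                  dimnames = list(spec$calibrators, colnames(truths)))
    truths <- rbind(truths, cal)
    genes <- colnames(truths)
    grid <- expand.grid(replicate = seq_len(spec$replicates),
                        gene_id = genes, sample_id = rownames(truths),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    withSeed(spec$seed, {
        tr <- truths[cbind(grid$sample_id, grid$gene_id)]
        e <- spec$efficiencies[grid$gene_id]
        cq <- spec$baselineCq[grid$gene_id] - log(tr) / log(e) +
            rnorm(nrow(grid), 0, spec$sigmaCq)
        data.frame(sample_id = grid$sample_id, gene_id = grid$gene_id,
                   gene_role = ifelse(grid$gene_id %in% spec$references,
                                      "reference", "target"),
                   dye = "SYBR", replicate = grid$replicate,
                   cq = unname(cq))
    })
}

#' Simulate ddPCR droplet partition counts
#'
#' Partitions template into `nDroplets` droplets; each droplet is positive
#' with probability `1 - exp(-lambdaTrue)` (Poisson zero class), so
#' `nPositive ~ Binomial(nDroplets, 1 - exp(-lambdaTrue))`.
#'
#' @param lambdaTrue True mean copies per droplet (>= 0).
#' @param nDroplets Number of droplets (default 20000, typical of a
#'   nanolitre droplet generator).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return List with elements `nPositive` and `nNegative`.
#' @export
simulateDroplets <- function(lambdaTrue, nDroplets = 20000L, seed = NULL) {
    if (lambdaTrue < 0)
        stop("lambdaTrue must be >= 0", call. = FALSE)
    withSeed(seed, {
        pos <- rbinom(1L, nDroplets, 1 - exp(-lambdaTrue))
        list(nPositive = pos, nNegative = nDroplets - pos)
    })
}

.windowGrid <- function(contigLength, window) {
    starts <- seq.int(0L, contigLength - 1L, by = window)
    ends <- pmin(starts + window, contigLength)
    list(start = starts, end = ends,
         mid = (starts + ends) / 2)
}

.inSegments <- function(mid, segments) {
    if (nrow(segments) == 0L) return(rep(FALSE, length(mid)))
    Reduce(`|`, lapply(seq_len(nrow(segments)), function(i)
        mid >= segments$start[i] & mid < segments$end[i]))
}

#' Simulate case/control pool-seq depth tracks
#'
#' Window depths are Poisson: the control at rate `mu`, the case at
#' `mu * fold` inside planted amplified segments and `mu` elsewhere. Windows
#' whose midpoint falls in a repeat-mask segment collapse to 5% of `mu` in
#' both libraries, emulating unresolved repetitive assembly. A baseline
#' contig without copy-number change is generated for each library for
#' depth normalisation.
#'
#' @param spec A [depthSimSpec()] object.
#' @return List of four [DepthTrack] objects: `case`, `control`,
#'   `caseBaseline`, `controlBaseline`.
#' @export
simulateDepth <- function(spec) {
    stopifnot(inherits(spec, "depthSimSpec"))
    g <- .windowGrid(spec$contigLength, spec$window)
    nb <- .windowGrid(spec$baselineLength, spec$window)
    foldVec <- rep(1, length(g$start))
    for (i in seq_len(nrow(spec$segments))) {
        inSeg <- g$mid >= spec$segments$start[i] & g$mid < spec$segments$end[i]
        foldVec[inSeg] <- spec$segments$fold[i]
    }
    maskVec <- .inSegments(g$mid, spec$maskSegments)
    withSeed(spec$seed, {
        caseMu <- ifelse(maskVec, spec$mu * 0.05, spec$mu * foldVec)
        ctrlMu <- ifelse(maskVec, spec$mu * 0.05, spec$mu)
        list(case = DepthTrack(spec$contig, g$start, g$end,
                               rpois(length(g$start), caseMu)),
             control = DepthTrack(spec$contig, g$start, g$end,
                                  rpois(length(g$start), ctrlMu)),
             caseBaseline = DepthTrack(spec$baselineContig, nb$start, nb$end,
                                       rpois(length(nb$start), spec$baselineMu)),
             controlBaseline = DepthTrack(spec$baselineContig, nb$start, nb$end,
                                          rpois(length(nb$start), spec$baselineMu)))
    })
}

#' Simulate a three-line RNA-seq count matrix
#'
#' Counts are negative binomial with mean `baseline * fold(group) *
#' sizeFactor(sample)` and the spec's dispersion. Planted genes carry the
#' per-group folds given in the spec (baseline 100 unless stated); all other
#' genes have fold 1 everywhere. Per-sample size factors are log-normal,
#' rescaled to geometric mean one.
#'
#' @param spec A [transcriptomeSimSpec()] object.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`, column data `group`/`replicate`, and the planted truth table
#'   in `metadata()$planted`.
#' @export
simulateCounts <- function(spec) {
    stopifnot(inherits(spec, "transcriptomeSimSpec"))
    nSamples <- length(spec$groups) * spec$replicates
    groups <- rep(spec$groups, each = spec$replicates)
    sampleIds <- paste(groups, rep(seq_len(spec$replicates),
                                   times = length(spec$groups)), sep = "_")
    withSeed(spec$seed, {
        geneIds <- sprintf("gene%05d", seq_len(spec$nGenes))
        baseline <- rlnorm(spec$nGenes, spec$baselineMeanlog, spec$baselineSdlog)
        folds <- matrix(1, spec$nGenes, length(spec$groups),
                        dimnames = list(geneIds, spec$groups))
        pl <- spec$planted
        if (nrow(pl)) {
            idx <- seq_len(nrow(pl))
            geneIds[idx] <- pl$gene_id
            rownames(folds) <- geneIds
            baseline[idx] <- if ("baseline" %in% names(pl)) pl$baseline else 100
            for (gr in spec$groups)
                folds[idx, gr] <- pl[[paste0("fold_", gr)]]
        }
        sf <- rlnorm(nSamples, 0, spec$librarySdlog)
        sf <- sf / exp(mean(log(sf)))
        mu <- baseline * folds[, groups, drop = FALSE] *
            rep(sf, each = spec$nGenes)
        counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                                 size = if (spec$dispersion > 0)
                                     1 / spec$dispersion else Inf),
                         nrow = spec$nGenes,
                         dimnames = list(geneIds, sampleIds))
        SummarizedExperiment(assays = list(counts = counts),
                             colData = DataFrame(group = groups,
                                                 replicate = rep(seq_len(spec$replicates),
                                                                 times = length(spec$groups)),
                                                 trueSizeFactor = sf,
                                                 row.names = sampleIds),
                             metadata = list(planted = pl))
    })
}

#' Simulate per-individual CNV profiles for a mosquito population
#'
#' Each individual carries haplotype A with probability `freqA`, haplotype B
#' with probability `freqB`, and no amplification otherwise. Genes amplified
#' under the drawn haplotype (all three cluster genes for A; AAEL019678 and
#' AAEL023844 for B) get true copy numbers drawn log-uniformly over
#' `copyRange`, with multiplicative log-normal measurement noise of the
#' spec's CV; single-copy genes are measured as Gaussian around 1 with the
#' same CV (floored at 0).
#'
#' @param spec A [populationSimSpec()] object.
#' @return Data frame with `individual_id`, `population_id`,
#'   `haplotype_true`, and one fold column per cluster gene.
#' @export
simulatePopulation <- function(spec) {
    stopifnot(inherits(spec, "populationSimSpec"))
    genes <- cceClusterGenes()
    hapGenes <- list(A = genes, B = genes[1:2], none = character())
    withSeed(spec$seed, {
        n <- spec$nIndividuals
        hap <- sample(c("A", "B", "none"), n, replace = TRUE,
                      prob = c(spec$freqA, spec$freqB,
                               1 - spec$freqA - spec$freqB))
        sdlog <- sqrt(log(1 + spec$measurementCV^2))
        folds <- matrix(NA_real_, n, length(genes),
                        dimnames = list(NULL, genes))
        for (i in seq_len(n)) {
            amp <- genes %in% hapGenes[[hap[i]]]
            true <- ifelse(amp,
                           exp(runif(length(genes), log(spec$copyRange[1L]),
                                     log(spec$copyRange[2L]))),
                           1)
            meas <- ifelse(amp,
                           true * rlnorm(length(genes), -sdlog^2 / 2, sdlog),
                           pmax(rnorm(length(genes), 1, spec$measurementCV), 0))
            folds[i, ] <- meas
        }
        out <- data.frame(individual_id = sprintf("ind%03d", seq_len(n)),
                          population_id = spec$populationId,
                          haplotype_true = hap)
        cbind(out, as.data.frame(folds))
    })
}

## ---------------------------------------------------------------------------
## Presets
## ---------------------------------------------------------------------------

#' Named simulation presets with pinned effect sizes
#'
#' Fully specified, seed-pinned simulation scenarios matching the effect
#' sizes of the study system:
#'
#' \describe{
#'   \item{`"g5mala_pool"`}{[qpcrSimSpec()]: seven pools of five females from
#'     the malathion-selected line, duplicate reactions, true folds 32 for
#'     AAEL019678 and AAEL023844 and 8 for AAEL005113, two single-copy
#'     reference genes, E = 2.0, cycle noise SD 0.15, plus three calibrator
#'     pools.}
#'   \item{`"high_copy_individual"`}{[qpcrSimSpec()]: one mosquito at the top
#'     of the observed copy-number range (80 copies of AAEL023844), single
#'     reactions, cycle noise SD 0.2.}
#'   \item{`"nakh_like"`}{[depthSimSpec()]: 1-Mb contig in 1-kb windows at
#'     mean depth 40, one planted 100-kb segment (450-550 kb) at 50-fold,
#'     two 3-kb repeat-mask gaps inside it, and a 1-Mb baseline contig.}
#'   \item{`"mala_transcriptome"`}{[transcriptomeSimSpec()]: 12,000 genes,
#'     3 lines x 4 libraries, planted over-expression in the focal line only
#'     of five clustered CCE genes (10-fold), one microsomal GST (13-fold)
#'     and one P450 (8-fold), plus 20 decoy genes elevated versus a single
#'     comparator line.}
#' }
#'
#' @param name Preset name.
#' @param seed Optional integer overriding the preset's pinned seed.
#' @return A simulation spec object for the matching generator.
#' @examples
#' spec <- simPreset("g5mala_pool")
#' cq <- simulateQpcr(spec)
#' @export
simPreset <- function(name, seed = NULL) {
    cce <- cceClusterGenes()
    refs <- cceReferenceGenes()
    spec <- switch(
        name,
        g5mala_pool = {
            truths <- matrix(rep(c(32, 32, 8, 1, 1), each = 7), nrow = 7,
                             dimnames = list(paste0("G5-Mala-pool-", 1:7),
                                             c(cce, refs)))
            qpcrSimSpec(truths, references = refs,
                        calibrators = paste0("Bora-Bora-pool-", 1:3),
                        sigmaCq = 0.15, replicates = 2L, seed = 1203L)
        },
        high_copy_individual = {
            truths <- matrix(c(80, 1, 1), nrow = 1,
                             dimnames = list("mosq-1",
                                             c("AAEL023844", refs)))
            qpcrSimSpec(truths, references = refs,
                        calibrators = paste0("Bora-Bora-", 1:3),
                        sigmaCq = 0.2, replicates = 1L, seed = 847L)
        },
        nakh_like = depthSimSpec(
            contig = "chr2", contigLength = 1e6L, window = 1000L, mu = 40,
            segments = data.frame(start = 450000L, end = 550000L, fold = 50),
            maskSegments = data.frame(start = c(470000L, 520000L),
                                      end = c(473000L, 523000L)),
            baselineContig = "chr1", baselineLength = 1e6L, baselineMu = 40,
            seed = 4211L),
        mala_transcriptome = {
            cluster5 <- c("AAEL015304", "AAEL019679", "AAEL019678",
                          "AAEL005123", "AAEL023844")
            planted <- data.frame(
                gene_id = c(cluster5, "AAEL006818", "AAEL010158",
                            sprintf("decoy%02d", 1:20)),
                family = c(rep("CCE", 5), "GST", "P450", rep("decoy", 20)),
                fold_focal = c(rep(10, 5), 13, 8, rep(10, 20)),
                fold_comparator_1 = c(rep(1, 7), rep(1, 10), rep(10, 10)),
                fold_comparator_2 = c(rep(1, 7), rep(10, 10), rep(1, 10)))
            transcriptomeSimSpec(nGenes = 12000L, replicates = 4L,
                                 dispersion = 0.01, planted = planted,
                                 seed = 577L)
        },
        stop("unknown preset: '", name, "'", call. = FALSE))
    if (!is.null(seed)) spec$seed <- as.integer(seed)
    spec
}
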