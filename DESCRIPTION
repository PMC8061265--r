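Package: cceamp
Title: Detection and Quantification of Carboxylesterase Gene-Cluster
    Amplification in Aedes aegypti
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and quantifying the genomic amplification of
    a carboxylesterase (CCE) gene cluster that confers organophosphate
    resistance in the mosquito Aedes aegypti. Implements efficiency-corrected
    relative quantification of gene copy number from qPCR (Pfaffl delta-delta-Cq
    with multiple single-copy reference genes and dual-colour TaqMan duplex
    wells), Poisson copy-number estimation from droplet digital PCR partition
    counts, positivity and structural-haplotype classification of individual
    mosquitoes with population-level prevalence summaries, read-depth-ratio
    scanning of case/control coverage tracks to delimit the amplified segment,
    and the RNA-seq candidate-gene filter (median-of-ratios normalisation,
    expression floor, one-way ANOVA with Tukey post hoc tests and
    Benjamini-Hochberg correction, fold-change filter against two susceptible
    comparator lines). Seeded synthetic-data generators with named presets
    reproduce the statistical structure of each assay so the whole pipeline is
    testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: CopyNumberVariation, Coverage, GeneExpression, qPCR,
    DifferentialExpression, Genetics
RoxygenNote: 7.3.3
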