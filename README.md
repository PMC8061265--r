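# cceamp

Detection and quantification of a carboxylesterase (CCE) gene-cluster
amplification conferring organophosphate resistance in the mosquito
*Aedes aegypti*.

Tandem amplification of a CCE cluster on chromosome 2 (including AAEL023844,
formerly CCEAE3A) raises the genomic copy number — and the expression — of
detoxification esterases that sequester and metabolise organophosphate
insecticides such as malathion and temephos. Because the marker is a DNA
copy-number change, it can be scored from single dead specimens of any life
stage, making it a practical surveillance marker for resistance-allele
monitoring. `cceamp` is for molecular entomologists and resistance-monitoring
labs who run these assays, and implements the full analysis chain:

* **qPCR relative quantification** — efficiency-corrected ΔΔCq (Pfaffl):
  `fold = E_t^ΔCq_t / E_r^ΔCq_r`, with standard-curve efficiency fitting
  (`E = 10^(−1/slope)`), multiple single-copy reference genes combined by
  geometric mean, technical replicates averaged on the Cq scale, and
  dual-colour (FAM/HEX) TaqMan duplex wells.
* **Droplet digital PCR** — Poisson occupancy `λ = −ln(negative fraction)`
  per well, Wilson-score confidence intervals, copy number as the
  target/control λ-ratio of sample over calibrator, and cross-platform
  Pearson concordance on log2 folds.
* **Genotyping** — positivity at the inclusive **CNV ≥ 2.5-fold** threshold,
  structural haplotype **A** (all of AAEL019678, AAEL023844, AAEL005113
  amplified) versus **B** (AAEL005113 spared), plus population prevalence and
  haplotype-frequency summaries.
* **Coverage scan** — case/control pool-seq depth tracks normalised by a
  baseline contig, repeat masking (control < 0.25), and amplified-segment
  calling (ratio ≥ 5, masked-gap bridging, median-ratio fold).
* **RNA-seq candidate filter** — median-of-ratios normalisation, expression
  floor ≥ 0.5, one-way ANOVA + Tukey HSD on log2 values,
  Benjamini–Hochberg correction, and the **FC ≥ 3 versus both susceptible
  comparators at corrected p ≤ 0.001** rule.
* **Synthetic data** — seeded generators and presets reproducing the study
  system's effect sizes, so every stage is testable without raw data.

See the methods vignette (`vignettes/cce-amplification-methods.Rmd`) for the
models, defaults and design decisions.

## Worked example

Simulate the malathion-selected-line qPCR experiment (seven pools in
duplicate, two reference genes, three calibrator pools), quantify copy
numbers, and genotype:

```r
library(cceamp)

spec  <- simPreset("g5mala_pool")
cq    <- simulateQpcr(spec)
quant <- quantifyCnv(cq, NULL, spec$calibrators, spec$targets, spec$references)
head(quant, 3)
#>        sample_id    gene_id      fold n_replicates         cv flag
#> 1 G5-Mala-pool-1 AAEL019678 31.627811            2 0.09848412 <NA>
#> 2 G5-Mala-pool-1 AAEL023844 32.005619            2 0.02196787 <NA>
#> 3 G5-Mala-pool-1 AAEL005113  7.200483            2 0.17643128 <NA>
```

The folds are relative gDNA quantities versus the susceptible calibrator
line: this pool carries ~32 copies of the two cluster-proximal CCE genes and
~8 of AAEL005113 (CCEAE1A), the planted truths of the preset. Haplotype
calls and the population summary follow directly (all three genes amplified
⇒ haplotype A; the summary's prevalence counts the calibrator pools too,
which are negative by construction):

```r
calls <- classifyHaplotypes(pivotProfiles(quant))
summarizePopulations(calls)[, 1:8]
#>   population_id  n n_positive prevalence freq_A freq_B freq_other
#> 1           all 10          7         70     70      0          0
```

Mapping the amplified segment from simulated pool-seq coverage of a
resistant population versus the susceptible line:

```r
d  <- simulateDepth(simPreset("nakh_like"))
rt <- ratioTrack(normalizeDepth(d$case,    d$caseBaseline),
                 normalizeDepth(d$control, d$controlBaseline))
callAmplifiedRegions(rt)
#> GRanges object with 1 range and 3 metadata columns:
#>       seqnames        ranges strand |      fold n_windows n_masked_internal
#>   [1]     chr2 450001-550000      * |   49.8268        94                 6
```

One 100-kb region at ~50-fold coverage ratio, spanning 94 analysable
windows and bridging 6 repeat-masked windows — the generator's planted
segment recovered with its two internal repeat gaps.

A thin command-line front end over the same functions is installed at
`inst/scripts/cceamp.R` (subcommands `qpcr`, `ddpcr`, `genotype`, `scan`,
`de-filter`, `simulate`).

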