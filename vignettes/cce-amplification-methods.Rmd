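---
title: "Methods: quantifying a carboxylesterase cluster amplification"
author: "cceamp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying a carboxylesterase cluster amplification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cceamp)
```

# Background and scope

Tandem genomic amplification of a carboxylesterase (CCE) gene cluster on
chromosome 2 of *Aedes aegypti* raises the copy number — and hence the
expression — of detoxification esterases such as AAEL023844 (formerly
CCEAE3A), conferring resistance to organophosphate insecticides. Because the
marker is genomic, it can be scored on dead, dried specimens of any life
stage, which makes copy-number assays attractive for resistance surveillance.

`cceamp` implements the complete analysis chain around this marker:

1. relative copy-number quantification from qPCR Cq values
   (efficiency-corrected ΔΔCq),
2. absolute-free copy-number ratios from droplet digital PCR (Poisson
   occupancy),
3. positivity calling and structural-haplotype assignment per mosquito with
   population summaries,
4. detection of the amplified segment from case/control pool-seq coverage,
5. the RNA-seq filter that nominates resistance-candidate genes, and
6. seeded simulators that generate statistically realistic inputs for every
   stage.

Upstream wet-lab and read-processing steps (primer design, alignment,
duplicate marking, MAPQ filtering, read counting) are out of scope: the
package consumes Cq tables, droplet counts, windowed depth tracks and count
matrices.

# qPCR relative quantification

## Model

For a gene $g$ with amplification efficiency $E_g$ (fold amplification per
cycle, estimated from a dilution series as $E_g = 10^{-1/\text{slope}}$), a
Cq shift $\Delta Cq_g = Cq_g(\text{calibrator}) - Cq_g(\text{sample})$
corresponds to an $E_g^{\Delta Cq_g}$-fold difference in starting template.
The efficiency-corrected relative quantity of a target $t$ versus a
reference $r$ is

$$ \text{fold} = \frac{E_t^{\Delta Cq_t}}{E_r^{\Delta Cq_r}}, $$

the classic $2^{-\Delta\Delta Cq}$ when both assays double perfectly. The
calibrator is the fully susceptible reference line, so fold values read
directly as relative copy numbers.

## Choices that the assay definition leaves open

* **Replicate aggregation** happens on the Cq scale (arithmetic mean of
  technical replicates) before any exponentiation — the standard ΔΔCq
  practice, and the scale on which qPCR noise is approximately Gaussian.
* **Two reference genes** (the single-copy genes AAEL007808 and AAEL005950)
  are combined by the geometric mean of per-reference folds, the standard
  multi-reference normalisation.
* **Undetermined wells.** Undetermined replicates are dropped; a target gene
  with no determined Cq in a non-calibrator sample means "no target
  amplification" and is reported as fold 0 with a flag rather than an error.
  A sample with no usable reference gene cannot be normalised and is skipped
  with a warning.
* **Efficiency defaults.** Without a standard curve the pipeline assumes
  $E = 2.0$ and says so with a message. Fitted efficiencies outside
  $(1, 2.2]$ are rejected: below 1 is physically meaningless, slightly above
  2 (apparent efficiency >100%) is tolerated as usual for inhibitor-related
  artefacts.
* **Raw traces.** `callCq()` supports raw amplification-curve exports:
  baseline mean over cycles 3–15 is subtracted and the automatic threshold
  is baseline mean + 10 baseline SDs, with the crossing cycle interpolated
  linearly.

The dual-colour TaqMan duplex path (`duplexQuantify()`) is the same Pfaffl
computation with the target read on FAM and the control on HEX in one well;
an undetermined HEX probe means the well failed (no DNA), whereas an
undetermined FAM probe with a healthy HEX signal is a genuine negative.

# Droplet digital PCR

With template partitioned into $n \approx 20{,}000$ droplets, copies per
droplet are Poisson with mean $\lambda$ and the negative fraction estimates
the zero class: $\hat\lambda = -\ln(n_{neg}/n)$. Confidence intervals
transform a Wilson score interval on the negative fraction through $-\ln$;
the Wilson form behaves well at the extreme fractions seen in nearly empty
or nearly saturated wells. Copy number is the doubly normalised ratio

$$ \text{fold} = \frac{(\hat\lambda_t/\hat\lambda_c)_{\text{sample}}}
                      {(\hat\lambda_t/\hat\lambda_c)_{\text{calibrator}}}, $$

which cancels the loaded gDNA mass, so droplet volume never enters.
Saturated wells ($n_{neg}=0$) are an error ("too concentrated to
quantify"), not an infinite estimate.

Cross-platform agreement (`platformConcordance()`) is a Pearson correlation
computed on log2 folds: copy numbers span 3–80, and on the raw scale the
correlation would be dominated by the few highest-copy individuals.

# Positivity and structural haplotypes

An individual is **positive** when any of the three assayed cluster genes
(AAEL019678, AAEL023844, AAEL005113) reaches 2.5-fold relative to the
susceptible line — an inclusive threshold chosen above the <2-fold
technical variation of single-mosquito qPCR. Haplotype **A** amplifies all
three genes; haplotype **B** spares AAEL005113 (CCEAE1A). Patterns that fit
neither named haplotype (e.g. AAEL023844 alone) are reported as **other**
rather than forced into A/B, since additional structural variants plausibly
segregate. Partial profiles stay callable for positivity but get an
"other" haplotype with a `partial-profile` flag.

Population summaries report haplotype frequencies both as a percentage of
all genotyped individuals (summing to the prevalence) and as a share of
positive individuals, because both framings are in common use and they
differ by a factor of the prevalence.

# Coverage-based amplification mapping

Each library's windowed depth is divided by the mean window depth of a
baseline contig carrying no copy-number change (a chromosome-1 surrogate),
which removes sequencing-depth differences; the per-window case/control
ratio then reads as relative copy number. Windows whose normalized control
depth falls below 0.25 are masked: in such repeat-dominated windows the
ratio is noise. The segment caller takes maximal runs of unmasked windows
with ratio ≥ 5, bridges interruptions of up to 10 consecutive masked
windows (repeat gaps inside the amplification), discards runs under 5
windows, and reports the median window ratio of each region as its fold.

Numerical choices: 1-kb windows resolve a ~100-kb segment at 1%
granularity; the fold floor of 5 sits far below a ~50-fold amplification but
above pooled heterozygous copy-number noise; the arithmetic mean (not
median) defines baseline "average coverage"; the median defines region
fold, robust to residual repeat windows. Coordinates are 0-based half-open
internally and in BED output.

# RNA-seq candidate filter

Counts are normalised with median-of-ratios size factors (rescaled to
geometric mean 1), genes below a normalized level of 0.5 in any library are
removed, and each remaining gene is tested with a one-way ANOVA across the
focal (resistant) line and two susceptible comparator lines on
$\log_2(\text{normalized}+1)$ values — the transform stabilises the
variance that ANOVA assumes homogeneous — followed by Tukey HSD post hoc
tests for the focal line against each comparator. Benjamini–Hochberg
correction is applied across genes separately within each pairwise
comparison (default); a gene is a candidate when its linear fold change is
≥3 in the same direction against *both* comparators with both corrected
p ≤ 0.001. Requiring both comparators suppresses genes that merely drifted
in one susceptible line.

The correction ordering is genuinely ambiguous in common practice, so the
alternative (BH on the ANOVA p across genes, Tukey uncorrected) is
available via `correction = "anova-bh"`. Zero-variance genes get p = 1 when
group means agree and the smallest representable p with an
`exact-separation` flag when they differ. The per-gene ANOVA/Tukey
machinery is vectorised (closed-form sums of squares and `ptukey`), and its
agreement with `aov()`/`TukeyHSD()` is asserted in the test suite.

# Synthetic data: what it emulates, and what it does not

All generators are pure functions of their spec (seed included) and restore
the caller's RNG state.

* `simulateQpcr()` inverts the ΔΔCq model exactly:
  $Cq = \text{baseline}_g - \log(\text{truth})/\log(E_g) + N(0, \sigma)$.
  At $\sigma = 0$ the pipeline recovers truths to machine precision — the
  round-trip identity used in the acceptance tests.
* `simulateDroplets()` draws the positive count binomially from the Poisson
  zero-class probability.
* `simulateDepth()` uses Poisson window depths (pooled libraries at 1-kb
  windows are near-Poisson, and this keeps the oracle analytic), with
  repeat-mask segments collapsing both libraries to 5% of the control mean.
* `simulateCounts()` draws negative-binomial counts around log-normal
  baseline means with per-sample library factors.
* `simulatePopulation()` draws haplotypes from the specified frequencies,
  log-uniform copy numbers over 3–80 for amplified genes (the wide observed
  range, with no assumed mode) and 20% multiplicative measurement noise —
  chosen so that single-copy genes stay comfortably below the 2.5-fold
  threshold, consistent with the <2-fold variation seen in negative
  controls.

The presets pin the study's effect sizes: `g5mala_pool` (7 pools in
duplicate; truths 32/32/8-fold; σ = 0.15 cycles), `high_copy_individual`
(one mosquito at 80 copies, single reactions, σ = 0.2),
`nakh_like` (100-kb segment at 50-fold in a 1-Mb contig, mean depth 40, two
3-kb internal repeat gaps) and `mala_transcriptome` (12,000 genes, 3 lines
× 4 libraries; five cluster CCEs at 10-fold, one GST at 13-fold, one P450
at 8-fold in the focal line only, 20 one-comparator decoys; NB dispersion
0.01, appropriate for libraries prepared from pools of 25 females).

What passing tests on these simulations do **not** show: robustness to
qPCR inhibition and efficiency drift between plates, droplet rain and
misclassified droplets, GC- and mappability-driven depth waves,
overdispersed pool-seq depth, or RNA-seq batch effects. The generators are
deliberately faithful to the *models the methods assume*, so recovery tests
validate the implementations, not the assays' field robustness.

# Problem sizes and determinism

The test suite and the acceptance script run at the preset scales above
(1,000 windows per contig; 12,000 genes; ≤ 2 × 10⁶ droplets; populations of
50–302 individuals), each completing in seconds on one CPU. Stochastic
recovery checks fix their seeds; where a single simulated estimate is
intrinsically noisy (single-mosquito qPCR at 80 copies has ~20% CV), the
acceptance script averages replicate simulations on the log scale — the
scale on which qPCR noise is symmetric and on which copy-number data are
routinely analysed — and reports the problem size it used.

# Known limitations

* Haplotype assignment is pattern-based on three genes; it cannot separate
  compound heterozygotes (A/B in one individual) from haplotype A, and
  "other" patterns are not resolved further without junction PCR.
* The ΔΔCq pipeline requires calibrator samples on each run; no historical
  fixed calibrator Cq is supported.
* The segment caller reports window-resolution boundaries; it is not a
  breakpoint caller.
* ddPCR quantification assumes ideal droplet classification and equal
  droplet volumes.
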