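---
title: "Methods: expression divergence between electric organ and skeletal muscle"
author: "electroase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression divergence between electric organ and skeletal muscle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(electroase)
```

## The biological setting

Mormyrid electric fish generate an electric organ discharge (EOD) with a
myogenic electric organ (EO) derived from skeletal muscle (SM). Within the
genus studied here, EOD duration spans two orders of magnitude (0.4 ms to
40 ms) across closely related species, and F1 hybrids between a
short-discharge and a long-discharge species produce discharges of
intermediate duration. This package implements the three statistical
analyses such a design supports:

1. **Tissue contrast per cohort.** Which genes are differentially expressed
   between EO and SM within each species or hybrid cohort, and which of
   those differences are shared by every cohort (candidate EO-specific
   genes)?
2. **Duration association.** Which genes change their EO expression
   systematically as EOD duration increases across the purebred species?
3. **Allele-specific expression.** In F1 hybrids, at SNPs where the two
   parental species are fixed for different alleles, is one parental allele
   expressed more than the other (allelic expression imbalance, AEI — the
   signature of *cis*-regulatory divergence)?

## Models and procedures

### Negative-binomial differential expression

Counts for gene $g$ in sample $j$ are modelled as
$y_{gj} \sim \mathrm{NB}(\mu_{gj},\ \alpha_g)$ with
$\mathrm{Var}(y) = \mu + \alpha\mu^2$ and
$\log \mu_{gj} = x_j^\top\beta_g + \log s_j$, where $s_j$ is a per-sample
size factor. The components are:

* **Size factors** (`estimate_size_factors()`): median-of-ratios against the
  per-gene geometric mean, over genes with no zero count, rescaled to
  geometric mean 1. This matches the behaviour of the widely used
  median-of-ratios implementations (a unit test cross-checks against
  DESeq2's on simulated data).
* **Dispersions** (`estimate_dispersions()`): per-gene method-of-moments on
  normalized counts within replicate groups (cohort × tissue cells), pooled
  by residual degrees of freedom, floored at $10^{-8}$, then averaged
  half-and-half with a parametric mean–dispersion trend
  $\alpha(\mu) = a_0 + a_1/\mu$ fitted by an iteratively trimmed gamma GLM.
  The half-weight average tempers the noise of the per-gene moment
  estimates at the 3–5 replicates typical of this design; the adequacy of
  this choice is gated by the calibration tests below, not assumed.
* **Wald test** (`wald_test_tissue()`): per cohort, an NB log-link GLM with
  intercept and tissue indicator (SM as reference), size factors as offsets
  and the gene's estimated dispersion held fixed; the tissue coefficient is
  tested against a standard normal. P-values are Benjamini–Hochberg
  adjusted within the cohort.
* **DEG rule** (`call_degs()`): $|\log_2\mathrm{FC}| > 1$ and adjusted
  $p < 0.05$, both strict. A raw-p mode is available
  (`use_adjusted = FALSE`) because the two conventions are both seen in
  practice; the adjusted default is the defensible one for genome-wide
  calling. Genes whose IRLS fit fails to converge are flagged and excluded
  from calls but never dropped from the output table.
* **Shared DEGs** (`shared_degs()`): set intersection of the up- and
  downregulated calls separately across all cohorts.

Calibration, measured by the test suite and `scripts/acceptance.R` on
generator output: on 10,000 null genes (5 vs 5, dispersion 0.05) the
fraction of raw $p < 0.05$ is required to fall in $[0.035, 0.065]$, and
planted two-fold effects at mean $\ge 100$ must be recovered with
sensitivity $\ge 0.9$ at a false-positive rate $\le 0.01$. The plug-in
dispersion makes the test mildly liberal (typically 0.055–0.060 at nominal
0.05); this is inherent to fixed-dispersion Wald testing at these replicate
numbers and stays within the accepted band.

### Duration-association LRT and pattern clustering

The interaction test (`lrt_interaction()`) compares, per gene, the full
model `~ duration + tissue + duration:tissue` with the reduced model
`~ duration + tissue` on the purebred cohorts only (hybrid samples are
rejected: their intermediate discharge would blur the duration axis). Both
models share the gene's dispersion, estimated once under the full design,
which makes the deviance difference a valid non-negative likelihood-ratio
statistic; it is referred to $\chi^2$ with the rank difference of the two
designs as degrees of freedom, and BH-adjusted across genes.

Duration enters as a factor ordered by duration (three levels, hence a 2-df
test) rather than as a continuous covariate. The clustering step treats
duration as an ordered grouping, and a factor makes the LRT sensitive to
any interaction shape instead of only linear-in-log-duration ones; a
continuous log10(ms) mode (`duration_as_factor = FALSE`, 1 df) is provided
for users who prefer the parametric reading.

Significant genes (adjusted $p < 0.05$) are clustered
(`cluster_patterns()`) on standardized profiles: the z-score, across the
six duration × tissue design cells, of the mean normalized
$\log_2(x + 1)$ expression. Distance is $1 - r$ (Pearson), linkage is
average, and the tree is cut at height $1 - 0.7$. Under average linkage
every merge inside a retained group occurred at mean cross-correlation
$\ge 0.7$, so the cut guarantees a within-group mean pairwise correlation
of at least 0.7. An earlier design that searched for the smallest number
of groups satisfying that same correlation bound was rejected: the bound is
reached *before* groups become pattern-pure, because genes with opposite
duration trends still correlate strongly through the shared EO-vs-SM
contrast. Groups smaller than `min_group_size = 3` are reattached to the
large group their members correlate best with (mean cross-correlation
$\ge 0.5$), mirroring how degPatterns-style clustering consolidates
stragglers; unmatched small groups stay separate. Exact group numbering is
arbitrary (groups are relabelled by size) and no attempt is made to
reproduce any particular published group indexing.

Selection (`select_duration_groups()`) applies the two study criteria to
each group's mean profile: EO above SM at every duration, and strictly
monotone EO expression across durations; the monotone sense labels member
genes `increasing` or `decreasing`. The criteria act on groups, not on
individual genes — a deliberately group-level reading, since single-gene
profiles at 3–5 replicates are too noisy to call monotonicity gene by gene.

### Allele-specific expression

The ASE stage consumes a multi-sample VCF called against CDS/transcript
coordinates, so `CHROM` is the gene identifier. The filter chain is:

1. `filter_biallelic()`: exactly one ALT, single-nucleotide REF and ALT,
   at least one called genotype (the `--exclude-uncalled -m2 -M2` step).
2. `filter_quality()`: site `QUAL >= 70` (strict below), then a per-hybrid
   depth screen at 10 reads. The phrase "allelic depth below 10 in both
   alleles" is ambiguous; the default requires **each** allele to reach
   depth 10 in an evaluated individual, because a proportion estimated
   from an allele observed fewer than 10 times is not meaningful. The
   literal both-below reading is available as `depth_rule = "both"`.
   Depth is screened per hybrid individual rather than site-wide so one
   shallow library does not discard a site for everyone; parents
   contribute genotypes only.
3. `identify_fixed_snps()`: every parent-A sample homozygous for one
   allele, every parent-B sample homozygous for the other, no missing
   parental genotypes (missingness is never imputed). The parent-A (com)
   allele is recorded whether it is REF or ALT, making all downstream
   quantities invariant to REF/ALT orientation.

Per gene and hybrid individual, `allelic_proportions()` computes the
com-allele proportion at each SNP and averages SNPs *within* the
individual by unweighted mean (depth-weighted pooling is available but not
the default); `classify_aei()` then averages individuals, attaches a
Student-t 95% confidence interval across individuals (biological
replicates), and applies two imbalance rules side by side: the headline
mean rule (mean strictly outside $[0.4, 0.6]$) and the stricter
all-individuals rule (every individual above 0.6 for the same parental
allele). Both are reported because both conventions exist; users filtering
on the all-individuals rule get the more conservative call set.

`compare_protein_alleles()` translates two in-frame CDS alleles with the
standard genetic code and reports non-synonymous positions, for following
up AEI genes whose parental alleles may also differ at the protein level.

## The synthetic-data generator

`simulate_experiment()` and `simulate_allelic_reads()` emulate the study
conditions end to end; the defaults in `sim_config()` are fixed to the
design the pipeline targets and are not tuning knobs:

* Cohorts: three purebred species at 0.4 / 5 / 40 ms with 5 / 3 / 5
  replicates, and two hybrid cohorts (5 replicates; 0.4 and 4 ms), each in
  both tissues — 46 samples.
* Counts: NB with per-gene baselines $\log_2$-normal around
  $\log_2 500$ (sd 1.5), dispersion 0.05, log-normal library size factors
  (sd 0.15). A fraction 0.1 of genes carries a ±2 log2 tissue effect; a
  fraction 0.05 carries an EO-specific duration slope of 1 log2 per log10
  ms plus an EO offset of 2.5 log2 units. The offset must exceed 2 so
  that decreasing genes keep EO above SM over the 100-fold duration range
  (the slope spans 2 log2 units); 2.5 leaves a half-unit margin while
  staying well inside the effect sizes reported for EO-specific channel
  genes.
* Allelic reads: for each AEI gene (default true com proportions 0.16,
  0.2, 0.8, 0.86 — the magnitudes reported for imbalanced channel genes —
  plus balanced 0.5 background genes), three fixed parental SNPs with the
  com allele randomly REF or ALT, parent reads all on the parental allele,
  hybrid com reads Binomial(Poisson(100) depth, p). A 20% decoy fraction
  (triallelic, indel, low-QUAL, low-depth, non-fixed sites) keeps the
  filter code paths honest.
* Determinism: one seed governs everything; per-gene substreams are derived
  from it, so adding genes to a configuration does not change the truth
  assignment of existing genes, and identical configurations yield
  byte-identical fixtures.

What the generator does *not* emulate: mapping bias at SNPs,
genotyping error, positional read-level structure, GC or length effects,
correlated genes, and outlier samples. Passing the recovery tests
therefore demonstrates that the estimators and filters implement their
definitions correctly under the assumed NB/binomial noise — not that real
libraries meet those assumptions.

## Numerical choices and degenerate inputs

* Dispersion floor $10^{-8}$; IRLS capped at 50 iterations; non-converged
  genes flagged with missing p-values and excluded from calls.
* LRT statistics clamped at 0 against rounding (shared dispersion makes
  them analytically non-negative).
* All thresholds are strict inequalities (`> 1`, `< 0.05`, `< 0.4`,
  `> 0.6`), matching the stated rules; boundary values are never called.
* Genes constant across all samples sit at the dispersion floor; genes
  all-zero in a cohort are flagged as non-converged rather than assigned a
  fold change.
* A gene observed in a single hybrid individual gets a missing confidence
  interval but is still reported.
* Zero-depth SNP-individual pairs are skipped, not treated as proportion 0.

## Problem sizes

The shipped checks run at desk scale, chosen to bound each quantity's
Monte-Carlo error well inside its acceptance band: 10,000 null genes for
Wald calibration, 5,000 + 500 for LRT calibration and power, 2,000 genes
for DE and duration-direction recovery, 300 genes for template clustering,
and 2,500 gene-replicates (500 per true proportion) at 3 SNPs × depth
100 × 5 individuals for AEI recovery. `scripts/acceptance.R` recomputes
all of them from scratch at any seed.

## Known limitations

* The Wald test's plug-in dispersion is mildly liberal at 3–5 replicates;
  analyses needing exact type-I control should prefer the LRT or larger
  designs.
* The clustering cut is correlation-based and scale-free; patterns that
  differ only in amplitude are merged by construction.
* Allelic counts are modelled binomially; extra-binomial variation across
  individuals is captured only through the across-individual confidence
  interval, not by a beta-binomial likelihood.
* Gene naming, annotation, GO enrichment and variant calling itself are
  out of scope: the pipeline starts at count matrices and called VCFs.
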