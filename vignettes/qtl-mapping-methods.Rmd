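---
title: "Mapping polygenic QTLs from pooled and individual segregants: models and design choices"
author: "bsaqtl"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`bsaqtl` implements the two complementary statistical engines used to map
quantitative trait loci (QTLs) in a haploid yeast cross between a *superior*
parent (carrying the trait, e.g. high acetic-acid tolerance) and an
*inferior* parent:

1. **Pooled-segregant (bulk segregant) mapping** — sequence a pool of
   phenotype-selected segregants and look for genomic regions where the
   frequency of the superior parent's SNP alleles deviates from the
   Mendelian expectation of 0.5.
2. **Individual-segregant parent-of-origin mapping** — sequence each
   selected segregant separately, assign every SNP to the parent whose
   genotype distribution it most resembles (by Kullback–Leibler divergence),
   reduce each genome to a ternary {+1, −1, 0} track, and average tracks
   over the phenotypically most extreme segregants.

A forward simulator of meiosis, multi-round random-spore inbreeding,
polygenic phenotypes, truncation selection and short-read allele counts
provides ground truth against which both engines are validated. The
simulator is first-class, tested code: its outputs are the package's test
bed, and its defaults mirror the experimental design the engines were built
for (288 F1 segregants screened, the best 27 pooled; six rounds of
inbreeding to an F7 generation; unselected 27-segregant control pools;
~1 SNP per 518 bp, the genome-wide density of a cross with ~23,150 SNPs
over 12 Mb).

# The simulator

## Meiosis

Each chromosome is a haplotype mosaic: alternating blocks labelled by
parent-of-origin. One meiosis draws, per chromosome, a crossover count from
a Poisson law with mean $2L$ where $L$ is the chromosome's map length in
Morgans (the factor 2 is per bivalent), with crossover positions uniform in
physical coordinates — the standard no-interference count-location model.
Each of the two complementary spore pairs receives each crossover
independently with probability 1/2. Consequences the tests assert:

* each gamete sees Poisson($L$) crossovers, matching the genetic map;
* a tetrad segregates exactly 2:2 at every locus of a heterozygous diploid;
* spores 1/2 and 3/4 are complementary pairs.

The default map density is 0.35 cM/kb, typical for *S. cerevisiae*; it is a
configuration field, not a constant, because the effective map of any
particular cross is rarely known. Crossover interference is not modelled.

## Inbreeding

`inbreed()` emulates random-spore mass mating: every diploid is sporulated,
all spores are pooled, and new diploids are formed by uniform random
pairing. Mating type is abstracted away (the protocol randomises mating;
modelling *MAT* compatibility would halve the pair space without changing
the statistics of block shortening), and sister-spore pairings are not
excluded — at population sizes of hundreds their effect is negligible.
`rounds = 0` returns F1 segregants; `rounds = 6` an F7 population. The
tested consequence is that mean parental block length decreases strictly
with rounds, which is what makes F7 intervals narrower than F1 intervals.

Note one deliberate property: populations produced by `inbreed()` consist
of complete tetrads, so an *entire* F1 population segregates exactly 1:1 at
every marker. Statistical null studies that need independent genomes (see
*Null calibration* below) therefore draw one spore per complementary pair
instead of taking whole tetrads.

## Phenotype and selection

Phenotypes are `baseline + genetic value + N(0, noise_sd)`. Under the
`additive` architecture each causal locus adds its effect when the
segregant carries the superior allele. Under `redundant`, loci in a
declared group contribute the *maximum* of their member contributions —
two interchangeable causal genes (the situation of a paralog able to take
over a transcription factor's function). `select_top()` performs truncation
selection with stable tie-breaking by original order; the tie rule is
documented because pool membership changes every downstream map.

## Sequencing

Depth per marker is negative-binomial around the configured mean (variance
$\mu + \phi\mu^2$; $\phi = 0$ gives Poisson), each read samples a pool
segregant uniformly and reports its allele flipped with the per-base error
rate, and mean PHRED qualities are Gaussian, truncated to [2, 41]. No raw
reads, alignment or base-caller artefacts are emulated; the engines ingest
allele depths, so the simulator produces exactly that.

All randomness flows from one root seed through named substreams
(`stage_seed(seed, stage)`), so e.g. re-sequencing with a different depth
leaves the meioses untouched.

# Pooled-segregant engine

The SNP variant frequency at a marker is the superior-allele read fraction,
masked below 15 reads coverage or below PHRED 35 (inclusive thresholds).
The genome-wide frequency series is smoothed by kernel-weighted local
binomial estimation: at each covered marker, neighbouring superior/total
read counts are combined with Gaussian weights in physical distance
(default bandwidth 20 kb, truncated at 4 bandwidths), and the estimate and
its normal-approximation confidence band are formed on the logit scale with
a half-read continuity correction. A cited smoothing-spline GLMM could fill
the same role; the local-binomial smoother was chosen because it reproduces
exactly what downstream calling consumes — a trend plus a pointwise band
against 0.5 — with one interpretable parameter.

**Pool-size-aware bands.** Read depth alone overstates precision: a pool of
27 segregants carries at most 27 independent genomes at any locus, and this
composition noise (standard deviation $\sqrt{p(1-p)/27} \approx 0.1$) is
*shared* by all linked markers, so smoothing across markers cannot average
it away. When the pool size is supplied, the effective sample size is
capped harmonically, $1/n_\mathrm{eff} \leftarrow 1/n_\mathrm{eff} + 1/n_\mathrm{pool}$.
Without the cap, unselected control pools produce abundant spurious
deviation calls whose subtraction can excise true signal; with it, the
recovery studies below reach their targets.

Intervals are maximal marker runs whose band lies entirely above (superior
linkage) or below (inferior linkage) 0.5 — boundaries are marker-anchored
because mapping reports quote marker coordinates. Coordinates are 1-based
inclusive internally; BED export converts to 0-based half-open. Linkage in
an unselected control pool of the same size, mapped identically, is
subtracted interval-wise (same-direction overlap only) to remove loci
enriched by the breeding protocol rather than the trait.

Individually scored SNPs are tested with the exact two-sided binomial test
(`k` superior carriers of `n` scored segregants against 1/2; the two-sided
p-value sums all outcomes no likelier than the observed one). No multiple-
testing correction is applied by default — per-SNP p-values are reported
raw against the conventional 0.05 line, with Benjamini–Hochberg available —
and zero-coverage markers are excluded rather than imputed.

# Individual-segregant engine

Allele counts become genotype distributions with a pseudocount:
$p = (k + \alpha)/(n + 2\alpha)$, $\alpha = 1$ by default. The pseudocount
is load-bearing: parental samples are near-monoallelic, and raw KL
divergences to a degenerate distribution are infinite. For each SNP of each
segregant we compute $D(\mathrm{seg}\,\|\,\mathrm{parent})$ to both parents
and assign the SNP to the nearer parent; the signed score is
$D_\mathrm{inf} - D_\mathrm{sup}$ (positive = superior). Equal divergences
(within $10^{-12}$, absorbing floating-point asymmetry of the two sums) are
undetermined.

Assignment confidence is the exact binomial tail probability of the
observed reads of the assigned allele under the *non-assigned* parent's
pseudocounted distribution — the rival parent's own genotype distribution
serves as its error model, so deeper or cleaner parental sequencing
automatically sharpens the null. These p-values are Benjamini–Hochberg
corrected *within each segregant* (the conservative q = 0.007 default
reflects correcting across ~28 samples analysed in parallel), and failing
assignments are zeroed. The step-up rule is inclusive: an adjusted p-value
exactly at q survives.

Scores are smoothed along each chromosome with a Gaussian kernel over
physical positions (row-normalised, truncated at 4σ; σ defaults to 1 kb
and results are stable for σ in 0.5–2 kb), correcting isolated
error-driven spikes. Non-overlapping 3-kb windows anchored at position 1
then sum the smoothed scores of their SNPs: positive sum → +1, negative →
−1, empty or zero → 0. A sliding stride equal to the window width (tiling)
is the default because the output is one ternary call per locus; the
minimum-evidence threshold τ defaults to 0 (the sign decides). Smoothing
followed by window summation *is* the distance-based segmentation — no
separate change-point algorithm is used.

Finally the ternary tracks of the k top-ranked segregants (by phenotype)
are averaged per window, and maximal window runs strictly above +0.7 or
strictly below −0.7 are reported as QTL intervals ("above" is read as
strict; a window at exactly 0.7 is not called). Averaging depth k is the
analyst's resolution dial: small k (e.g. 9, the most extreme tail)
resolves the allele combinations of the best segregants and is the setting
under which redundant-architecture linkage shifts become visible; large k
approaches the pooled picture.

# Validation studies and the problem sizes used

The studies in `R/validate.R` (run by both the test suite and
`scripts/acceptance.R`) use a 3-chromosome, 1.5-Mb scale-down at full
marker density (2,900 markers ≈ 1/518 bp), chosen so that forty-replicate
studies complete in about a minute while selection intensity (27/288),
depth (50×) and density match the full design:

* **Recovery** — one full-penetrance causal locus (effect 1, noise SD 0.1),
  288 F1, top 27: the pooled interval must contain the causal position in
  ≥95% of 40 replicates, and both engines jointly in ≥90%.
* **Narrowing** — the same specification mapped at rounds 0 vs 6: median
  causal-interval width must shrink (observed: roughly 270–300 kb → 70–100
  kb at this scale).
* **Network shift** — a redundant two-locus phenotype on different
  chromosomes, individual engine averaged over k = 9: in 20 replicates at
  least one must call exactly one group member at ±0.7.
* **Null calibration** — panels of 40 markers scattered over a
  16-chromosome 12-Mb genome (neighbouring panel markers ~100 cM apart,
  hence effectively unlinked), 300 independent spores scored per replicate,
  25 replicates: the exact test's rejection fraction at p < 0.05 must sit
  within 3 binomial standard errors of 0.05. Unlinked markers and
  independent spores are both essential: linked markers share segregant-
  sampling noise (invalidating the naive standard error), and complete
  tetrads segregate exactly 2:2 (rejection rate 0). The analytic level of
  the discrete exact test at n = 300 is 0.043, not 0.05 — the band must and
  does absorb that.

# What the synthetic data does not show

The simulator emulates the statistical structure the engines assume — it
cannot certify performance on real sequencing. Not modelled: alignment and
mapping bias, copy-number and structural variation, segmental aneuploidy
arising during inbreeding, non-uniform recombination (hot/cold spots) and
crossover interference, correlated base errors, batch effects between
sequencing runs, and phenotyping error beyond Gaussian noise. Passing
recovery studies therefore demonstrates correctness of the computation and
adequacy of the statistics under the stated model, not robustness to every
artefact of real data. The engines themselves ingest real allele-depth
tables (TSV or VCF) unchanged.

# Degenerate inputs and numerical conventions

* Markers with zero post-filter coverage are excluded from smoothing and
  frequency series (`NA`), never imputed.
* A chromosome with a single covered marker yields that marker's frequency
  with its exact binomial-based band.
* Constant frequency input returns a constant fit (the continuity
  correction is symmetric).
* Zero-coverage genotype distributions are the uniform distribution and are
  filtered by the coverage threshold upstream.
* Empty windows are undetermined (0), and an all-zero averaged track calls
  nothing.
* Interval subtraction drops empty remnants; a peak falling in an excised
  portion becomes `NA` rather than being re-estimated.

# Known limitations

The pooled band is a pointwise normal approximation on the logit scale;
genome-wide error control across thousands of correlated windows is not
attempted (the unselected-pool subtraction is the practical guard, as in
the underlying experimental design). The KL assignment treats segregants
as haploid at every SNP — heterozygous or aneuploid states are out of
scope. The redundant architecture implements max-redundancy only;
epistasis beyond it is not modelled.
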