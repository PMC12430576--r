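---
title: "Mapping a fiber-strength locus by bulked-segregant SNP-index analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a fiber-strength locus by bulked-segregant SNP-index analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the methods behind `bulkseg`: the statistical model
of the scan, the design of the synthetic population generator that backs the
test suite, and the numerical choices that make both reproducible.

## 1. The mapping design

The experiment modeled here is an advanced-backcross introgression study: a
donor parent is crossed into a recurrent (elite) parent, backcrossed for six
generations, and selfed once, producing BC₆F₂ families in which short donor
chromosome segments segregate on an otherwise recurrent background. Families
with extreme fiber strength form two bulks — a superior bulk HC1 (20
families) and an inferior bulk HC2 (12 families) — which are pool-sequenced
together with both parents.

At every SNP where the parents are opposite homozygotes, the **SNP-index** of
a bulk is the fraction of its reads carrying the donor allele, and

$$\Delta(\text{SNP-index}) = \text{index}_{HC1} - \text{index}_{HC2}.$$

Away from any trait locus both bulks are random draws from the population, so
$\Delta \approx 0$; near a locus whose donor allele increases fiber strength,
the superior bulk is enriched for donor reads and $\Delta > 0$.

## 2. Locus filters, windows, and the null envelope

Three per-site filters are applied before scanning, with one primary reason
recorded per failing site (`low_index_both` > `low_depth` >
`missing_in_pool`):

* SNP-index below 0.5 in **both** pools — in this design a site fixed for the
  recurrent allele in both bulks carries no contrast. An index below 0.5 in
  only one pool is exactly the association signal sought and is never
  filtered.
* Read depth below 5 in **either** pool — a single shallow pool already makes
  the site's contrast unreliable.
* Site missing (zero depth) in either pool. Zero-depth SNP-index is `NA`,
  never 0.

Pass-filter sites are averaged in 1 Mb windows sliding by 100 kb (windows
with fewer than 10 sites are not scored). Significance comes from a
depth-stratified simulated null: for each distinct (rounded) pair of window
mean depths, 10,000 replicates draw each bulk's allele frequency as
$\mathrm{Bin}(2n, 0.5)/2n$ over its $2n$ chromosomes ($n = 20$ and $12$) and
then reads as $\mathrm{Bin}(\text{depth}, f)$; the empirical nearest-rank
quantiles at 95% and 99% form the envelope. Windows whose mean $\Delta$
exceeds the one-sided 99% envelope merge (gap of at most one step) into
candidate regions; the region span is `end − start` in bp. A site-wise
label-permutation envelope is available as an alternative null.

Two numerical points are worth recording. First, the null distribution of
site-level $\Delta$ at small depths lives on a coarse lattice (multiples of
$1/d_1$ minus multiples of $1/d_2$), so empirical quantiles can flip by one
lattice step when the exact CDF passes close to the target probability; the
test suite therefore validates the sampler against an exhaustive enumeration
of the exact law by Kolmogorov distance (≤ 0.02 at 10,000 replicates) and
only compares quantiles directly where the exact CDF brackets the target with
a wide margin. Second, window means are computed with cumulative sums over
the sorted site list, so the scan is $O(\text{sites} + \text{windows})$ per
chromosome.

## 3. The synthetic population generator

The generator exists so that calibration (no QTL ⇒ few or no significant
windows) and power (one planted QTL ⇒ the region is recovered) can be
measured against known truth.

**Genome.** Four chromosomes of 25 Mb at 1 Morgan each, SNPs every 50 kb
(2,000 informative sites). The chromosome count, family count, bulk sizes and
depths follow the modeled study; the physical/genetic lengths and SNP density
are the package's own choices, set so that a full run takes a few seconds.

**Meiosis.** Haldane model: crossover count per chromosome is Poisson with
mean equal to the map length in Morgans, crossover positions are uniform, and
bp↔cM is linear. Segments are half-open intervals; a gamete is assembled by
switching between the two parental homologs at the crossover points.

**Pedigree.** F₁ → six backcrosses to the recurrent parent → one selfing.
Under neutrality the expected donor fraction halves each generation,
$0.5^{g+1}$ after $g$ backcrosses and selfing — $0.5^7 \approx 0.78\%$ at
BC₆F₂ — and the test suite checks both the value (2,000 families, within 3
SE) and the halving slope across generations.

**Marker-assisted retention.** A neutral BC₆F₂ leaves any given locus
segregating in only $\sim 0.5^6$ of families, far too few for a bulk of 20 to
show an elevated SNP-index, and incompatible with a locus explaining half the
trait variance. Real substitution-line libraries avoid this by retaining
donor segments with marker-assisted selection during backcrossing. The
generator models that with `targets_per_family` (default 3): target points
are tiled on an even genome grid and dealt round-robin across families (a
library designed to tile the donor genome), and each backcross meiosis
retries (up to 64 draws) to keep the family's target segments. Neutral
analytic checks run with the hook off (`targets_per_family = 0`), since their
derivations assume no selection. With the default design the median number of
distinct introgressed regions per family is 3.

**Phenotypes.** Two traits (fiber length, mm; fiber strength, cN/tex) share
the planted QTL effects — the strength effect plus a proportional length
effect (0.3× by default) — on top of a bivariate-normal residual with SDs 1.0
and 2.1 and correlation 0.6. With `env_sd = 0` and a single QTL a trait takes
at most three values (one per dose), which the tests assert.
`qtl_effect_for_variance()` sizes an additive effect so the locus explains a
requested variance fraction against the realized dose distribution.

**Sequencing.** Pooled depths are Poisson (defaults: parents 20×, bulks 30×);
donor-read counts are Binomial at the bulk's true donor frequency, with a
symmetric per-read error rate (default 0.001). Zero-depth sites are emitted
as missing. The emitted VCF alternates which parent matches the reference, so
the parent-polarized importer is exercised on both orientations; the
write/read round trip is byte-exact on counts.

**What is deliberately not modeled:** linkage-disequilibrium structure beyond
the pedigree itself, genotyping/alignment artifacts (paralogy,
allele-specific bias), dominance or epistasis, selection on phenotype during
line development, and multi-QTL genetic architectures (the generator accepts
several QTLs but the studies here plant at most one).

## 4. Phenotype screening and bulk construction

`summarize_trait()` reports mean, SD, CV, range and the bias-adjusted
(SPSS-convention) skewness and kurtosis; `normality_screen()` applies the
conventional |skewness| < 1 and |kurtosis| < 1 screen. Two bulk builders are
provided: `select_bulks()` applies strict dual-trait thresholds (both traits
high for HC1, both low for HC2), and `select_extreme_bulks()` takes the
top-20 / bottom-12 families by fiber strength, which is what the synthetic
studies use so bulk sizes are deterministic. A caveat observed in the shipped
showcase run: a single locus explaining 50% of the variance inflates the
trait's kurtosis past 1, so the screen flags exactly the situation it is
meant to detect; rank-truncation bulks remain valid.

## 5. Annotation

Called regions are intersected with a per-SNP variant-effect table, keeping
protein-altering classes (nonsynonymous, stopgain, stoploss) grouped by gene.
Term enrichment is a hypergeometric upper-tail test per term against the
genome-wide gene background with Benjamini–Hochberg adjustment, plus a
descriptive per-namespace classification for small candidate sets. In
synthetic mode both tables are simulated (genes on a 100 kb grid, genome-like
class proportions, random term incidences) — adequate for exercising the
plumbing, carrying no biology.

## 6. Reproducibility

Every stochastic stage takes an explicit integer seed, and the pipeline
manifest records a hash of the semantic configuration (paths and output
switches excluded) plus stage-wise record counts whose conservation the tests
assert. Repeated runs are byte-identical, including written artifacts. The
`analysis/` drivers reproduce the showcase study from one fixed seed, and
`scripts/acceptance.R` recomputes the headline quantities from any master
seed.
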