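---
title: "Methods: genome-wide scans for insecticide-resistance markers"
author: "sweepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide scans for insecticide-resistance markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The problem

Field studies of insecticide resistance in *Anopheles* mosquitoes phenotype
wild-caught individuals by bioassay — alive after exposure to a high dose
("resistant") versus dead after a lower dose ("susceptible") — and sequence
their genomes to find the loci driving survival. Resistance alleles rise in
frequency under strong selection, so two complementary signal types are
informative: *selection* signals (a haplotype sweeping towards fixation)
and *association* signals (genetic differences between resistant and
susceptible individuals). Copy-number variants (CNVs) amplifying
detoxification genes — carboxylesterases, cytochrome P450s, glutathione
transferases — are frequent drivers, visible in sequencing data as elevated
normalised read coverage.

`sweepscan` implements the whole analysis chain for such a study: kinship
quality control, haplotype-based selection scans, windowed differentiation
scans with permutation-filtered peak calling, coverage-HMM copy-number
calling, haplotype-cluster and marker association models, a SNP-wise and
windowed GWAS, and a Monte Carlo power analysis — together with a
synthetic-data generator so every stage can be exercised end to end without
any sequencing data.

## Statistics and models

### Kinship and sample QC

Full siblings in a cohort are pseudo-replicates. The KING-robust estimator
for a sample pair $(i,j)$ is

$$\phi_{ij} = \frac{N_{HetHet} - 2\,N_{OppHom}}{N_{Het}(i) + N_{Het}(j)}$$

over loci called in both samples ($N_{HetHet}$: both heterozygous;
$N_{OppHom}$: opposite homozygotes; $N_{Het}(\cdot)$: heterozygous loci of
each sample on the shared loci). Expected values are 0.5 for self, ~0.25
for full sibs, ~0 for unrelated pairs. Pairs with $\phi \ge 0.185$ are
classified as sibs and sib groups are the connected components of that
graph. Regions of known chromosomal inversions should be excluded
(`exclude_regions`) since they distort the estimator; the inversion
coordinates are species-specific configuration, not constants.
Cross-contaminated samples show inflated heterozygosity and uniformly high
kinship to everyone; `flag_contaminated()` flags samples that are extreme
in both (median-kinship quantile 0.99 and heterozygosity z > 4 by default —
the field provides no canonical numbers, so both are configuration).

One random member per sib group is retained per analysis
(`dedup_sibs()`); for windowed FST the package instead averages the track
over `sib_n_perm = 100` retention permutations, using the full sample set
without pseudo-replication.

The estimator here works on called genotypes. A genotype-likelihood
formulation would be preferable at low coverage; at the high coverages of
modern resequencing the difference is negligible.

### Haplotype homozygosity: H1, H12, H1X, deltaH12

Within a window of $w$ consecutive SNPs, haplotypes are compared as exact
allele strings and their frequencies $p_1 \ge p_2 \ge \dots$ computed.
Garud's statistics are $H_1 = \sum_i p_i^2$ and
$H_{12} = (p_1 + p_2)^2 + \sum_{i \ge 3} p_i^2$; pooling the two most
frequent haplotypes makes $H_{12}$ sensitive to *soft* sweeps where two
haplotype backgrounds rise together. Cross-population sharing is
$H_{1X} = \sum_i p_{ia} p_{ib}$ over the union of distinct haplotypes: high
when the same high-frequency haplotypes segregate in both populations.
$\Delta H_{12}$ is $H_{12}$ in resistant minus $H_{12}$ in susceptible
samples, so positive values mark swept haplotypes enriched among
survivors.

Window size is deliberately a parameter rather than a constant (field
analyses use 1000-SNP windows for scans and 2000-SNP windows for
genome-wide overviews; the synthetic data here use 50).

### Windowed differentiation: Hudson FST and PBS

Per site, with alt-allele frequency $p_k$ and allele count $n_k$ in
population $k$, Hudson's estimator contributes

$$\text{num} = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1},
\qquad \text{den} = p_1(1-p_2) + p_2(1-p_1),$$

and a window's FST is the ratio of summed numerators to summed denominators
(ratio of sums, which is invariant to site order and bounded above by 1).
Sites with missing calls in either group or with combined minor allele
count $\le 1$ (singletons) are excluded first. The population branch
statistic uses $T = -\ln(1-F_{ST})$ for the three pairs among focal,
sister and outgroup groups: $PBS = (T_{fs} + T_{fo} - T_{so})/2$, isolating
frequency change on the focal branch. FST is clipped at $1-10^{-12}$
before the logarithm; windows whose denominator sums are non-positive are
masked.

### Peak calling and the permutation filter

Provisional FST peaks are windows whose value exceeds
$\text{mode} + 3(\text{mode} - \min)$, where the mode of the genome-wide
track is estimated by Gaussian kernel density (Silverman's rule-of-thumb
bandwidth, argmax on a 512-point grid spanning the data range — a smooth,
deterministic choice). The rule needs at least one negative value; an
all-positive track yields no peaks and a warning. PBS and
$\Delta H_{12}$ peaks instead use three times the 95th (PBS) or 98th
(H12-based) linear-interpolation centile.

A window can be differentiated between phenotype groups merely because a
selective sweep is segregating, without any causal connection to
resistance. The permutation filter re-computes the statistic on the
candidate windows under `n_perm = 500` permutations of the phenotype
labels (within location strata — locations are analysed separately, making
within-stratum exchange the faithful null) and retains a peak only if the
observed value exceeds the 0.99 empirical quantile of its permuted values
(strict `>`; the counting p-value $(1 + \#\{perm \ge obs\})/(n_{perm}+1)$
is reported alongside). The strict rule with a type-7 quantile has
realised type-I error ~1.2% at 500 permutations, verified by simulation in
the test suite.

Surviving FST peaks are further required to contain a haplotype cluster
positively associated with resistance: haplotypes in the window are
clustered by Dxy (proportion of differing sites) with average-linkage
(UPGMA) hierarchical clustering cut at height 0.001 on cophenetic height
(the standard reading of cutting a tree at a height; the linkage itself is
a package choice, documented because runs must be bit-reproducible —
merge ties resolve by lowest index). Clusters of at least 20 haplotypes
are tested with a binomial-logit GLM of phenotype on per-sample haplotype
dose (0/1/2); the peak is kept iff some cluster has a positive coefficient
with p below 0.05 (the association level is a package default; "positively
associated" comes with no canonical level). When a window holds fewer
sites than $1/\text{cut height}$, any two distinct haplotypes are farther
apart than the cut, so the flat clusters are exactly the allele-string
equivalence classes; the implementation uses this identity as a fast path.

### Coverage HMM for copy number

Normalised coverage in fixed 300-bp windows (diploid expectation 2.0) is
decoded by a hidden Markov model with states equal to total copy number
$0\dots12$ (diploid plus up to 10 extra copies), Gaussian emissions
$\mathcal{N}(\text{state}, \sigma)$ with the copy-0 mean replaced by a
floor of 0.1, self-transition probability $1 - t$ with $t = 10^{-4}$
split equally among the other states, and a uniform initial distribution.
$\sigma = 0.5$ and $t = 10^{-4}$ are defaults chosen so single-window
state flips are unlikely; all are configuration. A gene's copy number is
the modal state over the windows overlapping it (ties toward the lower
state); extra copies = mode − 2; a carrier has extra copies > 0. For
amplifications beyond the 10-extra-copy ceiling the HMM saturates, and
`region_median_copy_number()` — median raw normalised coverage over the
windows inside the region, minus 2 — recovers the true amplitude (the
synthetic tests plant 26 extra copies and recover them within ±1).

### Marker association, stepwise models, power

Markers are tested with binomial-logit GLMs (IRLS to tolerance $10^{-8}$,
max 25 iterations) with the standard codings: SNPs as mutant-allele count
(0/1/2), CNV alleles as presence/absence, gene copy number as extra
copies. Complete separation (non-convergence or |coefficient| > 10
log-odds) flags the fit and the likelihood-ratio p-value replaces the Wald
p. Forward stepwise selection adds, from the null model, the marker with
the smallest LRT p-value against the current model while that p-value is
below 0.05 (ties broken by marker order). With two locations, location
enters as a fixed-effect covariate — a two-level factor cannot support a
random-effect variance component.

The power calculation simulates cohorts of $n$ individuals, each a CNV
carrier with probability equal to the observed carrier frequency, dying
with the wild-type or carrier mortality, and reports the fraction of
simulations in which the carrier term reaches $P < 0.05$. Carrier counts
are resampled per replicate (Bernoulli) rather than fixed; both protocols
agree to within Monte Carlo error. At the study scale
($n = 151$, carrier frequency 0.74, mortalities 0.442/0.167) the
simulation gives power ≈ 0.91 with Monte Carlo SE ≈ 0.009; the analytic
Wald approximation under exactly these parameters is 0.918, so the
simulated value is what these parameters imply even though field reports
of comparable designs quote slightly lower figures — small protocol
details (how the reference analysis extracted its p-value, parameter
uncertainty folded into the simulation) shift the third digit.

### GWAS

SNP-wise GWAS keeps sites with no missing data and minor allele count
$\ge 5$, then drops sites whose genotype correlates with the per-sample
contamination fraction (Spearman rank correlation, $P < 0.05$; Spearman
because the relationship need only be monotone). Each remaining site gets
a binomial-logit GLM of phenotype on allele dose. Multiple testing is
controlled by Benjamini–Hochberg at $Q = 1\%$ — a deterministic,
dependency-free substitute for empirical-null local-FDR tools. The
windowed analysis ranks sites by p-value (ties by position), takes the top
1000, tiles each contig with non-overlapping 100,000-bp windows from
coordinate 0 (the tile phase is configurable) and flags tiles holding at
least 10 of the top sites.

## The synthetic-data generator

`simulate_dataset()` emulates the *structure* of a two-location cohort:

* **Haplotypes.** Each of `n_blocks = 8` genomic blocks is an independent
  Kingman coalescent genealogy per population, with infinite-sites
  mutations placed on branches as a Poisson process (rate ∝ `theta = 16`
  per block, so expected within-population pairwise diversity per block is
  θ). Block independence is a proxy for recombination. A fraction
  `1 - divergence` (default 0.7) of mutations occupies shared genomic
  positions polymorphic in both populations (frequencies drifting
  independently on each population's genealogy); the rest are private, so
  `divergence` tunes differentiation. Mutation positions are uniform
  within the block's span of the contig (collisions redrawn).
* **Sweep.** In the focal population a randomly chosen core haplotype
  overwrites the focal block of a fraction `f = 0.6` of haplotypes. Each
  swept copy gains Poisson(`mut_rate = 0.5`) private mutations
  (sub-structure of the kind seen when CNV alleles arise on a sweeping
  background), and `core_snps = 12` sweep-defining mutations shared by all
  swept copies are added — the hitchhiking variants a real swept haplotype
  carries relative to its population. The latter matter at desk scale:
  with θ = 16 a block occasionally yields a core haplotype nearly
  identical to the consensus, which no actual sweeping haplotype is, and
  without its own variants the sweep would be invisible to
  frequency-difference statistics by construction rather than by biology.
* **CNV and coverage.** Samples with ≥ 1 swept haplotype carry the CNV
  with probability `link_p = 1` (the emulated system shows near-perfect
  concordance between the swept cluster and the CNV); carrier extra-copy
  number is `4 + Poisson(4)` (median 8, long right tail — the emulated
  CNV has median 8 extra copies and can exceed the HMM ceiling). Coverage
  per 300-bp window is Normal(true copy number, `0.3`) truncated at zero,
  mean 2 outside the region.
* **Phenotype.** Each sample dies with probability 0.442 (non-carrier) or
  0.167 (carrier) — the mortality contrast the power analysis uses — and
  dead samples are phenotyped susceptible.
* **Sibs and contamination.** Two shared parents per pair; each child
  inherits one haplotype of each parent per block (free recombination
  between blocks, none within). Contamination fractions are
  Uniform(0, 0.05); a target site can be made to track contamination to
  exercise the exclusion filter.

**Cohort sizes.** Defaults are 900 samples in the focal population and 300
in the comparison population. The comparison population only serves as the
second location and PBS outgroup and can stay small. The focal size comes
from a design-phase power analysis: with the documented effect sizes (a
0.6-frequency sweep, mortalities 0.442 vs 0.167, sample-level carrier
frequency ≈ 0.84), a windowed FST peak must clear the 99% quantile of 500
phenotype permutations *and* the cluster filter; that compound test needs
roughly a z ≥ 4 association signal, which at these effect sizes requires
several hundred phenotyped individuals. 900 gives the filters comfortable
power without inflating runtimes.

**What the generator does not emulate.** Continuous recombination (LD
decays blockwise, not smoothly); demography and selection through time;
sequencing error and missingness (genotypes are clean); genome-scale site
counts — a desk-scale dataset has ~2000 SNPs in 8 independent genealogies,
so genome-wide empirical distributions (the FST mode rule, centile
thresholds) rest on tens of windows rather than tens of thousands, and
genotype-based kinship cannot separate sibs from unrelated pairs (the
per-pair estimator noise is ~0.15 with 8 independent loci — that is a
property of block-count, not of the estimator, which is why the pipeline
accepts sib groups from the sample metadata, as studies using external
kinship tools do, and why the kinship module is validated on dedicated
24-block pedigree simulations). Passing tests therefore demonstrate
correctness of the statistics and the machinery around them, and recovery
of planted signals under the documented conditions — not performance on
real genomes.

## Numerical choices and degenerate inputs

* Terminal partial SNP windows are dropped so all windows hold exactly
  `window_size` SNPs and are comparable.
* Multiallelic and non-SNP VCF records are skipped (with a count), not
  split; haplotypes are taken only from records at which every sample is
  phased and non-missing; missing genotypes are `NA` and every downstream
  operation handles them explicitly.
* Windowed FST with a non-positive denominator sum is `NA` (masked);
  `garud_h()` of an empty spectrum and decoding an empty coverage track
  are errors; a phenotype with one class refuses to fit.
* UPGMA heights are rounded to 10 decimals and made non-decreasing before
  tree cutting to guard against floating-point jitter in merge order.
* Every stochastic function takes an explicit seed and is bit-reproducible
  under it, including the permutation filter's label stream and the sib
  retention permutations.

## Problem sizes used by the shipped checks

The test suite validates statistics against brute-force oracles on
hundreds of small random instances, calibration on independent-site null
fixtures (where joint uniformity of p-values is a property of the test,
not of linkage), and planted-signal recovery on 50 positive and 50
shared-sweep control datasets at the default study conditions with
analysis settings `window_size = 50`, scans on the focal location,
presence/absence CNV marker coding, and the kinship and GWAS stages
exercised in their own tests rather than inside the 50-seed loops. These
sizes keep the whole suite within a coffee break on a single CPU while
leaving every threshold at its field value (500 permutations, 99%
retention, cut height 0.001, minimum cluster 20, MAC ≥ 5, Q = 1%).
`scripts/acceptance.R` re-runs the power analysis from scratch at the
study scale.

## Known limitations

* Kinship from called genotypes only; no genotype-likelihood or IBD-segment
  support.
* The cluster filter tests clusters, not individual variants; a peak whose
  association is driven by several small clusters below `min_size` is
  discarded.
* BH control assumes the usual positive-dependence conditions; with the
  strong local LD of real data the windowed GWAS view is the more robust
  summary.
* The coverage HMM assumes normalised, GC-corrected input; no correction
  is applied in-package.
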