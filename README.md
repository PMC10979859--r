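# sweepscan

Genome-wide association scans for insecticide resistance in phenotyped
mosquito cohorts.

Field studies of resistance phenotype wild-caught *Anopheles* mosquitoes by
bioassay (alive after a high insecticide dose = resistant, dead after a
lower dose = susceptible) and sequence their genomes. `sweepscan`
implements the full analysis chain such a study needs:

* **Kinship QC** — KING-robust kinship from called genotypes,
  `φ = (N_HetHet − 2·N_OppHom) / (N_Het(i) + N_Het(j))`, sib groups as
  connected components above φ ≥ 0.185, contamination flags, and sib-aware
  sample retention (one random member per group, or averaging over
  retention permutations).
* **Selection scans** — Garud's haplotype homozygosity `H1 = Σ pᵢ²` and
  `H12 = (p₁+p₂)² + Σ_{i≥3} pᵢ²` in windows of a fixed number of SNPs,
  cross-population sharing `H1X = Σ pᵢₐ·pᵢᵦ`, and ΔH12 (resistant minus
  susceptible).
* **Differentiation scans** — windowed Hudson FST as a ratio of summed
  per-site numerators and denominators, the population branch statistic
  `PBS = (T_fs + T_fo − T_so)/2` with `T = −ln(1 − FST)`, mode- and
  centile-based peak calling, a 500-permutation phenotype-label filter
  (peaks retained only above the 99% quantile of their permuted values),
  and a haplotype-cluster filter (UPGMA on Dxy, cut height 0.001, clusters
  of ≥ 20 haplotypes tested by binomial-logit GLM).
* **Copy-number calling** — a Viterbi-decoded HMM over total copy-number
  states 0–12 on normalised coverage in 300-bp windows, per-gene modal
  copy number, and a median-coverage estimator for amplifications beyond
  the HMM ceiling.
* **Association** — single-marker binomial-logit GLMs with the standard
  codings (SNP dose 0/1/2, CNV presence/absence, extra copies), forward
  stepwise model building on likelihood-ratio tests, SNP-wise GWAS with
  MAC ≥ 5 / no-missing / contamination-correlation filters,
  Benjamini–Hochberg FDR at Q = 1%, a windowed top-SNP analysis, and a
  Monte Carlo power calculation for CNV markers.
* **Synthetic data** — a block-coalescent generator that emulates a
  two-location cohort with a soft sweep linked to a multi-copy CNV,
  genotype-dependent mortality (0.442 wild-type vs 0.167 carrier),
  full-sib pairs and per-sample contamination, with a truth set for every
  planted signal.

Inputs are standard formats: phased VCF, a sample metadata TSV/CSV, a
coverage TSV (`contig, start, end`, one column per sample) and BED region
annotations.

## Worked example

Simulate a study at its default conditions, run the pipeline, and ask the
three headline questions — where is the sweep, does its FST peak survive
the permutation and cluster filters, and which marker explains survival?

```r
library(sweepscan)

ds <- simulate_dataset(sim_config(seed = 42))
ds
#> <sim_dataset> 1923 sites, 1216 samples, 800 coverage windows

rc <- run_config(window_size = 50, scan_locations = "Moshi",
                 marker_codings = "carrier",
                 stages = c("selection", "differentiation", "cnv", "association"),
                 seed = 1)
run <- run_pipeline(ds, rc)
run
#> <sweepscan_run>
#>   kinship: 8 sib group(s), 0 sample(s) flagged contaminated
#>   Moshi: max H12 0.924, max deltaH12 0.095, FST peaks retained 3/6
#>   stepwise: cnv_region_carrier

sc <- run$scans$Moshi
sc$h12[which.max(sc$h12$value), c("first_pos", "last_pos")]
#>   first_pos last_pos
#>        126117   127561
run$stepwise
#> <stepwise_model> selected: cnv_region_carrier (p=1.53e-11)
```

The planted sweep occupies positions 120,000–150,000: the genome-wide H12
maximum (window 126,117–127,561) lands inside it, three FST candidate
windows survive both false-positive filters, and stepwise selection picks
the CNV presence/absence marker with an LRT p of 1.5 × 10⁻¹¹ — the
pipeline recovers exactly the planted causal structure.

The power analysis behind marker interpretation runs at study scale in a
few seconds:

```r
cnv_power_simulation(n = 151, carrier_freq = 0.74,
                     mort_wt = 0.442, mort_carrier = 0.167,
                     n_sims = 1000, seed = 1)
#> <power_result> power 0.913 (MC se 0.009) from 1000 simulations at alpha 0.05
```

With 151 individuals, a 74% carrier frequency and mortalities of 44.2%
(wild-type) vs 16.7% (carrier), a binomial-logit GLM detects the carrier
effect at P < 0.05 in about 91% of simulated cohorts.

See `vignettes/resistance-scans.Rmd` for the models, their assumptions,
all tunable parameters, and the design of the synthetic-data generator.

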