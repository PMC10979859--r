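Package: sweepscan
Title: Genome-Wide Association Scans for Insecticide Resistance in Mosquito
    Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a genome-wide workflow for detecting genetic markers of
    insecticide resistance in phenotyped mosquito cohorts: KING-robust kinship
    and sib-group handling, haplotype homozygosity selection scans (Garud H1,
    H12, cross-population H1X, and the resistant-minus-susceptible delta-H12),
    windowed Hudson FST and the population branch statistic with
    phenotype-permutation false-positive filtering, coverage-based hidden
    Markov model copy-number calling with per-gene modal copy number,
    haplotype clustering by Dxy with cluster-phenotype association, SNP-wise
    and windowed case-control GWAS with contamination filtering and
    false-discovery-rate control, and Monte Carlo power analysis for
    copy-number markers. A coalescent-based synthetic-data generator emulates
    the structure of two-population field studies (selective sweeps linked to
    multi-copy CNVs, genotype-dependent mortality, full-sib pairs, and sample
    contamination) so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
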