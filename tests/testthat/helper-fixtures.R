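# Small deterministic fixtures built in code.

# Haplotype set with explicit alleles: `alleles` is sites x (2*n_samples).
fix_hapset <- function(alleles, pos = NULL, contig = "2L") {
  alleles <- as.matrix(alleles)
  n_s <- ncol(alleles) / 2L
  if (is.null(pos)) pos <- seq_len(nrow(alleles)) * 10L
  sites <- site_info(rep(contig, nrow(alleles)), pos,
                     rep("A", nrow(alleles)), rep("T", nrow(alleles)))
  haplotype_set(sites, sprintf("S%02d", seq_len(n_s)), alleles)
}

fix_genoset <- function(calls, pos = NULL, contig = "2L") {
  calls <- as.matrix(calls)
  if (is.null(pos)) pos <- seq_len(nrow(calls)) * 10L
  sites <- site_info(rep(contig, nrow(calls)), pos,
                     rep("A", nrow(calls)), rep("T", nrow(calls)))
  genotype_set(sites, sprintf("S%02d", seq_len(ncol(calls))), calls)
}

# Random genotype matrix with optional missingness.
random_genoset <- function(n_sites, n_samples, miss_p = 0, maf = NULL) {
  if (is.null(maf)) maf <- runif(n_sites, 0.05, 0.5)
  calls <- vapply(seq_len(n_sites), function(i)
    rbinom(n_samples, 2L, maf[i]), integer(n_samples))
  calls <- t(calls)
  if (miss_p > 0)
    calls[runif(length(calls)) < miss_p] <- NA_integer_
  fix_genoset(calls)
}

fix_sample_table <- function(n, phenotype = NULL, location = "Moshi",
                             contamination = 0) {
  if (is.null(phenotype))
    phenotype <- rep(c("resistant", "susceptible"), length.out = n)
  sample_table(data.frame(
    sample = sprintf("S%02d", seq_len(n)), location = location,
    insecticide = "PM", phenotype = phenotype,
    contamination = contamination, stringsAsFactors = FALSE))
}

# A small simulated study, cheap enough for unit tests.
small_sim <- function(seed, ...) {
  args <- list(...)
  defaults <- list(
    n_samples = c(40L, 40L), n_blocks = 4L, contig_length = 48000L,
    theta = 8,
    sweep = list(block = 3L, f = 0.6, mut_rate = 0.5, core_snps = 6L, pop = 1L),
    cnv = list(start = 27000L, end = 32400L, link_p = 1,
               copy_dist = function(n) 4L + stats::rpois(n, 4)),
    n_sib_pairs = c(1L, 1L), seed = seed)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Plain-text VCF fixture written to a tempfile; returns the path.
write_vcf_fixture <- function(lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

vcf_row <- function(contig, pos, ref, alt, gts) {
  paste(c(contig, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}
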