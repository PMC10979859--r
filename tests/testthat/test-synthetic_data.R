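test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- small_sim(seed = 7L)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$haplotypes$alleles, b$haplotypes$alleles)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$coverage$coverage, b$coverage$coverage)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth$swept_haps, b$truth$swept_haps)
})

test_that("coalescent blocks reproduce E(pi) = theta", {
  set.seed(101)
  theta <- 6
  pis <- replicate(600, {
    tr <- sweepscan:::coalescent_tree(10L)
    muts <- sweepscan:::drop_mutations(tr, theta)
    if (!length(muts)) return(0)
    m <- matrix(0L, length(muts), 10L)
    for (i in seq_along(muts)) m[i, muts[[i]]] <- 1L
    d <- as.matrix(stats::dist(t(m), method = "manhattan"))
    mean(d[upper.tri(d)])
  })
  expect_lt(abs(mean(pis) - theta) / theta, 0.1)
})

test_that("two-population haplotypes have segregating sites and shared pool", {
  cfg <- small_sim(seed = 3L, n_samples = c(20L, 20L))
  out <- simulate_haplotypes(cfg)
  h <- out$haplotypes
  ac <- rowSums(h$alleles)
  expect_true(all(ac > 0 & ac < ncol(h$alleles)))        # all segregating
  expect_true(all(diff(h$sites$pos) > 0))                # sorted, unique
  expect_identical(length(out$truth$site_block), nrow(h$sites))
  # with divergence < 1 some sites are polymorphic in both populations
  pop <- out$truth$sample_pop[h$haplotypes$sample]
  ac1 <- rowSums(h$alleles[, pop == 1, drop = FALSE])
  ac2 <- rowSums(h$alleles[, pop == 2, drop = FALSE])
  expect_gt(sum(ac1 > 0 & ac2 > 0), 0)
})

test_that("implant_sweep drives focal-block haplotype structure", {
  cfg <- small_sim(seed = 5L, n_samples = c(20L, 20L))
  base <- simulate_haplotypes(cfg)

  # f = 1, no new mutations: a single haplotype in every focal-block window
  sw <- implant_sweep(base$haplotypes, base$truth, block = 3L, f = 1,
                      mut_rate = 0, seed = 9L, core_snps = 0L)
  idx <- which(sw$truth$site_block == 3L)
  w <- list(first = min(idx) - 1L, last = max(idx) - 1L)
  freqs <- hap_frequencies(sw$haplotypes, w)
  expect_identical(length(freqs), 1L)
  expect_identical(unname(garud_h(freqs)), c(1, 1))

  # f = 0.5 within one population: top frequency >= 0.5 there
  sw2 <- implant_sweep(base$haplotypes, base$truth, block = 3L, f = 0.5,
                       mut_rate = 0, seed = 9L, pop = 1L, core_snps = 0L)
  pop <- sw2$truth$sample_pop[sw2$haplotypes$haplotypes$sample]
  idx2 <- which(sw2$truth$site_block == 3L)
  f2 <- hap_frequencies(sw2$haplotypes,
                        list(first = min(idx2) - 1L, last = max(idx2) - 1L),
                        haps = which(pop == 1))
  expect_gte(f2[[1]], 0.5)

  # core_snps are carried by every swept copy and recorded as causal
  sw3 <- implant_sweep(base$haplotypes, base$truth, block = 3L, f = 0.6,
                       mut_rate = 0, seed = 9L, pop = 1L, core_snps = 4L)
  expect_identical(length(sw3$truth$causal_sites), 4L)
  swept_cols <- colnames(sw3$haplotypes$alleles) %in% sw3$truth$swept_haps
  causal_rows <- match(sw3$truth$causal_sites, sw3$haplotypes$sites$pos)
  expect_true(all(sw3$haplotypes$alleles[causal_rows, swept_cols] == 1L))
  expect_true(all(sw3$haplotypes$alleles[causal_rows, !swept_cols] == 0L))

  expect_error(implant_sweep(base$haplotypes, base$truth, block = 99L,
                             f = 0.5, seed = 1L), "out of range")
})

test_that("sib-pair children inherit one parental haplotype per block", {
  cfg <- small_sim(seed = 13L, n_samples = c(10L, 10L))
  base <- simulate_haplotypes(cfg)
  out <- make_sib_pairs(base$haplotypes, base$truth, n_pairs = c(2L, 0L),
                        seed = 21L)
  h <- out$haplotypes
  kids <- out$truth$sib_groups$sample
  expect_identical(length(kids), 4L)
  founders <- setdiff(h$samples, kids)
  for (kid in kids) {
    for (phase in 1:2) {
      col <- h$alleles[, paste0(kid, "_", phase)]
      for (b in seq_len(nrow(out$truth$block_bounds))) {
        idx <- which(out$truth$site_block == b)
        # the child's block must match some founder haplotype exactly
        founder_cols <- h$alleles[idx, !colnames(h$alleles) %in%
                                    paste0(rep(kids, each = 2), "_", 1:2),
                                  drop = FALSE]
        matches <- colSums(founder_cols != col[idx]) == 0
        expect_true(any(matches))
      }
    }
  }
  expect_error(make_sib_pairs(base$haplotypes, base$truth,
                              n_pairs = c(50L, 0L), seed = 1L),
               "not enough founders")
})

test_that("CNV assignment links carriers to the sweep and shapes coverage", {
  cfg <- small_sim(seed = 17L)
  ds <- simulate_dataset(cfg)
  truth <- ds$truth
  # link_p = 1: carrier set equals swept-sample set
  hap_swept <- colnames(ds$haplotypes$alleles) %in% truth$swept_haps
  swept_sample <- tapply(hap_swept, ds$haplotypes$haplotypes$sample, any)
  expect_identical(unname(truth$cnv$carrier[names(swept_sample)]),
                   unname(as.logical(swept_sample)))
  # in-region coverage mean tracks the assigned copy number
  reg <- ds$regions
  in_reg <- ds$coverage$starts >= reg$start &
    ds$coverage$starts + 300L <= reg$end
  carriers <- names(which(truth$cnv$carrier))
  for (s in carriers[1:3]) {
    cn <- truth$cnv$copy_number[s]
    expect_lt(abs(mean(ds$coverage$coverage[in_reg, s]) - cn), 0.5)
  }
  out_reg_mean <- mean(ds$coverage$coverage[!in_reg, carriers[1]])
  expect_lt(abs(out_reg_mean - 2), 0.2)
})

test_that("near-noiseless coverage lets the HMM recover every copy number", {
  cfg <- small_sim(seed = 23L, coverage_noise_sd = 0.01,
                   cnv = list(start = 27000L, end = 32400L, link_p = 1,
                              copy_dist = function(n) sample(1:8, n, replace = TRUE)))
  ds <- simulate_dataset(cfg)
  calls <- cnv_call(ds$coverage, ds$regions)
  expect_identical(stats::setNames(calls$state, calls$sample),
                   ds$truth$cnv$copy_number[calls$sample])
})

test_that("phenotype simulation follows the carrier-dependent mortalities", {
  cfg <- small_sim(seed = 29L)
  base <- simulate_haplotypes(cfg)
  truth <- base$truth
  truth$cnv <- list(carrier = stats::setNames(
    rep(c(TRUE, FALSE), length.out = length(truth$sample_pop)),
    names(truth$sample_pop)))

  st0 <- simulate_phenotypes(truth, base_mort = 0, carrier_mort = 0, seed = 1L)
  expect_true(all(st0$phenotype == "resistant"))

  st1 <- simulate_phenotypes(truth, base_mort = 1, carrier_mort = 0, seed = 1L)
  expect_true(all(st1$phenotype[truth$cnv$carrier[st1$sample]] == "resistant"))
  expect_true(all(st1$phenotype[!truth$cnv$carrier[st1$sample]] == "susceptible"))

  # observed mortalities sit inside a 3-se binomial band of the inputs
  cfg2 <- small_sim(seed = 31L, n_samples = c(400L, 400L),
                    n_sib_pairs = c(0L, 0L))
  ds2 <- simulate_dataset(cfg2)
  carrier <- ds2$truth$cnv$carrier[ds2$samples$sample]
  dead <- ds2$samples$phenotype == "susceptible"
  for (grp in list(list(sel = carrier, p = 0.167),
                   list(sel = !carrier, p = 0.442))) {
    n <- sum(grp$sel)
    obs <- mean(dead[grp$sel])
    expect_lt(abs(obs - grp$p), 4 * sqrt(grp$p * (1 - grp$p) / n))
  }
})

test_that("contamination fractions are bounded and can drive a target site", {
  cfg <- small_sim(seed = 37L)
  ds <- simulate_dataset(cfg)
  st <- ds$samples
  expect_true(all(st$contamination >= 0 & st$contamination <= 0.05))

  # a strong effect makes the target site trackable by the filter
  out <- simulate_contamination(ds$genotypes, st, target_site = 5L,
                                effect = 3, seed = 41L)
  kept <- contamination_filter(out$genotypes, out$sample_table, alpha = 0.05)
  expect_false(5L %in% kept)
})

test_that("written datasets can be read back by the package readers", {
  cfg <- small_sim(seed = 43L, n_samples = c(6L, 6L), n_sib_pairs = c(0L, 0L))
  ds <- simulate_dataset(cfg)
  dir <- tempfile("dataset")
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(
    dir, c("genotypes.vcf", "samples.tsv", "coverage.tsv", "regions.bed",
           "truth.tsv")))))
  back <- read_vcf(file.path(dir, "genotypes.vcf"))
  expect_identical(unname(back$haplotypes$alleles),
                   unname(ds$haplotypes$alleles))
  st <- read_sample_table(file.path(dir, "samples.tsv"))
  expect_identical(st$sample, ds$samples$sample)
  cov <- read_coverage(file.path(dir, "coverage.tsv"))
  expect_equal(cov$coverage, ds$coverage$coverage, tolerance = 1e-4,
               ignore_attr = TRUE)
})
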