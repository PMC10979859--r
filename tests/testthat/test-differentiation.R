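test_that("Hudson per-site components follow the estimator formula", {
  # fixed difference: num = den = 1
  comp <- hudson_fst_components(cbind(0, 10), cbind(10, 0))
  expect_equal(comp$num, 1)
  expect_equal(comp$den, 1)

  # p1 = p2 = 0.5 with n = 10 alleles each: negative expectation correction
  comp2 <- hudson_fst_components(cbind(5, 5), cbind(5, 5))
  expect_equal(comp2$num, -2 * (0.25 / 9))
  expect_equal(comp2$den, 0.5)
  expect_equal(comp2$num / comp2$den, -0.111111, tolerance = 1e-5)

  # monomorphic shared site: zero denominator (excluded upstream in scans)
  comp3 <- hudson_fst_components(cbind(10, 0), cbind(8, 0))
  expect_equal(comp3$den, 0)

  expect_error(hudson_fst_components(cbind(1, 0), cbind(5, 5)),
               ">= 2 called alleles")

  set.seed(10)
  for (rep in 1:50) {
    n1 <- sample(4:30, 1); n2 <- sample(4:30, 1)
    a1 <- sample(0:n1, 1); a2 <- sample(0:n2, 1)
    got <- hudson_fst_components(cbind(n1 - a1, a1), cbind(n2 - a2, a2))
    want <- oracle_hudson_site(a1, n1, a2, n2)
    expect_equal(got$num, unname(want["num"]), tolerance = 1e-12)
    expect_equal(got$den, unname(want["den"]), tolerance = 1e-12)
  }
})

test_that("windowed FST is a ratio of sums matching brute force", {
  set.seed(11)
  g <- random_genoset(120, 30)
  s1 <- g$samples[1:15]; s2 <- g$samples[16:30]
  tr <- fst_scan(g, s1, s2, window_size = 20L)
  sites <- attr(tr, "sites")
  gs <- subset_sites(g, sites)
  ac1 <- allele_counts(gs, s1); ac2 <- allele_counts(gs, s2)
  for (i in seq_len(nrow(tr))) {
    expect_equal(tr$value[i],
                 oracle_windowed_fst(ac1, ac2, tr$first[i], tr$last[i]),
                 tolerance = 1e-12)
  }

  # identical groups (same samples in both): values are one-population noise
  tr0 <- fst_scan(g, s1, s1, window_size = 20L)
  expect_true(all(abs(tr0$value) < 0.05))

  # fixed differences at every site give FST 1
  calls <- cbind(matrix(0L, 50, 10), matrix(2L, 50, 10))
  gf <- fix_genoset(calls)
  trf <- fst_scan(gf, gf$samples[1:10], gf$samples[11:20], window_size = 10L)
  expect_true(all(abs(trf$value - 1) < 1e-12))
})

test_that("sib-averaged FST averages retention permutations element-wise", {
  set.seed(12)
  g <- random_genoset(80, 12)
  st <- fix_sample_table(12)
  groups <- data.frame(group = "G1", sample = c("S01", "S03"))
  tr <- fst_scan_sib_averaged(g, st, groups, window_size = 20L,
                              n_perm = 20L, seed = 3L)
  # manual: rebuild the same retention lists and average plain scans
  sites <- sweepscan:::fst_usable_sites(
    g, st$sample[st$phenotype == "resistant"],
    st$sample[st$phenotype == "susceptible"])
  rets <- sib_retention_permutations(st, groups, n_perm = 20L, seed = 3L)
  vals <- sapply(rets, function(keep) {
    fst_scan(g, intersect(st$sample[st$phenotype == "resistant"], keep),
             intersect(st$sample[st$phenotype == "susceptible"], keep),
             window_size = 20L, sites = sites)$value
  })
  expect_equal(tr$value, rowMeans(vals), tolerance = 1e-12)
})

test_that("PBS combines pairwise FST via the branch-length transform", {
  expect_equal(oracle_pbs(0.5, 0.5, 0), -log(0.5), tolerance = 1e-12)
  expect_equal(oracle_pbs(0.1, 0.2, 0.3),
               (0.10536052 + 0.22314355 - 0.35667494) / 2, tolerance = 1e-6)

  set.seed(13)
  g <- random_genoset(90, 30)
  f <- g$samples[1:10]; s <- g$samples[11:20]; o <- g$samples[21:30]
  tr <- pbs_scan(g, f, s, o, window_size = 15L)
  gs <- subset_sites(g, attr(tr, "sites"))
  for (i in seq_len(nrow(tr))) {
    w_fst <- function(g1, g2) oracle_windowed_fst(
      allele_counts(gs, g1), allele_counts(gs, g2), tr$first[i], tr$last[i])
    expect_equal(tr$value[i],
                 oracle_pbs(min(w_fst(f, s), 1 - 1e-12),
                            min(w_fst(f, o), 1 - 1e-12),
                            min(w_fst(s, o), 1 - 1e-12)),
                 tolerance = 1e-10)
  }

  # three identical groups: PBS near zero (exact zero only asymptotically,
  # since Hudson's finite-sample correction leaves each T slightly negative)
  calls <- matrix(rep(rbinom(40, 2, 0.4), 90), 40, 90)
  gi <- fix_genoset(calls)
  tri <- pbs_scan(gi, gi$samples[1:30], gi$samples[31:60],
                  gi$samples[61:90], window_size = 10L)
  expect_true(all(abs(tri$value) < 0.02))

  # monotone in the focal-vs-sister differentiation
  pbs_of <- function(fs) oracle_pbs(fs, 0.4, 0.1)
  vals <- vapply(seq(0.05, 0.9, by = 0.05), pbs_of, numeric(1))
  expect_true(all(diff(vals) > 0))

  expect_error(pbs_scan(g, f, s, c(o, f[1]), 15L), "disjoint")
})

test_that("the mode-based FST peak rule follows its arithmetic", {
  # dense mass at 0.01 with minimum -0.02: threshold 0.01 + 3 * 0.03 = 0.10
  set.seed(14)
  vals <- c(rnorm(500, 0.01, 0.001), -0.02)
  thr <- fst_peak_threshold(vals)
  expect_lt(abs(thr$mode - 0.01), 0.003)
  expect_lt(abs(thr$threshold - 0.10), 0.015)

  # symmetric values dense around 0: mode near 0, threshold near 3*|min|
  vals2 <- c(seq(-0.02, 0.02, by = 0.0005), rnorm(400, 0, 0.004))
  vals2 <- pmax(pmin(vals2, 0.02), -0.02)
  thr2 <- fst_peak_threshold(vals2)
  expect_lt(abs(thr2$mode), 0.004)
  expect_lt(abs(thr2$threshold - 0.06), 0.015)

  # no negative values: undefined threshold, no peaks
  expect_warning(thr3 <- fst_peak_threshold(c(0.01, 0.02, 0.05)),
                 "undefined")
  expect_true(is.na(thr3$threshold))
  tr <- structure(data.frame(contig = "2L", first = 0L, last = 9L,
                             first_pos = 1L, last_pos = 100L, n_snps = 10L,
                             value = 0.05),
                  class = c("window_stat_track", "data.frame"))
  expect_identical(nrow(find_candidate_peaks(tr, NA)), 0L)

  # all-negative track: threshold exists but positivity filters all peaks
  vals4 <- -seq(0.001, 0.05, length.out = 60)
  thr4 <- fst_peak_threshold(vals4)
  tr4 <- structure(data.frame(contig = "2L", first = 0L, last = 9L,
                              first_pos = 1, last_pos = 100, n_snps = 10L,
                              value = vals4[1]),
                   class = c("window_stat_track", "data.frame"))
  expect_identical(nrow(find_candidate_peaks(tr4, thr4$threshold)), 0L)
})

test_that("centile thresholds use linear-interpolation quantiles", {
  expect_equal(centile_peak_threshold(1:100, 95), 3 * 95.05)
  expect_equal(centile_peak_threshold(1:100, 95, multiplier = 1), 95.05)
  # constant track: threshold 3v, no strict exceedances
  vals <- rep(0.2, 50)
  expect_equal(centile_peak_threshold(vals, 98), 0.6)
  expect_false(any(vals > 0.6))
})

test_that("the permutation filter implements the counting rules", {
  set.seed(15)
  cand <- data.frame(contig = "2L", first = 0L, last = 9L, first_pos = 1,
                     last_pos = 100, n_snps = 10L, value = 5)
  st <- fix_sample_table(20)
  # permuted statistic always far below the observed value
  ps <- permutation_filter(cand, function(labels) rnorm(1, 0, 0.01), st,
                           n_perm = 500L, seed = 4L)
  expect_true(ps$retained)
  expect_equal(ps$p_perm, 1 / 501)

  # permuted values always above: never retained, p near 1
  ps2 <- permutation_filter(cand, function(labels) 10 + rnorm(1), st,
                            n_perm = 500L, seed = 4L)
  expect_false(ps2$retained)
  expect_equal(ps2$p_perm, 1)

  # reproducible under the seed, including the permuted label stream
  seen <- list()
  fun <- function(labels) { seen[[length(seen) + 1L]] <<- labels; 0 }
  p1 <- permutation_filter(cand, fun, st, n_perm = 120L, seed = 9L)
  labels1 <- seen; seen <- list()
  p2 <- permutation_filter(cand, fun, st, n_perm = 120L, seed = 9L)
  expect_identical(labels1, seen)
  expect_identical(p1, p2)

  # strata: labels permute within location only
  st2 <- fix_sample_table(10, location = rep(c("Moshi", "Muleba"), each = 5))
  fun2 <- function(labels) {
    expect_identical(sort(labels[1:5]), sort(st2$phenotype[1:5]))
    expect_identical(sort(labels[6:10]), sort(st2$phenotype[6:10]))
    0
  }
  invisible(permutation_filter(cand, fun2, st2, n_perm = 100L, seed = 1L))

  expect_warning(permutation_filter(cand, function(l) 0, st, n_perm = 50L,
                                    seed = 1L), "unstable")
  # empty candidates pass through untouched
  ps0 <- permutation_filter(cand[0, ], function(l) numeric(), st,
                            n_perm = 100L, seed = 1L)
  expect_identical(nrow(ps0), 0L)
})
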