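#' Per-site allele counts for a group of samples
#'
#' @param g a [genotype_set()].
#' @param samples sample ids of the group.
#' @return Integer matrix, sites x 2 (`ref`, `alt` allele counts over
#'   non-missing calls).
#' @export
allele_counts <- function(g, samples) {
  calls <- g$calls[, g$samples %in% samples, drop = FALSE]
  alt <- rowSums(calls, na.rm = TRUE)
  an <- 2L * rowSums(!is.na(calls))
  cbind(ref = an - alt, alt = alt)
}

# Precomputed matrices for repeated group allele counts (BLAS products
# against a group indicator instead of per-call row sums).
ac_cache <- function(gs) {
  Z <- !is.na(gs$calls)
  M <- gs$calls
  M[!Z] <- 0L
  list(M = M * 1, Z = Z * 1, samples = gs$samples)
}

ac_from_cache <- function(cache, ids) {
  ind <- as.numeric(cache$samples %in% ids)
  alt <- drop(cache$M %*% ind)
  an <- 2 * drop(cache$Z %*% ind)
  cbind(ref = an - alt, alt = alt)
}

#' Per-site Hudson FST components
#'
#' Returns the numerator and denominator of Hudson's estimator so windowed
#' FST can be combined as a ratio of sums:
#' `num = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`,
#' `den = p1(1-p2) + p2(1-p1)`,
#' with `p` the alt-allele frequency and `n` the allele count in each
#' population. Both populations need at least 2 called alleles per site.
#'
#' @param ac1,ac2 allele-count matrices (sites x 2) from [allele_counts()].
#' @return A `data.frame` with columns `num`, `den`.
#' @export
hudson_fst_components <- function(ac1, ac2) {
  n1 <- rowSums(ac1); n2 <- rowSums(ac2)
  if (any(n1 < 2) || any(n2 < 2))
    stop("each population needs >= 2 called alleles at every site")
  p1 <- ac1[, 2] / n1; p2 <- ac2[, 2] / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  data.frame(num = num, den = den)
}

# Sites usable for FST between two sample groups: no missing calls in
# either group and combined minor allele count > 1 (singletons removed).
fst_usable_sites <- function(g, samples1, samples2) {
  c1 <- g$calls[, g$samples %in% samples1, drop = FALSE]
  c2 <- g$calls[, g$samples %in% samples2, drop = FALSE]
  no_miss <- !(rowSums(is.na(c1)) > 0L | rowSums(is.na(c2)) > 0L)
  ac <- rowSums(c1, na.rm = TRUE) + rowSums(c2, na.rm = TRUE)
  an <- 2L * (ncol(c1) + ncol(c2))
  mac <- pmin(ac, an - ac)
  which(no_miss & mac > 1L)
}

windowed_ratio_of_sums <- function(components, windows) {
  vapply(seq_len(nrow(windows)), function(i) {
    idx <- seq.int(windows$first[i] + 1L, windows$last[i] + 1L)
    s <- sum(components$den[idx])
    if (s <= 0) return(NA_real_)
    sum(components$num[idx]) / s
  }, numeric(1))
}

#' Windowed Hudson FST scan between two sample groups
#'
#' Sites with missing calls in either group or with combined minor allele
#' count <= 1 are excluded, windows of `window_size` SNPs are built on the
#' remaining sites, and each window's FST is the ratio of summed numerators
#' to summed denominators.
#'
#' @param g a [genotype_set()].
#' @param samples1,samples2 the two sample groups (>= 2 samples each).
#' @param window_size window size in SNPs (default 1000).
#' @param step window step in SNPs.
#' @param sites optional precomputed usable-site indices (internal use).
#' @return A `window_stat_track`; the site indices used are in
#'   `attr(, "sites")`.
#' @export
fst_scan <- function(g, samples1, samples2, window_size = 1000L,
                     step = window_size, sites = NULL) {
  if (length(samples1) < 2L || length(samples2) < 2L)
    stop("each group needs at least 2 samples")
  if (is.null(sites)) sites <- fst_usable_sites(g, samples1, samples2)
  gs <- subset_sites(g, sites)
  comp <- hudson_fst_components(allele_counts(gs, samples1),
                                allele_counts(gs, samples2))
  windows <- make_snp_windows(gs$sites, window_size, step)
  windows$first_global <- sites[windows$first + 1L] - 1L
  windows$last_global <- sites[windows$last + 1L] - 1L
  tr <- scan_track(windows, windowed_ratio_of_sums(comp, windows), "FST")
  attr(tr, "sites") <- sites
  tr
}

#' Sib-permutation-averaged FST scan
#'
#' Recomputes the resistant-vs-susceptible FST track once per sib retention
#' permutation (each permutation keeps one random member per sib group) and
#' averages the tracks element-wise, using the full sample set without
#' pseudo-replicating sibs. Site filtering and the window grid are fixed
#' from the full sample set so all permutations share one grid.
#'
#' @param g a [genotype_set()].
#' @param st a [sample_table()] (phenotype defines the two groups).
#' @param sib_groups sib-group table from [find_sib_groups()].
#' @param window_size,step window size/step in SNPs.
#' @param n_perm number of retention permutations (default 100).
#' @param seed integer seed.
#' @return A `window_stat_track` of the mean FST per window.
#' @export
fst_scan_sib_averaged <- function(g, st, sib_groups, window_size = 1000L,
                                  step = window_size, n_perm = 100L, seed) {
  res_ids <- st$sample[st$phenotype == "resistant"]
  sus_ids <- st$sample[st$phenotype == "susceptible"]
  sites <- fst_usable_sites(g, res_ids, sus_ids)
  gs <- subset_sites(g, sites)
  windows <- make_snp_windows(gs$sites, window_size, step)
  cache <- ac_cache(gs)
  retentions <- sib_retention_permutations(st, sib_groups, n_perm, seed)
  vals <- rowMeans(vapply(retentions, function(keep) {
    comp <- hudson_fst_components(
      ac_from_cache(cache, intersect(res_ids, keep)),
      ac_from_cache(cache, intersect(sus_ids, keep)))
    windowed_ratio_of_sums(comp, windows)
  }, numeric(nrow(windows))))
  windows$first_global <- sites[windows$first + 1L] - 1L
  windows$last_global <- sites[windows$last + 1L] - 1L
  tr <- scan_track(windows, vals, "FST_sib_averaged")
  attr(tr, "sites") <- sites
  tr
}

#' Windowed population branch statistic (PBS)
#'
#' Restricted to sites segregating across the union of the three groups.
#' Within each window, pairwise Hudson FST (ratio of sums) is transformed as
#' `T = -ln(1 - FST)` (FST clipped to `1 - 1e-12`), and
#' `PBS_focal = (T_fs + T_fo - T_so) / 2`, isolating allele-frequency change
#' on the focal branch.
#'
#' @param g a [genotype_set()].
#' @param focal,sister,outgroup disjoint sample-id groups.
#' @param window_size,step window size/step in SNPs.
#' @return A `window_stat_track` of PBS values.
#' @export
pbs_scan <- function(g, focal, sister, outgroup, window_size = 1000L,
                     step = window_size) {
  all_ids <- c(focal, sister, outgroup)
  if (anyDuplicated(all_ids)) stop("groups must be disjoint")
  calls <- g$calls[, g$samples %in% all_ids, drop = FALSE]
  no_miss <- rowSums(is.na(calls)) == 0L
  ac <- rowSums(calls, na.rm = TRUE)
  seg <- no_miss & ac > 0L & ac < 2L * ncol(calls)
  sites <- which(seg)
  gs <- subset_sites(g, sites)
  windows <- make_snp_windows(gs$sites, window_size, step)
  comp_fs <- hudson_fst_components(allele_counts(gs, focal),
                                   allele_counts(gs, sister))
  comp_fo <- hudson_fst_components(allele_counts(gs, focal),
                                   allele_counts(gs, outgroup))
  comp_so <- hudson_fst_components(allele_counts(gs, sister),
                                   allele_counts(gs, outgroup))
  tt <- function(comp) {
    fst <- windowed_ratio_of_sums(comp, windows)
    -log(1 - pmin(fst, 1 - 1e-12))
  }
  pbs <- (tt(comp_fs) + tt(comp_fo) - tt(comp_so)) / 2
  tr <- scan_track(windows, pbs, "PBS")
  attr(tr, "sites") <- sites
  tr
}

#' Mode-based FST peak threshold
#'
#' The genome-wide FST mode is estimated by Gaussian kernel density
#' (Silverman's rule-of-thumb bandwidth, argmax on a 512-point grid spanning
#' the data range); the peak threshold is the mode plus three times the
#' distance from the mode to the smallest (most negative) value:
#' `threshold = mode + 3 * (mode - min(values))`. Peaks are windows with
#' `value > threshold` and `value > 0`.
#'
#' @param values windowed FST values (must include at least one negative
#'   value for the rule to be defined).
#' @param multiplier distance multiplier (default 3).
#' @return A list with `mode` and `threshold` (`threshold = NA` with a
#'   warning when no value is negative).
#' @export
fst_peak_threshold <- function(values, multiplier = 3) {
  values <- values[is.finite(values)]
  d <- stats::density(values, bw = "nrd0", n = 512,
                      from = min(values), to = max(values))
  mode <- d$x[which.max(d$y)]
  if (!any(values < 0)) {
    warning("no negative FST values: peak threshold undefined")
    return(list(mode = mode, threshold = NA_real_))
  }
  list(mode = mode, threshold = mode + multiplier * (mode - min(values)))
}

#' Centile-based peak threshold
#'
#' `threshold = multiplier * quantile(values, centile / 100)` with
#' linear-interpolation quantiles. The defaults used in practice are the
#' 95th centile for PBS and the 98th for H12/deltaH12, both with
#' multiplier 3.
#'
#' @param values windowed statistic values.
#' @param centile centile in percent (e.g. 95).
#' @param multiplier threshold multiplier (default 3).
#' @return Numeric threshold.
#' @export
centile_peak_threshold <- function(values, centile, multiplier = 3) {
  multiplier * stats::quantile(values[is.finite(values)], centile / 100,
                               type = 7, names = FALSE)
}

#' Candidate peak windows above a threshold
#'
#' @param track a `window_stat_track`.
#' @param threshold numeric threshold (NA gives no peaks).
#' @param positive_only additionally require `value > 0`.
#' @return The subset of track rows exceeding the threshold.
#' @export
find_candidate_peaks <- function(track, threshold, positive_only = TRUE) {
  if (is.na(threshold)) return(track[0, , drop = FALSE])
  keep <- is.finite(track$value) & track$value > threshold
  if (positive_only) keep <- keep & track$value > 0
  track[keep, , drop = FALSE]
}

#' Phenotype-permutation filter for candidate peaks
#'
#' Distinguishes true phenotype association from the mere presence of a
#' selective sweep: phenotype labels are permuted within location strata,
#' the windowed statistic is recomputed on the candidate windows for each
#' permutation, and a peak is retained iff its observed value exceeds the
#' `retain_quantile` empirical quantile of its permuted values. The
#' counting p-value `(1 + #[perm >= obs]) / (n_perm + 1)` is reported
#' alongside.
#'
#' @param candidates candidate windows (rows of a `window_stat_track`,
#'   column `value` holds the observed statistic).
#' @param stat_fun function(phenotype_labels) returning the statistic for
#'   the candidate windows under the given labels (same order/length as
#'   `candidates`). See [make_fst_stat_fun()] and [make_delta_h12_stat_fun()].
#' @param st a [sample_table()]; `st$location` defines permutation strata.
#' @param n_perm number of permutations (default 500; fewer than 100 gives
#'   an unstable quantile and a warning).
#' @param retain_quantile retention quantile (default 0.99).
#' @param seed integer seed.
#' @return A `data.frame` of class `peak_set`: candidate columns plus
#'   `observed`, `p_perm`, `retained`.
#' @export
permutation_filter <- function(candidates, stat_fun, st, n_perm = 500L,
                               retain_quantile = 0.99, seed) {
  if (n_perm < 100L) warning("n_perm < 100: retention quantile is unstable")
  set.seed(seed)
  obs <- candidates$value
  if (!nrow(candidates)) {
    out <- cbind(candidates[0, , drop = FALSE],
                 observed = numeric(), p_perm = numeric(),
                 retained = logical())
    class(out) <- c("peak_set", "data.frame")
    return(out)
  }
  strata <- st$location
  perm_vals <- matrix(NA_real_, n_perm, length(obs))
  for (i in seq_len(n_perm)) {
    labels <- st$phenotype
    for (s in unique(strata)) {
      idx <- which(strata == s)
      labels[idx] <- labels[sample(idx)]
    }
    perm_vals[i, ] <- stat_fun(labels)
  }
  q <- apply(perm_vals, 2L, stats::quantile, probs = retain_quantile,
             type = 7, na.rm = TRUE, names = FALSE)
  p <- vapply(seq_along(obs), function(j) {
    (1 + sum(perm_vals[, j] >= obs[j], na.rm = TRUE)) / (n_perm + 1)
  }, numeric(1))
  out <- candidates
  out$observed <- obs
  out$p_perm <- p
  out$retained <- obs > q
  class(out) <- c("peak_set", "data.frame")
  out
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d candidate window(s), %d retained\n",
              nrow(x), sum(x$retained)))
  invisible(x)
}

#' Statistic recomputation closures for the permutation filter
#'
#' `make_fst_stat_fun()` returns a function recomputing windowed Hudson FST
#' (resistant vs susceptible under permuted labels) at the candidate
#' windows; `make_delta_h12_stat_fun()` does the same for deltaH12;
#' `make_pbs_stat_fun()` for PBS with a fixed outgroup. Site filtering and
#' window bounds are frozen from the observed scan so permutations only
#' relabel phenotypes.
#'
#' @param g a [genotype_set()].
#' @param track the observed `window_stat_track` the candidates came from.
#' @param candidates candidate window rows.
#' @param st a [sample_table()].
#' @return A function(labels) -> numeric vector of candidate-window values.
#' @export
make_fst_stat_fun <- function(g, track, candidates, st) {
  sites <- attr(track, "sites")
  gs <- subset_sites(g, sites)
  # restrict to the sites inside candidate windows; remap window bounds
  idx_list <- lapply(seq_len(nrow(candidates)), function(i)
    seq.int(candidates$first[i] + 1L, candidates$last[i] + 1L))
  all_idx <- unlist(idx_list)
  gs <- subset_sites(gs, all_idx)
  len <- lengths(idx_list)
  win <- data.frame(first = cumsum(c(0L, len[-length(len)])),
                    last = cumsum(len) - 1L)
  samples <- st$sample
  cache <- ac_cache(gs)
  function(labels) {
    s1 <- samples[labels == "resistant"]
    s2 <- samples[labels == "susceptible"]
    comp <- hudson_fst_components(ac_from_cache(cache, s1),
                                  ac_from_cache(cache, s2))
    windowed_ratio_of_sums(comp, win)
  }
}

#' @rdname make_fst_stat_fun
#' @param h a [haplotype_set()] (deltaH12 variant).
#' @export
make_delta_h12_stat_fun <- function(h, candidates, st) {
  hap_sample <- h$haplotypes$sample
  # haplotype identity strings per candidate window are label-independent:
  # compute once, then each permutation only re-splits them by phenotype
  codes <- lapply(seq_len(nrow(candidates)), function(i) {
    idx <- seq.int(candidates$first[i] + 1L, candidates$last[i] + 1L)
    s <- hap_strings(h$alleles[idx, , drop = FALSE])
    match(s, unique(s))  # integer haplotype codes: identity is all we need
  })
  h12_of <- function(x) {
    p <- tabulate(x) / length(x)
    unname(garud_h(p[p > 0])["H12"])
  }
  function(labels) {
    pheno <- stats::setNames(labels, st$sample)[hap_sample]
    res_cols <- pheno == "resistant"
    vapply(codes, function(x) {
      h12_of(x[res_cols]) - h12_of(x[!res_cols])
    }, numeric(1))
  }
}

#' @rdname make_fst_stat_fun
#' @param outgroup fixed outgroup sample ids (PBS variant); `st` must cover
#'   only the focal+sister (phenotyped) samples whose labels are permuted.
#' @export
make_pbs_stat_fun <- function(g, track, candidates, st, outgroup) {
  gs <- subset_sites(g, attr(track, "sites"))
  idx_list <- lapply(seq_len(nrow(candidates)), function(i)
    seq.int(candidates$first[i] + 1L, candidates$last[i] + 1L))
  gs <- subset_sites(gs, unlist(idx_list))
  len <- lengths(idx_list)
  win <- data.frame(first = cumsum(c(0L, len[-length(len)])),
                    last = cumsum(len) - 1L)
  samples <- st$sample
  cache <- ac_cache(gs)
  ac_out <- ac_from_cache(cache, outgroup)
  function(labels) {
    ac1 <- ac_from_cache(cache, samples[labels == "resistant"])
    ac2 <- ac_from_cache(cache, samples[labels == "susceptible"])
    tt <- function(comp) {
      fst <- windowed_ratio_of_sums(comp, win)
      -log(1 - pmin(fst, 1 - 1e-12))
    }
    (tt(hudson_fst_components(ac1, ac2)) +
       tt(hudson_fst_components(ac1, ac_out)) -
       tt(hudson_fst_components(ac2, ac_out))) / 2
  }
}
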