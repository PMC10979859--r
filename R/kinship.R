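#' KING-robust pairwise kinship from called genotypes
#'
#' For each sample pair (i, j) the estimator is
#' `phi = (N_HetHet - 2 * N_OppHom) / (N_Het(i) + N_Het(j))`
#' over the loci called in both samples, where `N_HetHet` counts loci at
#' which both are heterozygous, `N_OppHom` counts opposite homozygotes, and
#' `N_Het(.)` counts heterozygous loci of each sample restricted to the
#' shared loci. Expected values: 0.5 for self, about 0.25 for full sibs,
#' near 0 for unrelated samples. Sites inside `exclude_regions` (e.g.
#' chromosomal inversions, which distort relatedness) are removed first.
#'
#' @param g a [genotype_set()].
#' @param exclude_regions optional [gene_region()] table of spans to drop.
#' @return An object of class `kinship_matrix`: `samples`, `phi` (symmetric
#'   matrix, diagonal 0.5, `NA` where the denominator is 0), `n_loci`
#'   (informative loci per pair).
#' @export
king_kinship <- function(g, exclude_regions = NULL) {
  stopifnot(inherits(g, "genotype_set"))
  calls <- g$calls
  if (!is.null(exclude_regions) && nrow(exclude_regions)) {
    drop <- rep(FALSE, nrow(g$sites))
    for (r in seq_len(nrow(exclude_regions))) {
      drop <- drop | (g$sites$contig == exclude_regions$contig[r] &
                      pos_in_region(g$sites$pos, exclude_regions$start[r],
                                    exclude_regions$end[r]))
    }
    calls <- calls[!drop, , drop = FALSE]
  }
  nonmiss <- !is.na(calls)
  het <- nonmiss & calls == 1L
  homref <- nonmiss & calls == 0L
  homalt <- nonmiss & calls == 2L
  mode(het) <- "numeric"; mode(homref) <- "numeric"
  mode(homalt) <- "numeric"; mode(nonmiss) <- "numeric"
  n_hethet <- crossprod(het)
  n_opp <- crossprod(homref, homalt)
  n_opp <- n_opp + t(n_opp)
  n_het_i <- crossprod(het, nonmiss)        # het in i, called in j
  denom <- n_het_i + t(n_het_i)
  n_loci <- crossprod(nonmiss)
  if (any(denom == 0))
    warning("pair(s) with zero heterozygous loci: kinship undefined (NA)")
  phi <- (n_hethet - 2 * n_opp) / denom
  phi[denom == 0] <- NA_real_
  dimnames(phi) <- list(g$samples, g$samples)
  structure(list(samples = g$samples, phi = phi, n_loci = n_loci),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  off <- x$phi[upper.tri(x$phi)]
  cat(sprintf("<kinship_matrix> %d samples; off-diagonal phi: median %.4f, max %.4f\n",
              length(x$samples), stats::median(off, na.rm = TRUE),
              max(off, na.rm = TRUE)))
  invisible(x)
}

#' Identify sib groups from a kinship matrix
#'
#' Sib groups are the connected components of the graph whose edges join
#' pairs with `phi >= threshold`; singleton components are dropped.
#'
#' @param k a `kinship_matrix`.
#' @param threshold KING value above which a pair is classified as full sibs
#'   (default 0.185).
#' @return A `data.frame` with columns `group`, `sample` (empty when no pair
#'   reaches the threshold).
#' @export
find_sib_groups <- function(k, threshold = 0.185) {
  stopifnot(inherits(k, "kinship_matrix"))
  adj <- !is.na(k$phi) & k$phi >= threshold
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)
  keep <- which(comp$csize >= 2L)
  if (!length(keep))
    return(data.frame(group = character(), sample = character()))
  out <- do.call(rbind, lapply(seq_along(keep), function(i) {
    members <- k$samples[comp$membership == keep[i]]
    data.frame(group = sprintf("G%03d", i), sample = members,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Flag samples whose kinship profile suggests cross-contamination
#'
#' Contaminated samples show universally elevated kinship to all others
#' (driven by excess heterozygosity). A sample is flagged when its median
#' kinship to all other samples exceeds the `kin_quantile` quantile of the
#' per-sample medians AND its heterozygosity z-score against the cohort
#' exceeds `het_z`.
#'
#' @param k a `kinship_matrix`.
#' @param g the matching [genotype_set()].
#' @param kin_quantile quantile cutoff on per-sample median kinship
#'   (default 0.99).
#' @param het_z heterozygosity z-score cutoff (default 4).
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
flag_contaminated <- function(k, g, kin_quantile = 0.99, het_z = 4) {
  n <- length(k$samples)
  if (n < 2L) return(character())
  phi <- k$phi
  diag(phi) <- NA
  med_kin <- apply(phi, 2L, stats::median, na.rm = TRUE)
  het_rate <- colMeans(g$calls == 1L, na.rm = TRUE)
  z <- (het_rate - mean(het_rate)) / stats::sd(het_rate)
  cutoff <- stats::quantile(med_kin, kin_quantile, na.rm = TRUE, names = FALSE)
  flagged <- med_kin > cutoff & !is.na(z) & z > het_z
  k$samples[which(flagged)]
}

#' Retain one sample per sib group
#'
#' `dedup_sibs()` keeps one randomly chosen member per sib group plus every
#' sample outside any group. `sib_retention_permutations()` repeats the
#' random choice `n_perm` times, giving the retention lists over which
#' windowed statistics are averaged.
#'
#' @param st a [sample_table()].
#' @param groups sib-group `data.frame` (columns `group`, `sample`) as
#'   returned by [find_sib_groups()]; `NULL`/empty means no sibs.
#' @param seed integer seed.
#' @return `dedup_sibs()`: character vector of retained ids (in `st` order);
#'   `sib_retention_permutations()`: list of `n_perm` such vectors.
#' @export
dedup_sibs <- function(st, groups, seed) {
  set.seed(seed)
  one_retention(st, groups)
}

one_retention <- function(st, groups) {
  drop <- character()
  if (!is.null(groups) && nrow(groups)) {
    for (gid in unique(groups$group)) {
      members <- groups$sample[groups$group == gid]
      keep <- sample(members, 1L)
      drop <- c(drop, setdiff(members, keep))
    }
  }
  st$sample[!st$sample %in% drop]
}

#' @rdname dedup_sibs
#' @param n_perm number of retention permutations.
#' @export
sib_retention_permutations <- function(st, groups, n_perm, seed) {
  set.seed(seed)
  lapply(seq_len(n_perm), function(i) one_retention(st, groups))
}
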