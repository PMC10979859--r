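#' Pairwise haplotype distance (Dxy)
#'
#' Dxy between two haplotypes is the proportion of sites at which their
#' alleles differ, computed over the sites of `region` (or all sites).
#'
#' @param h a [haplotype_set()].
#' @param region optional one-row [gene_region()] restricting the sites.
#' @param sites optional 1-based site indices (overrides `region`).
#' @return Symmetric numeric matrix with zero diagonal, one row/column per
#'   haplotype.
#' @export
pairwise_dxy <- function(h, region = NULL, sites = NULL) {
  stopifnot(inherits(h, "haplotype_set"))
  if (is.null(sites)) {
    sites <- if (is.null(region)) seq_len(nrow(h$sites)) else
      which(h$sites$contig == region$contig &
              pos_in_region(h$sites$pos, region$start, region$end))
  }
  if (!length(sites)) stop("no sites in region")
  a <- h$alleles[sites, , drop = FALSE]
  # for 0/1 alleles, differing sites = x + y - 2xy summed over sites
  cp <- crossprod(a)
  cs <- colSums(a)
  diffs <- outer(cs, cs, "+") - 2 * cp
  diffs / length(sites)
}

#' Cluster haplotypes by hierarchical clustering on Dxy
#'
#' Average-linkage (UPGMA) agglomerative clustering; flat clusters are
#' obtained by cutting the dendrogram at `cut_height` on cophenetic height.
#' Clusters smaller than `min_size` are kept but flagged untestable.
#'
#' @param distmat Dxy matrix from [pairwise_dxy()].
#' @param cut_height tree-cut height (default 0.001 on the Dxy scale, i.e.
#'   haplotypes in a cluster are essentially identical).
#' @param min_size minimum cluster size eligible for association testing
#'   (default 20 haplotypes).
#' @return An object of class `hap_cluster_set`: `assign` (integer cluster
#'   id per haplotype, named), `sizes`, `testable` (logical per cluster),
#'   `cut_height`, `min_size`.
#' @export
cluster_haplotypes <- function(distmat, cut_height = 0.001, min_size = 20L) {
  if (nrow(distmat) < 2L) stop("need at least 2 haplotypes to cluster")
  hc <- stats::hclust(stats::as.dist(distmat), method = "average")
  # guard against floating-point jitter breaking UPGMA height monotonicity
  hc$height <- cummax(round(hc$height, 10))
  assign <- stats::cutree(hc, h = cut_height)
  sizes <- as.integer(table(assign))
  structure(list(assign = assign, sizes = sizes,
                 testable = sizes >= min_size,
                 cut_height = cut_height, min_size = as.integer(min_size)),
            class = "hap_cluster_set")
}

#' @export
print.hap_cluster_set <- function(x, ...) {
  cat(sprintf("<hap_cluster_set> %d haplotypes in %d clusters (%d testable, cut %.4g)\n",
              length(x$assign), length(x$sizes), sum(x$testable),
              x$cut_height))
  invisible(x)
}

#' Cluster-phenotype association
#'
#' For each testable cluster (size >= `min_size`), each sample's dose is its
#' number of member haplotypes (0, 1 or 2); a binomial-logit GLM of
#' phenotype (resistant = 1) on dose gives the Wald p-value and the
#' coefficient sign. Positive coefficients mean the cluster is enriched in
#' resistant samples.
#'
#' @param clusters a `hap_cluster_set`.
#' @param h the clustered [haplotype_set()] (maps haplotypes to samples).
#' @param st a [sample_table()] covering `h`'s samples.
#' @return A `data.frame`: `cluster`, `size`, `estimate`, `p`, with one row
#'   per testable cluster (zero rows when none is testable).
#' @export
cluster_association <- function(clusters, h, st) {
  stopifnot(inherits(clusters, "hap_cluster_set"))
  pheno <- stats::setNames(st$phenotype, st$sample)[h$samples]
  y <- as.integer(pheno == "resistant")
  testable <- which(clusters$testable)
  out <- lapply(testable, function(cl) {
    member <- clusters$assign == cl
    dose <- vapply(seq_along(h$samples), function(s) {
      sum(member[c(2L * s - 1L, 2L * s)])
    }, integer(1))
    if (length(unique(dose)) < 2L) return(NULL)  # constant dose: untestable
    fit <- glm_binomial(y, data.frame(dose = dose))
    row <- fit$table[fit$table$term == "dose", ]
    if (!nrow(row)) return(NULL)  # constant dose: term dropped
    data.frame(cluster = cl, size = sum(member),
               estimate = row$estimate, p = row$p)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(cluster = integer(), size = integer(),
                                      estimate = numeric(), p = numeric())
  out
}

#' Filter peaks on the presence of a resistance-associated haplotype
#'
#' A differentiation peak caused by a true resistance sweep should contain a
#' haplotype cluster positively associated with the resistant phenotype.
#' For each peak window, haplotypes are clustered on Dxy within the window
#' and tested for association; the peak is retained iff some testable
#' cluster has a positive coefficient with `p < alpha`.
#'
#' @param peaks a `peak_set` (or any window table) to filter.
#' @param h a [haplotype_set()] on the sites the peak indices refer to.
#' @param st a [sample_table()].
#' @param cut_height,min_size clustering parameters (see
#'   [cluster_haplotypes()]).
#' @param alpha association significance level (default 0.05).
#' @return `peaks` with a logical column `cluster_retained` added (and
#'   `retained`, when present, AND-ed with it).
#' @export
filter_peaks_by_cluster <- function(peaks, h, st, cut_height = 0.001,
                                    min_size = 20L, alpha = 0.05) {
  if (!nrow(peaks)) {
    peaks$cluster_retained <- logical()
    return(peaks)
  }
  # peaks built on a filtered site subset carry first_global/last_global
  # indices into the unfiltered site table that `h` is defined on
  first <- if ("first_global" %in% names(peaks)) peaks$first_global else peaks$first
  last <- if ("last_global" %in% names(peaks)) peaks$last_global else peaks$last
  keep <- vapply(seq_len(nrow(peaks)), function(i) {
    idx <- seq.int(first[i] + 1L, last[i] + 1L)
    if (1 / length(idx) > cut_height) {
      # any two non-identical haplotypes differ by >= 1/n_sites > cut
      # height, so every linkage merges below the cut only at distance 0:
      # flat clusters are exactly the allele-string equivalence classes
      strs <- hap_strings(h$alleles[idx, , drop = FALSE])
      assign <- match(strs, unique(strs))
      sizes <- tabulate(assign)
      cl <- structure(list(assign = assign, sizes = sizes,
                           testable = sizes >= min_size,
                           cut_height = cut_height,
                           min_size = as.integer(min_size)),
                      class = "hap_cluster_set")
    } else {
      d <- pairwise_dxy(h, sites = idx)
      cl <- cluster_haplotypes(d, cut_height, min_size)
    }
    if (!any(cl$testable)) return(FALSE)
    assoc <- suppressWarnings(cluster_association(cl, h, st))
    any(assoc$estimate > 0 & assoc$p < alpha, na.rm = TRUE)
  }, logical(1))
  peaks$cluster_retained <- keep
  if ("retained" %in% names(peaks)) peaks$retained <- peaks$retained & keep
  peaks
}
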