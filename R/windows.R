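#' Filter sites on minor allele count and missingness
#'
#' Retains sites whose minor allele count (over non-missing calls) is at
#' least `min_mac` and whose missing-call fraction is at most `max_missing`.
#' Site order is preserved; an empty result is permitted.
#'
#' @param g a [genotype_set()].
#' @param min_mac minimum minor allele count (default 5, with `max_missing = 0`,
#'   is the standard GWAS input filter).
#' @param max_missing maximum tolerated fraction of missing calls per site.
#' @return A filtered [genotype_set()]; the retained site indices are
#'   available as `attr(, "kept")`.
#' @export
filter_sites <- function(g, min_mac = 5L, max_missing = 0) {
  stopifnot(inherits(g, "genotype_set"), min_mac >= 0)
  nonmiss <- rowSums(!is.na(g$calls))
  ac <- rowSums(g$calls, na.rm = TRUE)
  an <- 2L * nonmiss
  mac <- pmin(ac, an - ac)
  miss_frac <- 1 - nonmiss / length(g$samples)
  keep <- which(mac >= min_mac & miss_frac <= max_missing)
  out <- subset_sites(g, keep)
  attr(out, "kept") <- keep
  out
}

#' Subset a genotype or haplotype set by site index and/or sample id
#'
#' @param x a [genotype_set()] or [haplotype_set()].
#' @param sites integer site indices (1-based, kept in the given order).
#' @param samples character sample ids to keep.
#' @return An object of the same class.
#' @export
subset_sites <- function(x, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(nrow(x$sites))
  # components of a valid object stay valid under subsetting: rebuild
  # directly instead of re-running constructor validation
  if (inherits(x, "genotype_set")) {
    keep_s <- if (is.null(samples)) x$samples else x$samples[x$samples %in% samples]
    structure(list(sites = x$sites[sites, , drop = FALSE], samples = keep_s,
                   calls = x$calls[sites, keep_s, drop = FALSE]),
              class = "genotype_set")
  } else if (inherits(x, "haplotype_set")) {
    keep_s <- if (is.null(samples)) x$samples else x$samples[x$samples %in% samples]
    cols <- as.vector(rbind(match(keep_s, x$samples) * 2L - 1L,
                            match(keep_s, x$samples) * 2L))
    structure(list(sites = x$sites[sites, , drop = FALSE], samples = keep_s,
                   haplotypes = data.frame(
                     sample = rep(keep_s, each = 2L),
                     phase = rep.int(1:2, length(keep_s)),
                     stringsAsFactors = FALSE),
                   alleles = x$alleles[sites, cols, drop = FALSE]),
              class = "haplotype_set")
  } else stop("unsupported class")
}

#' Build windows of a fixed number of SNPs
#'
#' Windows are defined on site indices (0-based, inclusive bounds). The
#' default step equals the window size (non-overlapping windows); a trailing
#' partial window is dropped so every emitted window holds exactly
#' `window_size` SNPs. Windows never span contigs.
#'
#' @param sites a site table ([site_info()]).
#' @param window_size number of SNPs per window (>= 2).
#' @param step step between window starts in SNPs (default `window_size`).
#' @return A `data.frame` with columns `contig`, `first`, `last` (0-based
#'   site indices into `sites`), `first_pos`, `last_pos`, `n_snps`. Empty
#'   when no contig holds `window_size` sites.
#' @export
make_snp_windows <- function(sites, window_size, step = window_size) {
  stopifnot(window_size >= 2L, step >= 1L)
  out <- list()
  for (ctg in unique(sites$contig)) {
    idx <- which(sites$contig == ctg)
    n <- length(idx)
    if (n < window_size) next
    first_local <- seq(0L, n - window_size, by = step)
    first <- idx[first_local + 1L] - 1L
    last <- idx[first_local + window_size] - 1L
    out[[ctg]] <- data.frame(
      contig = ctg, first = first, last = last,
      first_pos = sites$pos[first + 1L], last_pos = sites$pos[last + 1L],
      n_snps = window_size, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(contig = character(), first = integer(),
                      last = integer(), first_pos = integer(),
                      last_pos = integer(), n_snps = integer()))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# 1-based site indices covered by one SNP window row.
window_site_idx <- function(w) seq.int(w$first + 1L, w$last + 1L)
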