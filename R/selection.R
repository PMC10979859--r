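#' Haplotype frequency spectrum within a SNP window
#'
#' Haplotype identity is exact allele-string match over the window's sites.
#'
#' @param h a [haplotype_set()].
#' @param w one row of a window table from [make_snp_windows()] (or a list
#'   with `first`/`last` 0-based site indices).
#' @param haps optional column indices restricting the haplotypes used.
#' @return Named numeric vector of haplotype frequencies (names are the
#'   allele strings), sorted in decreasing order; sums to 1.
#' @export
hap_frequencies <- function(h, w, haps = NULL) {
  idx <- seq.int(w$first + 1L, w$last + 1L)
  block <- h$alleles[idx, haps %||% seq_len(ncol(h$alleles)), drop = FALSE]
  strs <- hap_strings(block)
  tab <- sort(table(strs), decreasing = TRUE)
  stats::setNames(as.numeric(tab) / length(strs), names(tab))
}

# Allele-string identity per haplotype column, via one vectorised paste0
# over the window's rows.
hap_strings <- function(block) {
  do.call(paste0, as.data.frame(t(block), optional = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Garud's H1 and H12 haplotype homozygosity
#'
#' `H1 = sum(p_i^2)`; `H12 = (p1 + p2)^2 + sum_{i>=3} p_i^2`, pooling the
#' two most frequent haplotypes so that soft sweeps (two high-frequency
#' haplotypes) score highly. A window with a single haplotype has
#' `H1 = H12 = 1`.
#'
#' @param freqs haplotype frequency spectrum (sorted internally).
#' @return Named numeric vector `c(H1 = , H12 = )`.
#' @export
garud_h <- function(freqs) {
  if (!length(freqs)) stop("empty haplotype frequency spectrum")
  p <- sort(as.numeric(freqs), decreasing = TRUE)
  h1 <- sum(p^2)
  h12 <- if (length(p) == 1L) h1 else
    (p[1] + p[2])^2 + sum(p[-(1:2)]^2)
  c(H1 = h1, H12 = h12)
}

#' Cross-population haplotype sharing H1X
#'
#' `H1X = sum_i p_ia * p_ib` over the union of distinct haplotypes, where
#' `p_ia`, `p_ib` are haplotype i's frequencies in populations a and b. High
#' values indicate that high-frequency (swept) haplotypes are shared.
#'
#' @param freqs_a,freqs_b named frequency spectra (names identify
#'   haplotypes across populations).
#' @return Numeric H1X value.
#' @export
h1x <- function(freqs_a, freqs_b) {
  shared <- intersect(names(freqs_a), names(freqs_b))
  if (!length(shared)) return(0)
  sum(as.numeric(freqs_a[shared]) * as.numeric(freqs_b[shared]))
}

scan_track <- function(windows, values, statistic) {
  out <- cbind(windows, value = as.numeric(values))
  attr(out, "statistic") <- statistic
  class(out) <- c("window_stat_track", "data.frame")
  out
}

#' @export
print.window_stat_track <- function(x, ...) {
  cat(sprintf("<window_stat_track> %s: %d windows, value range [%.4g, %.4g]\n",
              attr(x, "statistic"), nrow(x),
              min(x$value), max(x$value)))
  invisible(x)
}

#' Windowed haplotype-homozygosity scans
#'
#' `h12_scan()` computes H12 (and H1, kept as attribute `h1`) per SNP
#' window; `h1x_scan()` computes cross-population sharing between two
#' haplotype sets defined on the same sites; `delta_h12()` computes H12 in
#' resistant samples minus H12 in susceptible samples, so positive values
#' mark swept haplotypes enriched in resistant mosquitoes.
#'
#' @param h,h_a,h_b,h_res,h_sus [haplotype_set()]s; two-set variants require
#'   identical site tables.
#' @param window_size,step window size and step in SNPs.
#' @return A `window_stat_track` data.frame (`contig`, window bounds,
#'   `value`).
#' @export
h12_scan <- function(h, window_size, step = window_size) {
  windows <- make_snp_windows(h$sites, window_size, step)
  vals <- vapply(seq_len(nrow(windows)), function(i) {
    garud_h(hap_frequencies(h, windows[i, ]))
  }, numeric(2))
  tr <- scan_track(windows, vals["H12", ], "H12")
  attr(tr, "h1") <- vals["H1", ]
  tr
}

#' @rdname h12_scan
#' @export
h1x_scan <- function(h_a, h_b, window_size, step = window_size) {
  if (!identical(h_a$sites$pos, h_b$sites$pos))
    stop("haplotype sets must share one site set")
  windows <- make_snp_windows(h_a$sites, window_size, step)
  vals <- vapply(seq_len(nrow(windows)), function(i) {
    h1x(hap_frequencies(h_a, windows[i, ]),
        hap_frequencies(h_b, windows[i, ]))
  }, numeric(1))
  scan_track(windows, vals, "H1X")
}

#' @rdname h12_scan
#' @export
delta_h12 <- function(h_res, h_sus, window_size, step = window_size) {
  if (!identical(h_res$sites$pos, h_sus$sites$pos))
    stop("haplotype sets must share one site set")
  res <- h12_scan(h_res, window_size, step)
  sus <- h12_scan(h_sus, window_size, step)
  scan_track(res[setdiff(names(res), "value")],
             res$value - sus$value, "deltaH12")
}

# Split a haplotype set by sample phenotype; shared site set by construction.
split_by_phenotype <- function(h, st) {
  res_ids <- st$sample[st$phenotype == "resistant"]
  sus_ids <- st$sample[st$phenotype == "susceptible"]
  list(res = subset_sites(h, samples = res_ids),
       sus = subset_sites(h, samples = sus_ids))
}
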