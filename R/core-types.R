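#' Site table constructor
#'
#' Builds the table of biallelic SNP sites shared by [genotype_set()] and
#' [haplotype_set()]. Positions are 1-based (VCF convention) and must be
#' strictly increasing within each contig.
#'
#' @param contig character vector of contig names.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-character reference and alternate alleles.
#' @return A `data.frame` with columns `contig`, `pos`, `ref`, `alt`.
#' @export
site_info <- function(contig, pos, ref, alt) {
  pos <- as.integer(pos)
  stopifnot(length(contig) == length(pos), length(ref) == length(pos),
            length(alt) == length(pos))
  if (any(nchar(ref) != 1L) || any(nchar(alt) != 1L))
    stop("sites must be biallelic SNPs (single-character alleles)")
  df <- data.frame(contig = as.character(contig), pos = pos,
                   ref = as.character(ref), alt = as.character(alt),
                   stringsAsFactors = FALSE)
  for (ctg in unique(df$contig)) {
    p <- df$pos[df$contig == ctg]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within contig ", ctg)
  }
  df
}

#' Diploid genotype container
#'
#' Per-sample diploid genotypes at ordered biallelic sites. Calls are coded as
#' the number of alternate-allele copies (0, 1, 2); missing calls are `NA`.
#' All downstream operations treat `NA` explicitly.
#'
#' @param sites site table from [site_info()].
#' @param samples character vector of unique sample ids.
#' @param calls integer matrix, sites x samples, values in `{0, 1, 2, NA}`.
#' @return An object of class `genotype_set`.
#' @export
genotype_set <- function(sites, samples, calls) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (anyDuplicated(samples)) stop("duplicate sample id")
  if (nrow(calls) != nrow(sites) || ncol(calls) != length(samples))
    stop("calls matrix dimensions do not match sites x samples")
  if (any(!is.na(calls) & (calls < 0L | calls > 2L)))
    stop("genotype calls must be 0, 1, 2 or NA")
  colnames(calls) <- samples
  structure(list(sites = sites, samples = as.character(samples), calls = calls),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("<genotype_set> %d sites x %d samples (%.2f%% missing)\n",
              nrow(x$sites), length(x$samples),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_set <- function(x) c(nrow(x$sites), length(x$samples))

#' Phased haplotype container
#'
#' Phased alleles (0 = ref, 1 = alt, no missing data) at ordered biallelic
#' sites. Every sample contributes exactly two haplotypes, identified as
#' `<sample>_1` and `<sample>_2`.
#'
#' @param sites site table from [site_info()].
#' @param samples character vector of sample ids (each owning two haplotypes).
#' @param alleles integer matrix, sites x (2 * samples), values in `{0, 1}`;
#'   columns ordered sample-major (`s1_1, s1_2, s2_1, ...`).
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(sites, samples, alleles) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (anyDuplicated(samples)) stop("duplicate sample id")
  if (ncol(alleles) != 2L * length(samples))
    stop("haplotype sets require exactly 2 haplotypes per sample")
  if (nrow(alleles) != nrow(sites))
    stop("allele matrix rows do not match sites")
  if (anyNA(alleles) || any(alleles < 0L | alleles > 1L))
    stop("haplotype alleles must be 0/1 with no missing data")
  haps <- data.frame(
    sample = rep(as.character(samples), each = 2L),
    phase = rep.int(1:2, length(samples)),
    stringsAsFactors = FALSE)
  colnames(alleles) <- paste0(haps$sample, "_", haps$phase)
  structure(list(sites = sites, samples = as.character(samples),
                 haplotypes = haps, alleles = alleles),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d sites x %d haplotypes (%d samples)\n",
              nrow(x$sites), ncol(x$alleles), length(x$samples)))
  invisible(x)
}

#' Collapse phased haplotypes to diploid genotypes
#'
#' @param h a [haplotype_set()].
#' @return A [genotype_set()] with calls equal to the per-sample sum of
#'   alternate alleles.
#' @export
genotypes_from_haplotypes <- function(h) {
  stopifnot(inherits(h, "haplotype_set"))
  idx1 <- seq(1L, ncol(h$alleles), by = 2L)
  calls <- h$alleles[, idx1, drop = FALSE] + h$alleles[, idx1 + 1L, drop = FALSE]
  genotype_set(h$sites, h$samples, calls)
}

#' Sample metadata table
#'
#' @param df data.frame with columns `sample`, `location`, `insecticide`,
#'   `phenotype` (`"resistant"` or `"susceptible"`), and optionally
#'   `contamination` (fraction in `[0, 1]`, default 0) and `sib_group`
#'   (`NA` for samples outside any sib group).
#' @return A `data.frame` of class `sample_table`.
#' @export
sample_table <- function(df) {
  req <- c("sample", "location", "insecticide", "phenotype")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample)) stop("duplicate sample id")
  bad <- !is.na(df$phenotype) & !df$phenotype %in% c("resistant", "susceptible")
  if (any(bad)) stop("phenotype must be 'resistant' or 'susceptible'")
  if (is.null(df$contamination)) df$contamination <- 0
  if (any(df$contamination < 0 | df$contamination > 1, na.rm = TRUE))
    stop("contamination must lie in [0, 1]")
  if (is.null(df$sib_group)) df$sib_group <- NA_character_
  df <- df[c(req, "contamination", "sib_group")]
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Normalised coverage in fixed-width genomic windows
#'
#' Window starts are 0-based half-open; the grid must be sorted,
#' non-overlapping and of constant width 300 bp. Coverage is on the
#' normalised scale where the diploid expectation is 2.0.
#'
#' @param contig single contig name.
#' @param starts integer vector of 0-based window starts.
#' @param coverage numeric matrix, windows x samples, non-negative.
#' @param samples sample ids (defaults to `colnames(coverage)`).
#' @param width window width in bp; must be 300.
#' @return An object of class `coverage_matrix`.
#' @export
coverage_matrix <- function(contig, starts, coverage, samples = colnames(coverage),
                            width = 300L) {
  width <- as.integer(width)
  if (width != 300L) stop("coverage windows must be exactly 300 bp")
  starts <- as.integer(starts)
  coverage <- as.matrix(coverage)
  if (is.null(samples)) stop("sample ids required")
  if (length(starts) != nrow(coverage)) stop("starts do not match coverage rows")
  if (length(samples) != ncol(coverage)) stop("samples do not match coverage columns")
  if (anyDuplicated(samples)) stop("duplicate sample id")
  if (is.unsorted(starts, strictly = TRUE) || any(diff(starts) < width))
    stop("windows must be sorted and non-overlapping")
  if (any(coverage < 0, na.rm = TRUE)) stop("coverage must be non-negative")
  colnames(coverage) <- samples
  structure(list(contig = as.character(contig)[1], starts = starts,
                 width = width, coverage = coverage,
                 samples = as.character(samples)),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf("<coverage_matrix> %s: %d windows (%d bp) x %d samples\n",
              x$contig, length(x$starts), x$width, length(x$samples)))
  invisible(x)
}

#' Gene/region annotation table
#'
#' Intervals are 0-based half-open (BED convention).
#'
#' @param name region names.
#' @param contig contig names.
#' @param start,end 0-based half-open bounds, `start < end`.
#' @return A `data.frame` of class `gene_region`.
#' @export
gene_region <- function(name, contig, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop("region start must be < end")
  df <- data.frame(name = as.character(name), contig = as.character(contig),
                   start = start, end = end, stringsAsFactors = FALSE)
  class(df) <- c("gene_region", "data.frame")
  df
}

# Which 1-based VCF positions fall inside a 0-based half-open interval.
pos_in_region <- function(pos, start, end) {
  (pos - 1L) >= start & (pos - 1L) < end
}
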