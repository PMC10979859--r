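#' Read genotypes and phased haplotypes from a VCF
#'
#' Only biallelic SNP records are kept; multiallelic and non-SNP records are
#' skipped (a message reports the count). The haplotype set is built from the
#' subset of retained records at which every sample is phased and non-missing;
#' records with any unphased or missing call contribute to the genotype set
#' only (missing calls become `NA`).
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param region optional `"contig:start-end"` string (1-based, inclusive)
#'   restricting the records read.
#' @return A list with elements `genotypes` ([genotype_set()]) and
#'   `haplotypes` ([haplotype_set()], `NULL` when no record is fully phased).
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) stop("VCF contains no records")
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  bases <- c("A", "C", "G", "T", "a", "c", "g", "t")
  keep <- !is.na(alt) & ref %in% bases & alt %in% bases
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    message(n_skipped, " multiallelic/non-SNP record(s) skipped")
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L) stop("malformed region string: ", region)
    keep <- keep & chrom == m[2] & pos >= as.integer(m[3]) & pos <= as.integer(m[4])
  }
  if (!any(keep)) stop("no biallelic SNP records retained")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  samples <- colnames(gt)
  sites <- site_info(chrom[keep], pos[keep], ref[keep], alt[keep])

  a1 <- substr(gt, 1L, 1L)
  sep <- substr(gt, 2L, 2L)
  a2 <- substr(gt, 3L, 3L)
  missing <- is.na(gt) | a1 == "." | a2 == "." | a2 == ""
  d1 <- array(suppressWarnings(as.integer(a1)), dim = dim(gt))
  d2 <- array(suppressWarnings(as.integer(a2)), dim = dim(gt))
  calls <- d1 + d2
  calls[missing] <- NA_integer_
  g <- genotype_set(sites, samples, calls)

  phased_row <- rowSums(!missing & sep == "|") == length(samples)
  h <- NULL
  if (any(phased_row)) {
    n <- length(samples)
    alleles <- matrix(0L, sum(phased_row), 2L * n)
    alleles[, seq(1L, 2L * n, 2L)] <- d1[phased_row, , drop = FALSE]
    alleles[, seq(2L, 2L * n, 2L)] <- d2[phased_row, , drop = FALSE]
    h <- haplotype_set(sites[phased_row, , drop = FALSE], samples, alleles)
  }
  list(genotypes = g, haplotypes = h)
}

#' Write genotypes (optionally phased) to a plain-text VCF
#'
#' @param g a [genotype_set()].
#' @param path output path.
#' @param haplotypes optional [haplotype_set()] over the same sites and
#'   samples; when given, calls are written phased (`a|b`), otherwise
#'   unphased genotypes are written from allele dose.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path, haplotypes = NULL) {
  stopifnot(inherits(g, "genotype_set"))
  n <- length(g$samples)
  if (!is.null(haplotypes)) {
    stopifnot(inherits(haplotypes, "haplotype_set"))
    if (!identical(haplotypes$sites$pos, g$sites$pos) ||
        !identical(haplotypes$samples, g$samples))
      stop("haplotypes must cover the same sites and samples as the genotypes")
    h1 <- haplotypes$alleles[, seq(1L, 2L * n, 2L), drop = FALSE]
    h2 <- haplotypes$alleles[, seq(2L, 2L * n, 2L), drop = FALSE]
    gt <- matrix(paste0(h1, "|", h2), nrow = nrow(h1))
  } else {
    gt <- matrix("./.", nrow = nrow(g$calls), ncol = n)
    gt[!is.na(g$calls) & g$calls == 0L] <- "0/0"
    gt[!is.na(g$calls) & g$calls == 1L] <- "0/1"
    gt[!is.na(g$calls) & g$calls == 2L] <- "1/1"
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples), collapse = "\t"))
  body <- paste(g$sites$contig, g$sites$pos, ".", g$sites$ref, g$sites$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects a delimited text file with a header containing at least the
#' columns `sample`, `location`, `insecticide`, `phenotype`; `contamination`
#' and `sib_group` are optional.
#'
#' @param path input path.
#' @param sep field separator (tab by default).
#' @return A [sample_table()].
#' @export
read_sample_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  sample_table(df)
}

#' @rdname read_sample_table
#' @param st a [sample_table()] to write.
#' @export
write_sample_table <- function(st, path, sep = "\t") {
  utils::write.table(st, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a normalised coverage matrix
#'
#' Expects a tab-separated file with header `contig`, `start`, `end`, then
#' one column per sample; windows must be a sorted non-overlapping 300-bp
#' grid on a single contig.
#'
#' @param path input path.
#' @return A [coverage_matrix()].
#' @export
read_coverage <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("contig", "start", "end")
  if (!all(req %in% names(df))) stop("coverage file needs contig/start/end columns")
  if (length(unique(df$contig)) != 1L)
    stop("coverage matrix must cover a single contig")
  if (any(df$end - df$start != 300L)) stop("coverage windows must be 300 bp")
  samples <- setdiff(names(df), req)
  if (!length(samples)) stop("coverage file has no sample columns")
  coverage_matrix(df$contig[1], df$start,
                  as.matrix(df[samples]), samples = samples)
}

#' @rdname read_coverage
#' @param cov a [coverage_matrix()] to write.
#' @export
write_coverage <- function(cov, path) {
  df <- data.frame(contig = cov$contig, start = cov$starts,
                   end = cov$starts + cov$width, check.names = FALSE)
  df <- cbind(df, as.data.frame(cov$coverage, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene/region annotations from a BED file
#'
#' BED intervals are 0-based half-open and are stored unchanged. A fourth
#' column, when present, provides region names; otherwise names are
#' `contig:start-end`.
#'
#' @param path BED file path.
#' @return A [gene_region()] table.
#' @export
read_regions <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns")
  name <- if (ncol(df) >= 4L) as.character(df[[4]]) else
    paste0(df[[1]], ":", df[[2]], "-", df[[3]])
  gene_region(name, df[[1]], df[[2]], df[[3]])
}

#' @rdname read_regions
#' @param regions a [gene_region()] table to write.
#' @export
write_regions <- function(regions, path) {
  utils::write.table(regions[c("contig", "start", "end", "name")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
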