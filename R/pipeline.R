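#' Pipeline run configuration
#'
#' Collects every tunable threshold of the end-to-end workflow. The
#' defaults are the standard analysis constants: KING sib threshold 0.185,
#' 1000-SNP windows, 100 sib-retention permutations for FST, 500 phenotype
#' permutations with 99% retention, centile thresholds 95 (PBS) and 98
#' (H12/deltaH12) with multiplier 3, Dxy cut height 0.001 with minimum
#' cluster size 20, GWAS filters MAC >= 5 / no missing data /
#' contamination P < 0.05 / FDR Q = 1%, and windowed GWAS over 100,000-bp
#' tiles flagging >= 10 of the top 1000 SNPs.
#'
#' @param window_size SNP-window size for all windowed scans.
#' @param king_threshold kinship threshold classifying full sibs.
#' @param exclude_regions optional [gene_region()] table removed before
#'   kinship (e.g. chromosomal inversions).
#' @param kin_quantile,het_z contamination-flag cutoffs
#'   (see [flag_contaminated()]).
#' @param sib_n_perm sib-retention permutations averaged in the FST scan.
#' @param n_perm phenotype permutations in the peak filter.
#' @param retain_quantile permutation retention quantile.
#' @param pbs_centile,h12_centile,centile_multiplier centile peak rules.
#' @param cut_height,min_cluster,cluster_alpha haplotype-cluster peak filter.
#' @param min_mac,contam_alpha,fdr_q,top_n,gwas_window_bp,min_hits GWAS
#'   settings.
#' @param cnv_pad_windows coverage windows of padding decoded around each
#'   CNV region.
#' @param marker_codings CNV marker codings offered to the association
#'   stage: `"carrier"` (presence/absence) and/or `"copies"` (extra
#'   copies).
#' @param scan_locations locations to scan (`NULL` = every location with
#'   both phenotype classes).
#' @param stages character vector of stages to run, any of `"kinship"`,
#'   `"selection"`, `"differentiation"`, `"cnv"`, `"association"`, `"gwas"`.
#' @param seed integer seed driving every stochastic stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(window_size = 1000L,
                       king_threshold = 0.185,
                       exclude_regions = NULL,
                       kin_quantile = 0.99, het_z = 4,
                       sib_n_perm = 100L,
                       n_perm = 500L, retain_quantile = 0.99,
                       pbs_centile = 95, h12_centile = 98,
                       centile_multiplier = 3,
                       cut_height = 0.001, min_cluster = 20L,
                       cluster_alpha = 0.05,
                       min_mac = 5L, contam_alpha = 0.05, fdr_q = 0.01,
                       top_n = 1000L, gwas_window_bp = 100000L,
                       min_hits = 10L,
                       cnv_pad_windows = 10L,
                       marker_codings = c("carrier", "copies"),
                       scan_locations = NULL,
                       stages = c("kinship", "selection", "differentiation",
                                  "cnv", "association", "gwas"),
                       seed = 1L) {
  stopifnot(window_size >= 2L, king_threshold > 0, king_threshold < 0.5,
            retain_quantile > 0, retain_quantile < 1,
            fdr_q > 0, fdr_q < 1)
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

# One location's scans: H12, deltaH12 (dedup'd samples), sib-averaged FST,
# PBS against an outgroup, and the permutation + cluster peak filters.
scan_location <- function(g, h, st_loc, sib_groups_loc, outgroup_ids, cfg,
                          seed) {
  dedup_ids <- dedup_sibs(st_loc, sib_groups_loc, seed = seed)
  st_dedup <- st_loc[st_loc$sample %in% dedup_ids, ]
  h_dedup <- subset_sites(h, samples = dedup_ids)
  out <- list(samples_used = dedup_ids)

  out$h12 <- h12_scan(h_dedup, cfg$window_size)
  ph <- split_by_phenotype(h_dedup, st_dedup)
  out$delta_h12 <- delta_h12(ph$res, ph$sus, cfg$window_size)

  thr_d <- centile_peak_threshold(out$delta_h12$value, cfg$h12_centile,
                                  cfg$centile_multiplier)
  cand_d <- find_candidate_peaks(out$delta_h12, thr_d, positive_only = TRUE)
  out$delta_peaks <- permutation_filter(
    cand_d, make_delta_h12_stat_fun(h_dedup, cand_d, st_dedup), st_dedup,
    n_perm = cfg$n_perm, retain_quantile = cfg$retain_quantile,
    seed = seed + 1L)

  out$fst <- fst_scan_sib_averaged(g, st_loc, sib_groups_loc,
                                   window_size = cfg$window_size,
                                   n_perm = cfg$sib_n_perm, seed = seed + 2L)
  thr_f <- fst_peak_threshold(out$fst$value)
  out$fst_threshold <- thr_f
  cand_f <- find_candidate_peaks(out$fst, thr_f$threshold)
  g_dedup <- subset_sites(g, samples = dedup_ids)
  fst_peaks <- permutation_filter(
    cand_f, make_fst_stat_fun(g_dedup, out$fst, cand_f, st_dedup), st_dedup,
    n_perm = cfg$n_perm, retain_quantile = cfg$retain_quantile,
    seed = seed + 3L)
  out$fst_peaks <- filter_peaks_by_cluster(
    fst_peaks, h_dedup, st_dedup, cut_height = cfg$cut_height,
    min_size = cfg$min_cluster, alpha = cfg$cluster_alpha)

  if (length(outgroup_ids) >= 2L) {
    res_ids <- st_dedup$sample[st_dedup$phenotype == "resistant"]
    sus_ids <- st_dedup$sample[st_dedup$phenotype == "susceptible"]
    out$pbs <- pbs_scan(g, res_ids, sus_ids, outgroup_ids, cfg$window_size)
    thr_p <- centile_peak_threshold(out$pbs$value, cfg$pbs_centile,
                                    cfg$centile_multiplier)
    cand_p <- find_candidate_peaks(out$pbs, thr_p, positive_only = TRUE)
    out$pbs_peaks <- permutation_filter(
      cand_p, make_pbs_stat_fun(g, out$pbs, cand_p, st_dedup, outgroup_ids),
      st_dedup, n_perm = cfg$n_perm,
      retain_quantile = cfg$retain_quantile, seed = seed + 4L)
  }
  out
}

#' Run the end-to-end resistance-association workflow
#'
#' Executes, in order: KING kinship with contaminated-sample exclusion and
#' sib-group detection; per-location selection scans (H12, deltaH12) and
#' differentiation scans (sib-averaged Hudson FST, PBS against the other
#' location as outgroup) with mode/centile peak calling, the 500-permutation
#' phenotype filter and the haplotype-cluster filter; coverage-HMM CNV calls
#' with per-region carrier and extra-copy markers plus the median-coverage
#' estimator; single-marker tests and forward stepwise model building (with
#' location as a fixed covariate when several locations are phenotyped);
#' and the SNP-wise + windowed GWAS. Stages can be switched off via
#' `cfg$stages`.
#'
#' @param data a list with elements `genotypes` ([genotype_set()]),
#'   `haplotypes` ([haplotype_set()]), `coverage` ([coverage_matrix()],
#'   needed for the cnv/association stages), `samples` ([sample_table()]),
#'   `regions` ([gene_region()] table of CNV regions) — e.g. a
#'   [simulate_dataset()] result — or a named list of file paths
#'   (`vcf`, `samples`, `coverage`, `regions`).
#' @param cfg a [run_config()].
#' @param out_dir optional directory; when given, every stage's tables are
#'   written as TSV plus a JSON run manifest.
#' @return A list of class `sweepscan_run` bundling every stage's output.
#' @export
run_pipeline <- function(data, cfg = run_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(data$vcf)) {
    vc <- read_vcf(data$vcf)
    data <- list(genotypes = vc$genotypes, haplotypes = vc$haplotypes,
                 samples = read_sample_table(data$samples),
                 coverage = if (!is.null(data$coverage))
                   read_coverage(data$coverage),
                 regions = if (!is.null(data$regions))
                   read_regions(data$regions))
  }
  g <- data$genotypes; h <- data$haplotypes; st <- data$samples
  bundle <- list(config = cfg)
  seed <- cfg$seed

  retained <- st$sample
  # sib groups: taken from the sample table when provided (e.g. from an
  # external kinship tool), otherwise derived from the KING matrix below
  sib_groups <- NULL
  if (any(!is.na(st$sib_group))) {
    with_group <- st[!is.na(st$sib_group), ]
    sib_groups <- data.frame(group = with_group$sib_group,
                             sample = with_group$sample,
                             stringsAsFactors = FALSE)
  }
  if ("kinship" %in% cfg$stages) {
    bundle$kinship <- king_kinship(g, cfg$exclude_regions)
    bundle$flagged <- flag_contaminated(bundle$kinship, g,
                                        cfg$kin_quantile, cfg$het_z)
    retained <- setdiff(retained, bundle$flagged)
    if (is.null(sib_groups))
      sib_groups <- find_sib_groups(bundle$kinship, cfg$king_threshold)
  }
  if (!is.null(sib_groups))
    sib_groups <- sib_groups[sib_groups$sample %in% retained, , drop = FALSE]
  bundle$sib_groups <- sib_groups
  st_r <- st[st$sample %in% retained, ]
  bundle$retained <- dedup_sibs(st_r, sib_groups, seed = seed)
  st_dedup <- st_r[st_r$sample %in% bundle$retained, ]

  scannable <- Filter(function(loc) {
    tab <- table(st_r$phenotype[st_r$location == loc])
    length(tab) == 2L && all(tab >= 2L)
  }, unique(st_r$location))
  if (!is.null(cfg$scan_locations))
    scannable <- intersect(scannable, cfg$scan_locations)

  if (any(c("selection", "differentiation") %in% cfg$stages)) {
    bundle$scans <- lapply(stats::setNames(nm = scannable), function(loc) {
      st_loc <- st_r[st_r$location == loc, ]
      sg_loc <- if (!is.null(sib_groups))
        sib_groups[sib_groups$sample %in% st_loc$sample, , drop = FALSE]
      outgroup <- intersect(bundle$retained,
                            st_r$sample[st_r$location != loc])
      scan_location(g, h, st_loc, sg_loc, outgroup, cfg, seed = seed + 10L)
    })
  }

  if ("cnv" %in% cfg$stages && !is.null(data$coverage)) {
    cov <- data$coverage
    keep_cov <- cov$samples %in% retained
    # decode only the windows near the regions being genotyped
    pad <- cfg$cnv_pad_windows * 300L
    near <- rep(FALSE, length(cov$starts))
    for (r in seq_len(nrow(data$regions)))
      near <- near | (cov$starts < data$regions$end[r] + pad &
                        cov$starts + cov$width > data$regions$start[r] - pad)
    cov <- coverage_matrix(cov$contig, cov$starts[near],
                           cov$coverage[near, keep_cov, drop = FALSE],
                           samples = cov$samples[keep_cov])
    bundle$cnv_calls <- cnv_call(cov, data$regions)
    bundle$carriers <- carrier_table(bundle$cnv_calls)
    bundle$median_copy_number <- lapply(
      stats::setNames(nm = data$regions$name), function(rn) {
        region_median_copy_number(cov, data$regions[data$regions$name == rn, ])
      })
  }

  if ("association" %in% cfg$stages && !is.null(bundle$cnv_calls)) {
    ids <- st_dedup$sample
    markers <- data.frame(row.names = ids)
    for (rn in unique(bundle$cnv_calls$region)) {
      calls_r <- bundle$cnv_calls[bundle$cnv_calls$region == rn, ]
      idx <- match(ids, calls_r$sample)
      if ("carrier" %in% cfg$marker_codings)
        markers[[paste0(rn, "_carrier")]] <- as.integer(calls_r$carrier[idx])
      if ("copies" %in% cfg$marker_codings)
        markers[[paste0(rn, "_copies")]] <- pmax(calls_r$extra_copies[idx], 0L)
    }
    covars <- if (length(unique(st_dedup$location)) > 1L)
      data.frame(location = factor(st_dedup$location)) else NULL
    bundle$marker_tests <- suppressWarnings(
      marker_tests(st_dedup, markers, covariates = covars))
    bundle$stepwise <- suppressWarnings(
      stepwise_build(st_dedup, markers, covariates = covars))
  }

  if ("gwas" %in% cfg$stages) {
    g_dedup <- subset_sites(g, samples = st_dedup$sample)
    bundle$gwas <- snp_gwas(g_dedup, st_dedup, min_mac = cfg$min_mac,
                            contam_alpha = cfg$contam_alpha)
    bundle$gwas_significant <- fdr_select(bundle$gwas, cfg$fdr_q)
    bundle$gwas_windows <- windowed_gwas(bundle$gwas, cfg$top_n,
                                         cfg$gwas_window_bp, cfg$min_hits)
  }

  class(bundle) <- "sweepscan_run"
  if (!is.null(out_dir)) write_run(bundle, out_dir)
  bundle
}

#' @export
print.sweepscan_run <- function(x, ...) {
  cat("<sweepscan_run>\n")
  if (!is.null(x$sib_groups))
    cat(sprintf("  kinship: %d sib group(s), %d sample(s) flagged contaminated\n",
                length(unique(x$sib_groups$group)), length(x$flagged)))
  for (loc in names(x$scans)) {
    s <- x$scans[[loc]]
    cat(sprintf("  %s: max H12 %.3f, max deltaH12 %.3f, FST peaks retained %d/%d\n",
                loc, max(s$h12$value), max(s$delta_h12$value),
                sum(s$fst_peaks$retained), nrow(s$fst_peaks)))
  }
  if (!is.null(x$stepwise)) {
    cat("  stepwise:",
        if (length(x$stepwise$selected))
          paste(x$stepwise$selected, collapse = " + ") else "(null model)",
        "\n")
  }
  if (!is.null(x$gwas))
    cat(sprintf("  gwas: %d site(s) tested, %d significant at Q=%g, %d window(s) flagged\n",
                nrow(x$gwas), nrow(x$gwas_significant), x$config$fdr_q,
                sum(x$gwas_windows$flagged)))
  invisible(x)
}

# Write every tabular stage output plus a JSON manifest.
write_run <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$kinship)) {
    phi <- bundle$kinship$phi
    pairs <- which(upper.tri(phi), arr.ind = TRUE)
    wt(data.frame(sample1 = rownames(phi)[pairs[, 1]],
                  sample2 = colnames(phi)[pairs[, 2]],
                  phi = phi[pairs]), "kinship_pairs")
    wt(bundle$sib_groups, "sib_groups")
  }
  for (loc in names(bundle$scans)) {
    s <- bundle$scans[[loc]]
    for (nm in c("h12", "delta_h12", "fst", "pbs"))
      if (!is.null(s[[nm]])) wt(s[[nm]], paste0(loc, "_", nm))
    for (nm in c("delta_peaks", "fst_peaks", "pbs_peaks"))
      if (!is.null(s[[nm]])) wt(s[[nm]], paste0(loc, "_", nm))
  }
  if (!is.null(bundle$cnv_calls)) wt(bundle$cnv_calls, "cnv_calls")
  if (!is.null(bundle$marker_tests)) wt(bundle$marker_tests, "marker_tests")
  if (!is.null(bundle$stepwise))
    wt(data.frame(step = seq_along(bundle$stepwise$selected),
                  marker = bundle$stepwise$selected,
                  p_lrt = bundle$stepwise$p_path), "stepwise")
  if (!is.null(bundle$gwas)) {
    wt(bundle$gwas, "gwas")
    wt(bundle$gwas_significant, "gwas_significant")
    wt(bundle$gwas_windows, "gwas_windows")
  }
  cfg <- bundle$config
  manifest <- list(
    package = "sweepscan",
    version = as.character(utils::packageVersion("sweepscan")),
    r_version = as.character(getRversion()),
    timestamp_utc = format(Sys.time(), tz = "UTC"),
    config = cfg[vapply(cfg, function(x)
      is.numeric(x) || is.character(x) || is.logical(x), logical(1))])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
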