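#' Configuration for the synthetic two-population dataset
#'
#' The generator emulates the structure of a two-location phenotyped mosquito
#' cohort: two partially differentiated populations built from independent
#' coalescent blocks (a proxy for recombination), a soft selective sweep in
#' one population, a linked multi-copy CNV observable as elevated normalised
#' coverage, genotype-dependent mortality after insecticide exposure,
#' full-sib pairs, and a per-sample contamination fraction.
#'
#' Default effect sizes are the study conditions being emulated: wild-type
#' mortality 0.442 and CNV-carrier mortality 0.167, a sweep carrier fraction
#' of 0.6, and a CNV whose extra-copy number is high and variable (median 8
#' extra copies). Sample sizes default to 900 in the focal (phenotyped)
#' population and 300 in the comparison population: cohort sizes chosen by
#' power analysis so that, at these mortalities and sweep frequency, the
#' windowed statistics clear a 99% phenotype-permutation threshold reliably
#' (see the methods vignette).
#'
#' @param n_samples integer vector of length 2, samples per population.
#' @param pop_names location labels for the two populations.
#' @param insecticide insecticide label applied to all samples.
#' @param n_blocks number of independent genealogy blocks.
#' @param contig,contig_length contig name and length in bp; blocks tile the
#'   contig in equal spans and mutation positions are uniform within a block.
#' @param theta per-block scaled mutation parameter (expected pairwise
#'   differences within a population).
#' @param divergence fraction of mutations private to one population
#'   (0 = maximal sharing of polymorphic sites, 1 = fully private).
#' @param sweep list: `block` (1-based focal block), `f` (haplotype carrier
#'   fraction), `mut_rate` (expected private mutations per swept copy),
#'   `core_snps` (sweep-defining mutations shared by all swept copies),
#'   `pop` (population carrying the sweep).
#' @param cnv list: `start`/`end` (0-based half-open region, must lie on the
#'   300-bp grid), `link_p` (probability that a sweep-carrying sample carries
#'   the CNV), `copy_dist` (function drawing extra copies for carriers).
#' @param coverage_noise_sd per-window coverage noise (sd around the true
#'   copy number on the normalised scale).
#' @param phenotype list: `base_mort`, `carrier_mort` (death probabilities).
#' @param n_sib_pairs integer vector of length 2, full-sib pairs added per
#'   population (children appended as extra samples).
#' @param contamination list: `max_frac` (upper bound of the uniform
#'   contamination fraction), `target_site`, `effect` (see
#'   [simulate_contamination()]).
#' @param seed integer seed; mandatory, every stochastic step derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = c(900L, 300L),
                       pop_names = c("Moshi", "Muleba"),
                       insecticide = "PM",
                       n_blocks = 8L,
                       contig = "2L",
                       contig_length = 240000L,
                       theta = 16,
                       divergence = 0.3,
                       sweep = list(block = 5L, f = 0.6, mut_rate = 0.5,
                                    core_snps = 12L, pop = 1L),
                       cnv = list(start = 135000L, end = 148200L, link_p = 1,
                                  copy_dist = function(n) 4L + stats::rpois(n, 4)),
                       coverage_noise_sd = 0.3,
                       phenotype = list(base_mort = 0.442, carrier_mort = 0.167),
                       n_sib_pairs = c(2L, 6L),
                       contamination = list(max_frac = 0.05, target_site = NULL,
                                            effect = 0),
                       seed = NULL) {
  stopifnot(length(n_samples) == 2L, all(n_samples >= 2L),
            theta > 0, divergence >= 0, divergence <= 1,
            sweep$f > 0, sweep$f <= 1,
            phenotype$base_mort >= 0, phenotype$base_mort <= 1,
            phenotype$carrier_mort >= 0, phenotype$carrier_mort <= 1,
            cnv$link_p >= 0, cnv$link_p <= 1,
            coverage_noise_sd > 0)
  if (is.null(seed)) stop("sim_config requires an explicit seed")
  cfg <- list(n_samples = as.integer(n_samples), pop_names = pop_names,
              insecticide = insecticide, n_blocks = as.integer(n_blocks),
              contig = contig, contig_length = as.integer(contig_length),
              theta = theta, divergence = divergence, sweep = sweep,
              cnv = cnv, coverage_noise_sd = coverage_noise_sd,
              phenotype = phenotype, n_sib_pairs = as.integer(n_sib_pairs),
              contamination = contamination, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# One Kingman n-coalescent genealogy. Nodes 1..n are tips, n+1..2n-1 are
# internal; returns the children of each internal node and every non-root
# node's branch length (coalescent time units of 2N generations).
coalescent_tree <- function(n_tips) {
  n_nodes <- 2L * n_tips - 1L
  children <- matrix(0L, 2L, n_tips - 1L)
  birth <- numeric(n_nodes)
  len <- numeric(n_nodes)
  active <- seq_len(n_tips)
  t <- 0
  k <- n_tips
  while (k > 1L) {
    t <- t + stats::rexp(1L, k * (k - 1L) / 2)
    pr <- sort(sample.int(k, 2L))
    a <- active[pr[1L]]; b <- active[pr[2L]]
    new <- 2L * n_tips - k + 1L
    children[, new - n_tips] <- c(a, b)
    birth[new] <- t
    len[a] <- t - birth[a]
    len[b] <- t - birth[b]
    # the new lineage takes the first merged slot; the last active
    # lineage fills the second (no-op when pr[2] is already last)
    active[pr[1L]] <- new
    active[pr[2L]] <- active[k]
    k <- k - 1L
  }
  list(children = children, len = len[-n_nodes], n_tips = n_tips)
}

# Contiguous tip intervals per node: children ids always precede their
# parent, so subtree sizes build bottom-up and intervals top-down in O(n);
# the tips below node v are then order[lo[v]:hi[v]].
tree_tip_ranges <- function(tree) {
  n <- tree$n_tips
  n_nodes <- 2L * n - 1L
  size <- c(rep.int(1L, n), integer(n - 1L))
  for (v in (n + 1L):n_nodes) {
    ch <- tree$children[, v - n]
    size[v] <- size[ch[1L]] + size[ch[2L]]
  }
  lo <- integer(n_nodes); hi <- integer(n_nodes)
  lo[n_nodes] <- 1L; hi[n_nodes] <- n
  for (v in n_nodes:(n + 1L)) {
    ch <- tree$children[, v - n]
    lo[ch[1L]] <- lo[v]; hi[ch[1L]] <- lo[v] + size[ch[1L]] - 1L
    lo[ch[2L]] <- hi[ch[1L]] + 1L; hi[ch[2L]] <- hi[v]
  }
  ord <- integer(n)
  ord[lo[seq_len(n)]] <- seq_len(n)
  list(order = ord, lo = lo, hi = hi)
}

# Tips below a node, via the precomputed tip intervals.
node_tips <- function(tree, node, ranges = tree_tip_ranges(tree)) {
  ranges$order[seq.int(ranges$lo[node], ranges$hi[node])]
}

# Drop Poisson(theta/2 * total length) infinite-sites mutations on a tree;
# returns a list of descendant tip sets, one per segregating site.
drop_mutations <- function(tree, theta) {
  total <- sum(tree$len)
  m <- stats::rpois(1L, theta / 2 * total)
  if (m == 0L) return(list())
  br <- sample.int(length(tree$len), m, replace = TRUE, prob = tree$len)
  rg <- tree_tip_ranges(tree)
  lapply(br, function(b) rg$order[seq.int(rg$lo[b], rg$hi[b])])
}

# Unique integer positions within [lo, hi) (1-based VCF positions lo+1..hi).
draw_positions <- function(m, lo, hi) {
  if (m == 0L) return(integer())
  avail <- hi - lo
  if (m > avail) stop("more sites than available positions in block")
  sort(sample.int(avail, m) + lo)
}

#' Simulate phased haplotypes for two partially differentiated populations
#'
#' Each of `n_blocks` genomic blocks is an independent genealogy (a proxy for
#' free recombination between blocks). Within a block, each population gets
#' its own Kingman coalescent with Poisson mutations (rate proportional to
#' `theta`), so expected within-population pairwise diversity per block is
#' `theta`. A fraction `1 - divergence` of mutations is assigned to shared
#' genomic positions that are polymorphic in both populations (with
#' frequencies drifting independently under each population's genealogy);
#' the rest are population-private, so `divergence` tunes differentiation.
#'
#' @param cfg a [sim_config()].
#' @return A list: `haplotypes` ([haplotype_set()] over both populations) and
#'   `truth` (block bounds, per-site block index, per-sample population).
#' @export
simulate_haplotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n1 <- cfg$n_samples[1]; n2 <- cfg$n_samples[2]
  h1n <- 2L * n1; h2n <- 2L * n2
  block_span <- cfg$contig_length %/% cfg$n_blocks
  block_bounds <- data.frame(block = seq_len(cfg$n_blocks),
                             start = (seq_len(cfg$n_blocks) - 1L) * block_span,
                             end = seq_len(cfg$n_blocks) * block_span)
  pos_all <- integer(); block_all <- integer()
  cols <- list()
  for (b in seq_len(cfg$n_blocks)) {
    tA <- coalescent_tree(h1n)
    tB <- coalescent_tree(h2n)
    mA <- drop_mutations(tA, cfg$theta)
    mB <- drop_mutations(tB, cfg$theta)
    n_shared <- stats::rbinom(1L, min(length(mA), length(mB)),
                              1 - cfg$divergence)
    shA <- if (length(mA)) sample.int(length(mA), n_shared) else integer()
    shB <- if (length(mB)) sample.int(length(mB), n_shared) else integer()
    n_sites <- length(mA) + length(mB) - n_shared
    if (n_sites == 0L) next
    pos <- draw_positions(n_sites, block_bounds$start[b], block_bounds$end[b])
    # allele matrix for this block: shared sites first, then private
    mat <- matrix(0L, n_sites, h1n + h2n)
    row <- 0L
    if (n_shared > 0L) for (j in seq_len(n_shared)) {
      row <- row + 1L
      mat[row, mA[[shA[j]]]] <- 1L
      mat[row, h1n + mB[[shB[j]]]] <- 1L
    }
    for (j in setdiff(seq_along(mA), shA)) {
      row <- row + 1L
      mat[row, mA[[j]]] <- 1L
    }
    for (j in setdiff(seq_along(mB), shB)) {
      row <- row + 1L
      mat[row, h1n + mB[[j]]] <- 1L
    }
    # positions were drawn sorted; shuffle assignment so shared/private sites
    # interleave along the block
    ord <- sample.int(n_sites)
    mat <- mat[ord, , drop = FALSE]
    pos_all <- c(pos_all, pos)
    block_all <- c(block_all, rep.int(b, n_sites))
    cols[[length(cols) + 1L]] <- mat
  }
  alleles <- do.call(rbind, cols)
  samples <- sprintf("S%04d", seq_len(n1 + n2))
  pop <- rep(1:2, times = c(n1, n2))
  sites <- site_info(rep(cfg$contig, length(pos_all)), pos_all + 1L,
                     rep("A", length(pos_all)), rep("T", length(pos_all)))
  h <- haplotype_set(sites, samples, alleles)
  truth <- list(block_bounds = block_bounds, site_block = block_all,
                sample_pop = stats::setNames(pop, samples),
                swept_haps = character(), cnv = NULL, sib_groups = NULL)
  list(haplotypes = h, truth = truth)
}

#' Implant a soft selective sweep into one genomic block
#'
#' A randomly chosen core haplotype overwrites the focal-block alleles of a
#' fraction `f` of the eligible haplotypes; each swept copy then receives
#' `Poisson(mut_rate)` new private mutations at fresh positions within the
#' block, creating the sub-structure seen under recent CNV amplifications.
#' In addition, `core_snps` new sweep-defining mutations shared by every
#' swept copy are placed in the block: the hitchhiking variants a real
#' swept haplotype carries relative to the rest of the population, which a
#' low-diversity simulated block can otherwise lack when the drawn core
#' happens to resemble the consensus.
#'
#' @param h a [haplotype_set()].
#' @param truth truth list from [simulate_haplotypes()] (block bounds and
#'   site-block assignment are taken from it and updated).
#' @param block 1-based focal block index.
#' @param f fraction of eligible haplotypes swept (0 < f <= 1).
#' @param mut_rate expected number of private mutations per swept copy.
#' @param seed integer seed.
#' @param pop population whose haplotypes are eligible (`NULL` = all).
#' @param core_snps number of sweep-defining mutations shared by all swept
#'   copies (default 0).
#' @return A list: updated `haplotypes` and `truth` (with `swept_haps`,
#'   `sweep_block`, `causal_sites`).
#' @export
implant_sweep <- function(h, truth, block, f, mut_rate = 0, seed, pop = NULL,
                          core_snps = 0L) {
  stopifnot(inherits(h, "haplotype_set"), f > 0, f <= 1)
  if (block < 1L || block > nrow(truth$block_bounds))
    stop("focal block out of range")
  set.seed(seed)
  hap_pop <- truth$sample_pop[h$haplotypes$sample]
  eligible <- if (is.null(pop)) seq_len(ncol(h$alleles)) else
    which(hap_pop == pop)
  site_idx <- which(truth$site_block == block)
  n_swept <- max(1L, round(f * length(eligible)))
  swept <- sample(eligible, n_swept)
  core <- sample(swept, 1L)
  h$alleles[site_idx, swept] <- h$alleles[site_idx, core]
  # new mutations: `core_snps` shared by every swept copy (hitchhiking
  # variants of the swept haplotype) plus Poisson(mut_rate) private ones
  # per copy, all at fresh positions in the block
  bb <- truth$block_bounds[block, ]
  n_priv <- stats::rpois(n_swept, mut_rate)
  core_snps <- as.integer(core_snps)
  total_new <- core_snps + sum(n_priv)
  causal_pos <- integer()
  if (total_new > 0L) {
    new_pos <- integer(total_new)
    taken <- h$sites$pos - 1L
    k <- 0L
    while (k < total_new) {
      p <- sample.int(bb$end - bb$start, 1L) + bb$start
      if (!(p %in% taken) && !(p %in% new_pos[seq_len(k)])) {
        k <- k + 1L
        new_pos[k] <- p
      }
    }
    new_alleles <- matrix(0L, total_new, ncol(h$alleles))
    if (core_snps > 0L) {
      new_alleles[seq_len(core_snps), swept] <- 1L
      causal_pos <- new_pos[seq_len(core_snps)] + 1L
    }
    if (sum(n_priv) > 0L) {
      owner <- rep(swept, n_priv)
      new_alleles[cbind(core_snps + seq_len(sum(n_priv)), owner)] <- 1L
    }
    sites2 <- rbind(h$sites,
                    data.frame(contig = h$sites$contig[1], pos = new_pos + 1L,
                               ref = "A", alt = "T"))
    alleles2 <- rbind(h$alleles, new_alleles)
    block2 <- c(truth$site_block, rep.int(block, total_new))
    ord <- order(sites2$pos)
    h <- haplotype_set(sites2[ord, , drop = FALSE], h$samples,
                       alleles2[ord, , drop = FALSE])
    truth$site_block <- block2[ord]
  }
  truth$swept_haps <- colnames(h$alleles)[swept]
  truth$sweep_block <- block
  truth$causal_sites <- causal_pos
  list(haplotypes = h, truth = truth)
}

#' Append full-sib pairs to a simulated cohort
#'
#' Each pair of children is formed from two shared parents drawn from one
#' population; per independent block a child inherits one of the two
#' haplotypes of each parent (free recombination between blocks, none
#' within). Children are appended as new samples; parents stay in the
#' cohort.
#'
#' @param h a [haplotype_set()].
#' @param truth truth list carrying `block_bounds`, `site_block`,
#'   `sample_pop` (updated in the result with `sib_groups`).
#' @param n_pairs integer vector: sib pairs to create per population.
#' @param seed integer seed.
#' @return A list: updated `haplotypes` and `truth`.
#' @export
make_sib_pairs <- function(h, truth, n_pairs, seed) {
  stopifnot(inherits(h, "haplotype_set"))
  set.seed(seed)
  n_pops <- length(unique(truth$sample_pop))
  if (length(n_pairs) == 1L) n_pairs <- rep.int(n_pairs, n_pops)
  new_cols <- list(); new_samples <- character(); new_pop <- integer()
  sib_groups <- list()
  swept <- colnames(h$alleles) %in% truth$swept_haps
  new_swept <- character()
  blocks <- truth$site_block
  child_id <- 0L
  for (p in seq_len(n_pops)) {
    pool <- names(truth$sample_pop)[truth$sample_pop == p]
    if (2L * n_pairs[p] > length(pool))
      stop("not enough founders for the requested sib pairs")
    parents <- sample(pool, 2L * n_pairs[p])
    for (i in seq_len(n_pairs[p])) {
      pa <- parents[2L * i - 1L]; pb <- parents[2L * i]
      pa_cols <- match(pa, h$samples) * 2L - 1:0
      pb_cols <- match(pb, h$samples) * 2L - 1:0
      kids <- character(2L)
      for (k in 1:2) {
        child_id <- child_id + 1L
        id <- sprintf("SIB%03d", child_id)
        kids[k] <- id
        hap <- matrix(0L, nrow(h$alleles), 2L)
        for (b in seq_len(nrow(truth$block_bounds))) {
          idx <- which(blocks == b)
          ca <- sample(pa_cols, 1L)
          cb <- sample(pb_cols, 1L)
          hap[idx, 1L] <- h$alleles[idx, ca]
          hap[idx, 2L] <- h$alleles[idx, cb]
          if (!is.null(truth$sweep_block) && b == truth$sweep_block) {
            if (swept[ca]) new_swept <- c(new_swept, paste0(id, "_1"))
            if (swept[cb]) new_swept <- c(new_swept, paste0(id, "_2"))
          }
        }
        new_cols[[length(new_cols) + 1L]] <- hap
        new_samples <- c(new_samples, id)
        new_pop <- c(new_pop, p)
      }
      sib_groups[[length(sib_groups) + 1L]] <-
        data.frame(group = sprintf("G%03d", length(sib_groups) + 1L),
                   sample = kids, stringsAsFactors = FALSE)
    }
  }
  if (length(new_samples)) {
    alleles2 <- cbind(h$alleles, do.call(cbind, new_cols))
    h <- haplotype_set(h$sites, c(h$samples, new_samples), alleles2)
    truth$sample_pop <- c(truth$sample_pop,
                          stats::setNames(new_pop, new_samples))
    truth$swept_haps <- c(truth$swept_haps, new_swept)
    truth$sib_groups <- do.call(rbind, sib_groups)
  }
  list(haplotypes = h, truth = truth)
}

#' Assign a linked CNV and emit a normalised coverage matrix
#'
#' Samples carrying at least one swept haplotype become CNV carriers with
#' probability `link_p`; a carrier's extra-copy number is drawn from
#' `copy_dist`. Per-window normalised coverage is Normal(true total copy
#' number, `noise_sd`) truncated at 0, with mean 2 outside the CNV region.
#'
#' @param h a [haplotype_set()] (defines the samples).
#' @param truth truth list with `swept_haps` (updated with `cnv`).
#' @param region single-row [gene_region()] giving the CNV span; must lie on
#'   the 300-bp grid of the contig.
#' @param copy_dist function drawing integer extra-copy numbers.
#' @param link_p linkage probability between sweep and CNV.
#' @param noise_sd coverage noise sd (> 0).
#' @param seed integer seed.
#' @param contig_length contig length in bp (defines the window grid).
#' @return A list: `coverage` ([coverage_matrix()]) and updated `truth`
#'   (fields `cnv$carrier`, `cnv$copy_number` keyed by sample).
#' @export
assign_cnv_and_coverage <- function(h, truth, region, copy_dist, link_p,
                                    noise_sd, seed, contig_length) {
  stopifnot(noise_sd > 0)
  set.seed(seed)
  starts <- seq.int(0L, contig_length - 300L, by = 300L)
  in_region <- starts >= region$start & (starts + 300L) <= region$end
  if (!any(in_region)) stop("CNV region not covered by the window grid")
  samples <- h$samples
  hap_swept <- colnames(h$alleles) %in% truth$swept_haps
  swept_sample <- tapply(hap_swept, h$haplotypes$sample, any)[samples]
  carrier <- swept_sample & stats::runif(length(samples)) < link_p
  extra <- integer(length(samples))
  extra[carrier] <- copy_dist(sum(carrier))
  cn <- 2L + extra
  n_w <- length(starts)
  mean_mat <- matrix(2, n_w, length(samples))
  mean_mat[in_region, ] <- rep(cn, each = sum(in_region))
  cov <- matrix(stats::rnorm(n_w * length(samples), mean_mat, noise_sd),
                n_w, length(samples))
  cov <- pmax(cov, 0)
  truth$cnv <- list(region = region,
                    carrier = stats::setNames(as.logical(carrier), samples),
                    copy_number = stats::setNames(cn, samples))
  list(coverage = coverage_matrix(region$contig[1], starts, cov,
                                  samples = samples),
       truth = truth)
}

#' Simulate dead/alive phenotypes from CNV carrier status
#'
#' Each sample dies with probability `base_mort` (non-carrier) or
#' `carrier_mort` (carrier). Dead samples are phenotyped "susceptible",
#' survivors "resistant".
#'
#' @param truth truth list with `cnv$carrier` and `sample_pop`.
#' @param base_mort,carrier_mort death probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @param pop_names location labels indexed by population.
#' @param insecticide insecticide label.
#' @return A [sample_table()] (contamination 0, sib groups filled from
#'   `truth$sib_groups`).
#' @export
simulate_phenotypes <- function(truth, base_mort, carrier_mort, seed,
                                pop_names = c("pop1", "pop2"),
                                insecticide = "PM") {
  stopifnot(base_mort >= 0, base_mort <= 1, carrier_mort >= 0, carrier_mort <= 1)
  set.seed(seed)
  samples <- names(truth$sample_pop)
  carrier <- if (!is.null(truth$cnv)) truth$cnv$carrier[samples] else
    stats::setNames(rep(FALSE, length(samples)), samples)
  mort <- ifelse(carrier, carrier_mort, base_mort)
  dead <- stats::runif(length(samples)) < mort
  sib <- rep(NA_character_, length(samples))
  if (!is.null(truth$sib_groups))
    sib[match(truth$sib_groups$sample, samples)] <- truth$sib_groups$group
  sample_table(data.frame(
    sample = samples,
    location = pop_names[truth$sample_pop],
    insecticide = insecticide,
    phenotype = ifelse(dead, "susceptible", "resistant"),
    contamination = 0,
    sib_group = sib,
    stringsAsFactors = FALSE))
}

#' Simulate per-sample contamination fractions
#'
#' Contamination fractions are drawn Uniform(0, `max_frac`). When
#' `target_site` is given with a non-zero `effect`, the genotype at that
#' site is redrawn so its allele dose correlates with contamination (a
#' logistic shift of `effect` log-odds per contamination standard
#' deviation), providing a positive control for the contamination filter.
#'
#' @param g a [genotype_set()] (modified only at `target_site`).
#' @param st a [sample_table()].
#' @param target_site optional 1-based site index.
#' @param effect log-odds of the alternate allele per sd of contamination.
#' @param seed integer seed.
#' @param max_frac upper bound of the contamination fraction.
#' @return A list: updated `sample_table` and `genotypes`.
#' @export
simulate_contamination <- function(g, st, target_site = NULL, effect = 0,
                                   seed, max_frac = 0.05) {
  set.seed(seed)
  n <- nrow(st)
  st$contamination <- stats::runif(n, 0, max_frac)
  if (!is.null(target_site) && effect != 0) {
    z <- as.numeric(scale(st$contamination))
    p <- stats::plogis(stats::qlogis(0.3) + effect * z)
    g$calls[target_site, ] <- stats::rbinom(n, 2L, p)
  }
  list(sample_table = st, genotypes = g)
}

#' Simulate a complete synthetic dataset
#'
#' Runs the whole generator: coalescent haplotypes for two populations, a
#' soft sweep in the focal population, full-sib pairs, a linked CNV with its
#' coverage matrix, mortality phenotypes, and contamination fractions.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `sim_dataset`: `haplotypes`, `genotypes`,
#'   `coverage`, `samples` ([sample_table()]), `regions` (the CNV region),
#'   `truth`, and `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  base <- simulate_haplotypes(cfg)
  sw <- implant_sweep(base$haplotypes, base$truth, block = cfg$sweep$block,
                      f = cfg$sweep$f, mut_rate = cfg$sweep$mut_rate,
                      seed = cfg$seed + 1L, pop = cfg$sweep$pop,
                      core_snps = cfg$sweep$core_snps %||% 0L)
  sb <- make_sib_pairs(sw$haplotypes, sw$truth, cfg$n_sib_pairs,
                       seed = cfg$seed + 2L)
  region <- gene_region("cnv_region", cfg$contig, cfg$cnv$start, cfg$cnv$end)
  cv <- assign_cnv_and_coverage(sb$haplotypes, sb$truth, region,
                                copy_dist = cfg$cnv$copy_dist,
                                link_p = cfg$cnv$link_p,
                                noise_sd = cfg$coverage_noise_sd,
                                seed = cfg$seed + 3L,
                                contig_length = cfg$contig_length)
  st <- simulate_phenotypes(cv$truth, cfg$phenotype$base_mort,
                            cfg$phenotype$carrier_mort, seed = cfg$seed + 4L,
                            pop_names = cfg$pop_names,
                            insecticide = cfg$insecticide)
  g <- genotypes_from_haplotypes(sb$haplotypes)
  ct <- simulate_contamination(g, st,
                               target_site = cfg$contamination$target_site,
                               effect = cfg$contamination$effect,
                               seed = cfg$seed + 5L,
                               max_frac = cfg$contamination$max_frac)
  structure(list(haplotypes = sb$haplotypes, genotypes = ct$genotypes,
                 coverage = cv$coverage, samples = ct$sample_table,
                 regions = region, truth = cv$truth, config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d sites, %d samples, %d coverage windows\n",
              nrow(x$genotypes$sites), length(x$genotypes$samples),
              length(x$coverage$starts)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits `genotypes.vcf` (phased), `samples.tsv`, `coverage.tsv`,
#' `regions.bed` and `truth.tsv` under `dir`.
#'
#' @param ds a `sim_dataset` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_vcf(ds$genotypes, file.path(dir, "genotypes.vcf"),
            haplotypes = ds$haplotypes)
  write_sample_table(ds$samples, file.path(dir, "samples.tsv"))
  write_coverage(ds$coverage, file.path(dir, "coverage.tsv"))
  write_regions(ds$regions, file.path(dir, "regions.bed"))
  truth <- data.frame(sample = names(ds$truth$sample_pop),
                      population = ds$truth$sample_pop,
                      cnv_carrier = ds$truth$cnv$carrier,
                      copy_number = ds$truth$cnv$copy_number)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
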