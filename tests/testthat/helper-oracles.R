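# Independent brute-force implementations used to cross-check the package's
# statistics on small instances. Kept deliberately naive (loops, direct
# formulas) and separate from the implementation code paths.

oracle_garud <- function(p) {
  p <- sort(p, decreasing = TRUE)
  h1 <- 0
  for (x in p) h1 <- h1 + x^2
  h12 <- if (length(p) >= 2) (p[1] + p[2])^2 + sum(p[-(1:2)]^2) else h1
  c(H1 = h1, H12 = h12)
}

oracle_h1x <- function(fa, fb) {
  tot <- 0
  for (nm in union(names(fa), names(fb))) {
    pa <- if (nm %in% names(fa)) fa[[nm]] else 0
    pb <- if (nm %in% names(fb)) fb[[nm]] else 0
    tot <- tot + pa * pb
  }
  tot
}

oracle_hudson_site <- function(a1, n1, a2, n2) {
  a1 <- unname(a1); n1 <- unname(n1); a2 <- unname(a2); n2 <- unname(n2)
  p1 <- a1 / n1; p2 <- a2 / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  c(num = num, den = den)
}

oracle_windowed_fst <- function(ac1, ac2, first, last) {
  num <- den <- 0
  for (i in (first + 1):(last + 1)) {
    s <- oracle_hudson_site(ac1[i, 2], sum(ac1[i, ]), ac2[i, 2], sum(ac2[i, ]))
    num <- num + s["num"]; den <- den + s["den"]
  }
  unname(num / den)
}

oracle_pbs <- function(fst_fs, fst_fo, fst_so) {
  tt <- function(f) -log(1 - f)
  (tt(fst_fs) + tt(fst_fo) - tt(fst_so)) / 2
}

# KING-robust phi for a single pair of genotype vectors (NA = missing).
oracle_king_pair <- function(gi, gj) {
  both <- !is.na(gi) & !is.na(gj)
  gi <- gi[both]; gj <- gj[both]
  n_hethet <- n_opp <- n_het_i <- n_het_j <- 0
  for (k in seq_along(gi)) {
    if (gi[k] == 1) n_het_i <- n_het_i + 1
    if (gj[k] == 1) n_het_j <- n_het_j + 1
    if (gi[k] == 1 && gj[k] == 1) n_hethet <- n_hethet + 1
    if ((gi[k] == 0 && gj[k] == 2) || (gi[k] == 2 && gj[k] == 0))
      n_opp <- n_opp + 1
  }
  if (n_het_i + n_het_j == 0) return(NA_real_)
  (n_hethet - 2 * n_opp) / (n_het_i + n_het_j)
}

oracle_dxy_pair <- function(x, y) mean(x != y)

oracle_modal_state <- function(states) {
  counts <- table(states)
  best <- as.integer(names(counts)[counts == max(counts)])
  min(best)
}

oracle_bh_select <- function(p, q) {
  n <- length(p)
  ord <- order(p)
  k_max <- 0
  for (k in seq_len(n)) if (p[ord[k]] <= q * k / n) k_max <- k
  if (k_max == 0) integer() else sort(ord[seq_len(k_max)])
}

oracle_windowed_gwas <- function(pos, p, top_n, window_bp, min_hits) {
  ord <- order(p, pos)
  top_pos <- pos[ord[seq_len(min(top_n, length(p)))]]
  flagged <- integer()
  for (tile in unique((top_pos - 1) %/% window_bp)) {
    if (sum((top_pos - 1) %/% window_bp == tile) >= min_hits)
      flagged <- c(flagged, tile)
  }
  sort(flagged)
}

# Exhaustive Viterbi over all K^W state paths (tiny instances only).
oracle_viterbi <- function(track, params) {
  K <- params$max_state + 1L
  W <- length(track)
  means <- c(params$zero_floor, seq_len(params$max_state))
  log_self <- log(1 - params$trans_p)
  log_off <- log(params$trans_p / (K - 1L))
  paths <- as.matrix(expand.grid(rep(list(0:(K - 1L)), W)))[, W:1, drop = FALSE]
  best_lp <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    st <- paths[r, ]
    lp <- log(1 / K) + sum(dnorm(track, means[st + 1L], params$sigma, log = TRUE))
    if (W > 1) for (w in 2:W)
      lp <- lp + if (st[w] == st[w - 1]) log_self else log_off
    if (lp > best_lp + 1e-12) { best_lp <- lp; best_path <- st }
  }
  unname(best_path)
}

# Connected components via union-find, for the sib-group graph.
oracle_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && isTRUE(adj[i, j])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
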