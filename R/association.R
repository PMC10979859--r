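#' Binomial-logit GLM for marker-phenotype association
#'
#' Fits `phenotype ~ predictors` with binomial error and logit link via
#' iteratively reweighted least squares (tolerance 1e-8, at most 25
#' iterations). Constant predictors are dropped with a warning. Complete
#' separation is flagged when the fit fails to converge or any coefficient
#' magnitude exceeds 10 log-odds; flagged terms fall back to the
#' likelihood-ratio p-value, which stays well defined under separation.
#'
#' @param y binary response (1 = resistant/alive), or a two-level factor.
#' @param predictors `data.frame` of numeric predictors.
#' @return An object of class `glm_assoc`: `table` (`term`, `estimate`,
#'   `se`, `z`, `p_wald`, `p_lrt`, `p`), `loglik`, `converged`,
#'   `separation`, and the underlying `fit`.
#' @export
glm_binomial <- function(y, predictors) {
  if (is.factor(y) || is.character(y)) y <- as.integer(y == "resistant")
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("phenotype takes a single value: GLM undefined")
  predictors <- as.data.frame(predictors)
  keep <- vapply(predictors, function(v) length(unique(v)) > 1L, logical(1))
  if (!all(keep)) {
    warning("dropping constant predictor(s): ",
            paste(names(predictors)[!keep], collapse = ", "))
    predictors <- predictors[keep]
  }
  if (!ncol(predictors)) stop("no varying predictor")
  dat <- cbind(.y = y, predictors)
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 25L))
  coefs <- summary(fit)$coefficients
  terms <- setdiff(rownames(coefs), "(Intercept)")
  separation <- !fit$converged ||
    any(abs(coefs[terms, "Estimate"]) > 10)
  # LRT p per term (drop-one), used when Wald is unreliable
  p_lrt <- rep(NA_real_, length(terms))
  if (separation && length(terms)) {
    d1 <- stats::drop1(fit, test = "LRT")
    p_lrt <- d1[terms, "Pr(>Chi)"]
  }
  tab <- data.frame(
    term = terms,
    estimate = coefs[terms, "Estimate"],
    se = coefs[terms, "Std. Error"],
    z = coefs[terms, "z value"],
    p_wald = coefs[terms, "Pr(>|z|)"],
    p_lrt = p_lrt,
    stringsAsFactors = FALSE)
  tab$p <- ifelse(separation & !is.na(tab$p_lrt), tab$p_lrt, tab$p_wald)
  rownames(tab) <- NULL
  structure(list(table = tab, loglik = as.numeric(stats::logLik(fit)),
                 converged = fit$converged, separation = separation,
                 fit = fit),
            class = "glm_assoc")
}

#' @export
print.glm_assoc <- function(x, ...) {
  cat(sprintf("<glm_assoc> logLik %.3f%s\n", x$loglik,
              if (x$separation) " [separation: LRT p reported]" else ""))
  print(x$table[c("term", "estimate", "se", "p")], row.names = FALSE)
  invisible(x)
}

#' Single-marker association tests
#'
#' Fits one binomial-logit GLM per marker (with optional shared fixed
#' covariates such as location), using the standard codings: SNP genotypes
#' as the number of mutant alleles (0/1/2), CNV alleles as presence/absence
#' (0/1), gene copy number as the number of extra copies.
#'
#' @param st a [sample_table()] (phenotype is the response).
#' @param markers `data.frame` of numeric markers, rows aligned with `st`.
#' @param covariates optional `data.frame` of fixed covariates included in
#'   every model.
#' @return A `data.frame` with one row per testable marker: `marker`,
#'   `estimate`, `se`, `p`, `separation`. Constant markers are dropped with
#'   a warning.
#' @export
marker_tests <- function(st, markers, covariates = NULL) {
  y <- as.integer(st$phenotype == "resistant")
  out <- lapply(names(markers), function(m) {
    v <- markers[[m]]
    if (length(unique(v[!is.na(v)])) < 2L) {
      warning("marker ", m, " is constant: dropped")
      return(NULL)
    }
    preds <- data.frame(marker = v)
    if (!is.null(covariates)) preds <- cbind(preds, covariates)
    fit <- glm_binomial(y, preds)
    row <- fit$table[fit$table$term == "marker", ]
    data.frame(marker = m, estimate = row$estimate, se = row$se, p = row$p,
               separation = fit$separation, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(marker = character(),
                                      estimate = numeric(), se = numeric(),
                                      p = numeric(), separation = logical())
  rownames(out) <- NULL
  out
}

#' Forward stepwise model building over markers
#'
#' Starting from the null model (optionally containing fixed covariates),
#' the marker giving the smallest likelihood-ratio p-value against the
#' current model is added at each step, as long as that p-value is below
#' `alpha`. Ties are broken by marker order. Markers already in the model
#' or without variation are skipped.
#'
#' @param st a [sample_table()].
#' @param markers `data.frame` of candidate numeric markers.
#' @param alpha inclusion threshold on the LRT p-value (default 0.05).
#' @param covariates optional `data.frame` of fixed covariates.
#' @return A list of class `stepwise_model`: `selected` (markers in entry
#'   order), `p_path` (their LRT p-values at entry), `loglik_path`, and the
#'   final `fit` (`NULL` when nothing is selected and no covariates given).
#' @export
stepwise_build <- function(st, markers, alpha = 0.05, covariates = NULL) {
  y <- as.integer(st$phenotype == "resistant")
  base_df <- if (is.null(covariates)) data.frame(row.names = seq_along(y)) else
    as.data.frame(covariates)
  fit_with <- function(cols) {
    dat <- cbind(.y = y, base_df, markers[cols])
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 25L))
  }
  current <- fit_with(character())
  selected <- character(); p_path <- numeric()
  loglik_path <- as.numeric(stats::logLik(current))
  remaining <- names(markers)[vapply(markers, function(v)
    length(unique(v[!is.na(v)])) > 1L, logical(1))]
  repeat {
    if (!length(remaining)) break
    ll0 <- as.numeric(stats::logLik(current))
    pvals <- vapply(remaining, function(m) {
      cand <- tryCatch(fit_with(c(selected, m)), error = function(e) NULL)
      if (is.null(cand)) return(NA_real_)
      lr <- 2 * (as.numeric(stats::logLik(cand)) - ll0)
      stats::pchisq(max(lr, 0), df = 1L, lower.tail = FALSE)
    }, numeric(1))
    if (all(is.na(pvals))) break
    best <- which.min(pvals)  # first minimum: deterministic tie-break
    if (is.na(pvals[best]) || pvals[best] >= alpha) break
    m <- remaining[best]
    selected <- c(selected, m)
    p_path <- c(p_path, pvals[best])
    current <- fit_with(selected)
    loglik_path <- c(loglik_path, as.numeric(stats::logLik(current)))
    remaining <- setdiff(remaining, m)
  }
  structure(list(selected = selected, p_path = p_path,
                 loglik_path = loglik_path, fit = current),
            class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  if (!length(x$selected)) {
    cat("<stepwise_model> null model (no marker reached the threshold)\n")
  } else {
    cat("<stepwise_model> selected:",
        paste(sprintf("%s (p=%.3g)", x$selected, x$p_path), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Exclude sites whose genotype correlates with sample contamination
#'
#' Per site, the Spearman rank correlation between allele dose and the
#' per-sample contamination fraction is tested; sites with p < `alpha` are
#' excluded (contamination-driven artefact loci). Sites where either
#' variable has zero variance are kept.
#'
#' @param g a [genotype_set()].
#' @param st a [sample_table()] with a `contamination` column.
#' @param alpha exclusion threshold (default 0.05).
#' @return Integer vector of retained 1-based site indices.
#' @export
contamination_filter <- function(g, st, alpha = 0.05) {
  contam <- stats::setNames(st$contamination, st$sample)[g$samples]
  if (length(unique(contam)) < 2L) return(seq_len(nrow(g$sites)))
  keep <- vapply(seq_len(nrow(g$sites)), function(i) {
    dose <- g$calls[i, ]
    ok <- !is.na(dose)
    if (length(unique(dose[ok])) < 2L) return(TRUE)
    p <- suppressWarnings(stats::cor.test(dose[ok], contam[ok],
                                          method = "spearman",
                                          exact = FALSE)$p.value)
    is.na(p) || p >= alpha
  }, logical(1))
  which(keep)
}

#' SNP-wise case-control GWAS
#'
#' Sites are filtered to those with no missing data and minor allele count
#' >= `min_mac`, then contamination-correlated sites are excluded; each
#' remaining site is tested with a binomial-logit GLM of phenotype on
#' allele dose.
#'
#' @param g a [genotype_set()].
#' @param st a [sample_table()] aligned with `g`'s samples.
#' @param min_mac minor allele count threshold (default 5).
#' @param contam_alpha contamination-correlation exclusion threshold.
#' @param covariates optional `data.frame` of fixed covariates.
#' @return A `data.frame` of class `gwas_result`: `site` (1-based index
#'   into `g`), `contig`, `pos`, `mac`, `estimate`, `p`.
#' @export
snp_gwas <- function(g, st, min_mac = 5L, contam_alpha = 0.05,
                     covariates = NULL) {
  gf <- filter_sites(g, min_mac = min_mac, max_missing = 0)
  kept <- attr(gf, "kept")
  retained <- contamination_filter(gf, st, alpha = contam_alpha)
  gf <- subset_sites(gf, retained)
  kept <- kept[retained]
  y <- as.integer(stats::setNames(st$phenotype, st$sample)[gf$samples] ==
                    "resistant")
  ac <- rowSums(gf$calls)
  an <- 2L * length(gf$samples)
  mac <- pmin(ac, an - ac)
  res <- lapply(seq_len(nrow(gf$sites)), function(i) {
    preds <- data.frame(dose = gf$calls[i, ])
    if (!is.null(covariates)) preds <- cbind(preds, covariates)
    fit <- suppressWarnings(glm_binomial(y, preds))
    row <- fit$table[fit$table$term == "dose", ]
    c(estimate = row$estimate, p = row$p)
  })
  res <- do.call(rbind, res)
  out <- data.frame(site = kept, contig = gf$sites$contig, pos = gf$sites$pos,
                    mac = mac, estimate = res[, "estimate"], p = res[, "p"],
                    stringsAsFactors = FALSE)
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Benjamini-Hochberg selection at FDR level q
#'
#' @param p_table a `data.frame` with a `p` column (e.g. from [snp_gwas()]).
#' @param q FDR level (default 0.01).
#' @return The significant subset of `p_table` with an added `q_value`
#'   column (BH-adjusted p).
#' @export
fdr_select <- function(p_table, q = 0.01) {
  p_table$q_value <- stats::p.adjust(p_table$p, method = "BH")
  p_table[p_table$q_value <= q & !is.na(p_table$q_value), , drop = FALSE]
}

#' Windowed GWAS signal detection
#'
#' Ranks sites by p-value (ties by position), takes the `top_n` most
#' significant, tiles each contig with non-overlapping `window_bp` windows
#' starting at `offset`, and flags windows containing at least `min_hits`
#' of the top sites.
#'
#' @param p_table a `data.frame` with `contig`, `pos`, `p` columns.
#' @param top_n number of most-significant sites considered (default 1000).
#' @param window_bp tile width in bp (default 100000).
#' @param min_hits minimum top-site count to flag a window (default 10).
#' @param offset tile phase in bp (default 0).
#' @return A `data.frame`: `contig`, `start`, `end` (0-based half-open
#'   tiles), `n_hits`, `flagged`; only tiles containing at least one top
#'   site are listed.
#' @export
windowed_gwas <- function(p_table, top_n = 1000L, window_bp = 100000L,
                          min_hits = 10L, offset = 0L) {
  ord <- order(p_table$p, p_table$pos)
  top <- p_table[ord[seq_len(min(top_n, nrow(p_table)))], ]
  tile <- (top$pos - 1L - offset) %/% window_bp
  key <- paste(top$contig, tile)
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " (?=[^ ]+$)", perl = TRUE))
  out <- data.frame(contig = parts[, 1],
                    start = as.integer(parts[, 2]) * window_bp + offset,
                    n_hits = as.integer(tab), stringsAsFactors = FALSE)
  out$end <- out$start + window_bp
  out$flagged <- out$n_hits >= min_hits
  out <- out[order(out$contig, out$start), c("contig", "start", "end",
                                             "n_hits", "flagged")]
  rownames(out) <- NULL
  out
}

#' Monte Carlo power of the CNV presence/absence association test
#'
#' Simulates cohorts of `n` individuals in which each is a CNV carrier with
#' probability `carrier_freq` and dies with probability `mort_wt`
#' (non-carrier) or `mort_carrier` (carrier), then fits the binomial-logit
#' GLM of phenotype (alive = 1) on carrier status. Power is the fraction of
#' simulations with a carrier-term p-value below `alpha` (likelihood-ratio
#' fallback under separation); replicates where phenotype or carrier status
#' is constant are counted as non-significant.
#'
#' @param n cohort size per simulation.
#' @param carrier_freq CNV carrier probability.
#' @param mort_wt,mort_carrier death probabilities for non-carriers and
#'   carriers.
#' @param n_sims number of Monte Carlo replicates (default 1000).
#' @param alpha significance criterion (default 0.05).
#' @param seed integer seed.
#' @return An object of class `power_result`: `power`, `se` (Monte Carlo
#'   standard error), `n_sims`, `alpha`, `n_degenerate`.
#' @export
cnv_power_simulation <- function(n, carrier_freq, mort_wt, mort_carrier,
                                 n_sims = 1000L, alpha = 0.05, seed) {
  stopifnot(n >= 2L, carrier_freq >= 0, carrier_freq <= 1,
            mort_wt >= 0, mort_wt <= 1, mort_carrier >= 0, mort_carrier <= 1)
  set.seed(seed)
  sig <- logical(n_sims)
  n_degenerate <- 0L
  for (i in seq_len(n_sims)) {
    carrier <- stats::rbinom(n, 1L, carrier_freq)
    dead <- stats::rbinom(n, 1L, ifelse(carrier == 1L, mort_carrier, mort_wt))
    y <- 1L - dead
    if (length(unique(y)) < 2L || length(unique(carrier)) < 2L) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    fit <- suppressWarnings(glm_binomial(y, data.frame(carrier = carrier)))
    p <- fit$table$p[fit$table$term == "carrier"]
    sig[i] <- isTRUE(p < alpha)
  }
  power <- mean(sig)
  structure(list(power = power,
                 se = sqrt(power * (1 - power) / n_sims),
                 n_sims = n_sims, alpha = alpha,
                 n_degenerate = n_degenerate),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("<power_result> power %.3f (MC se %.3f) from %d simulations at alpha %.3g\n",
              x$power, x$se, x$n_sims, x$alpha))
  if (x$n_degenerate > 0L)
    cat(sprintf("  %d degenerate replicate(s) counted non-significant\n",
                x$n_degenerate))
  invisible(x)
}
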