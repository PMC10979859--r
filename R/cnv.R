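#' Parameters of the coverage copy-number HMM
#'
#' States are total copy numbers 0..`2 + max_extra` (diploid 2 plus up to
#' `max_extra` extra copies; 10 by default, so 13 states). Emissions are
#' Normal(state, `sigma`) on the normalised coverage scale where diploid
#' coverage is 2; the copy-0 state emits around `zero_floor` instead of an
#' exact zero mean. Transitions keep the current state with probability
#' `1 - trans_p` and split `trans_p` equally among the other states, making
#' single-window state flips unlikely at the default `trans_p = 1e-4`.
#'
#' @param max_extra maximum extra copies above diploid (default 10).
#' @param sigma emission standard deviation (default 0.5).
#' @param trans_p total probability of leaving the current state per window.
#' @param zero_floor emission mean of the copy-0 state.
#' @return A list of class `coverage_hmm_params`.
#' @export
coverage_hmm_params <- function(max_extra = 10L, sigma = 0.5, trans_p = 1e-4,
                                zero_floor = 0.1) {
  stopifnot(sigma > 0, trans_p > 0, trans_p < 1, max_extra >= 0)
  structure(list(max_state = 2L + as.integer(max_extra), sigma = sigma,
                 trans_p = trans_p, zero_floor = zero_floor),
            class = "coverage_hmm_params")
}

#' Viterbi decoding of one coverage track
#'
#' Decodes the most likely copy-number state sequence for one sample's
#' per-window normalised coverage, with a uniform initial distribution.
#' Ties in the path score are broken toward the lower state.
#'
#' @param track numeric vector of non-negative normalised coverage values.
#' @param params a [coverage_hmm_params()].
#' @return Integer vector of decoded total copy-number states (0-based
#'   states: values 0..`max_state`).
#' @export
hmm_decode <- function(track, params = coverage_hmm_params()) {
  if (!length(track)) stop("empty coverage track")
  drop(hmm_decode_matrix(matrix(track, ncol = 1L), params))
}

# Vectorised Viterbi over samples: cov is windows x samples; returns a
# windows x samples integer matrix of states.
hmm_decode_matrix <- function(cov, params = coverage_hmm_params()) {
  stopifnot(all(is.finite(cov)), all(cov >= 0))
  K <- params$max_state + 1L
  n_w <- nrow(cov); n_s <- ncol(cov)
  means <- c(params$zero_floor, seq_len(params$max_state))
  log_self <- log(1 - params$trans_p)
  log_off <- log(params$trans_p / (K - 1L))
  emis <- function(x) {
    # n_s x K matrix of log emission densities for one window
    outer(x, means, function(xx, mm) stats::dnorm(xx, mm, params$sigma, log = TRUE))
  }
  v <- matrix(log(1 / K), n_s, K) + emis(cov[1L, ])
  bp <- array(0L, dim = c(n_w, n_s, K))
  if (n_w > 1L) for (w in 2L:n_w) {
    e <- emis(cov[w, ])
    new_v <- matrix(-Inf, n_s, K)
    for (j in seq_len(K)) {
      trans <- rep(log_off, K); trans[j] <- log_self
      cand <- sweep(v, 2L, trans, "+")
      best <- max.col(cand, ties.method = "first")
      bp[w, , j] <- best
      new_v[, j] <- cand[cbind(seq_len(n_s), best)] + e[, j]
    }
    v <- new_v
  }
  states <- matrix(0L, n_w, n_s)
  last <- max.col(v, ties.method = "first")
  states[n_w, ] <- last - 1L
  if (n_w > 1L) for (w in n_w:2L) {
    last <- bp[cbind(w, seq_len(n_s), last)]
    states[w - 1L, ] <- last - 1L
  }
  states
}

#' Decode copy-number states for every sample of a coverage matrix
#'
#' @param cov a [coverage_matrix()].
#' @param params a [coverage_hmm_params()].
#' @return Integer matrix, windows x samples, of decoded states.
#' @export
decode_coverage <- function(cov, params = coverage_hmm_params()) {
  stopifnot(inherits(cov, "coverage_matrix"))
  states <- hmm_decode_matrix(cov$coverage, params)
  colnames(states) <- cov$samples
  states
}

#' Modal copy number of a gene from decoded states
#'
#' The gene's copy number is the modal HMM state over the coverage windows
#' overlapping the gene region; ties are broken toward the lower state.
#'
#' @param states integer vector of decoded states for one sample (aligned
#'   with `starts`).
#' @param region one-row [gene_region()].
#' @param starts 0-based window starts of the coverage grid.
#' @param width window width in bp.
#' @return Integer modal state.
#' @export
gene_copy_number <- function(states, region, starts, width = 300L) {
  idx <- which(starts < region$end & (starts + width) > region$start)
  if (!length(idx)) stop("no coverage window overlaps region ", region$name)
  tab <- table(states[idx])
  min(as.integer(names(tab)[tab == max(tab)]))
}

#' Median-coverage copy number for high-amplitude CNVs
#'
#' The HMM saturates at its maximum state, so for highly amplified regions
#' the copy number is instead estimated as the median raw normalised
#' coverage over the windows falling fully inside the region, minus 2 (the
#' normal diploid copy number).
#'
#' @param cov a [coverage_matrix()].
#' @param region one-row [gene_region()].
#' @return Named numeric vector of extra-copy estimates per sample.
#' @export
region_median_copy_number <- function(cov, region) {
  idx <- which(cov$starts >= region$start & (cov$starts + cov$width) <= region$end)
  if (!length(idx)) stop("no coverage window inside region ", region$name)
  med <- apply(cov$coverage[idx, , drop = FALSE], 2L, stats::median)
  stats::setNames(med - 2, cov$samples)
}

#' Copy-number calls per sample and region
#'
#' Decodes every sample's coverage track and reports, per region, the modal
#' state, the extra copies (modal state minus 2) and the carrier flag
#' (extra copies > 0).
#'
#' @param cov a [coverage_matrix()].
#' @param regions a [gene_region()] table.
#' @param params a [coverage_hmm_params()].
#' @param states optional precomputed state matrix from [decode_coverage()].
#' @return A `data.frame` of class `copy_number_calls`: `sample`, `region`,
#'   `state`, `extra_copies`, `carrier`.
#' @export
cnv_call <- function(cov, regions, params = coverage_hmm_params(),
                     states = NULL) {
  if (is.null(states)) states <- decode_coverage(cov, params)
  out <- do.call(rbind, lapply(seq_len(nrow(regions)), function(r) {
    modal <- vapply(seq_along(cov$samples), function(s) {
      gene_copy_number(states[, s], regions[r, ], cov$starts, cov$width)
    }, integer(1))
    data.frame(sample = cov$samples, region = regions$name[r],
               state = modal, extra_copies = modal - 2L,
               carrier = modal > 2L, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("copy_number_calls", "data.frame")
  out
}

#' Presence/absence carrier table
#'
#' @param calls a `copy_number_calls` table from [cnv_call()].
#' @return A logical matrix, samples x regions, `TRUE` where extra copies
#'   are > 0.
#' @export
carrier_table <- function(calls) {
  samples <- unique(calls$sample)
  regions <- unique(calls$region)
  out <- matrix(FALSE, length(samples), length(regions),
                dimnames = list(samples, regions))
  out[cbind(match(calls$sample, samples), match(calls$region, regions))] <-
    calls$extra_copies > 0L
  out
}
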