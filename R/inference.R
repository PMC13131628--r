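#' Local false sign rate of a scalar effect
#'
#' The LFSR summarizes confidence in the sign of an effect from its
#' posterior draws:
#' \deqn{LFSR = \min\{P(D \ge 0 \mid \cdot),\ P(D \le 0 \mid \cdot)\}}
#' estimated by the corresponding empirical fractions of draws. Draws
#' exactly equal to zero count toward both tails (both inequalities are
#' inclusive), so the value lies in [0, 0.5] up to the granularity of the
#' draw count. Small values mean the sign of the effect is confidently
#' determined.
#'
#' @param draws numeric vector of posterior draws of a scalar effect.
#' @return LFSR value in [0, 0.5] (can slightly exceed 0.5 only when ties
#'   at zero are counted in both tails; capped at 0.5).
#' @examples
#' lfsr(c(-1, 2, 3, 4))  # 0.25
#' @export
lfsr <- function(draws) {
  if (length(draws) == 0) stop("lfsr needs at least one draw")
  min(mean(draws >= 0), mean(draws <= 0), 0.5)
}

#' Detect differentially abundant isoforms at an LFSR threshold
#'
#' @param lfsr_values named numeric vector of per-isoform LFSR values.
#' @param alpha threshold in (0, 0.5]; default 0.05.
#' @return character vector of isoform ids with LFSR <= alpha.
#' @export
detect_differential <- function(lfsr_values, alpha = 0.05) {
  if (alpha <= 0 || alpha > 0.5) stop("alpha must lie in (0, 0.5]")
  ids <- names(lfsr_values) %||% as.character(seq_along(lfsr_values))
  ids[lfsr_values <= alpha]
}

#' Consensus detections across chains
#'
#' Counts, for each isoform, in how many chains it was detected, and forms
#' the consensus set of isoforms detected in at least \code{gamma} chains
#' (the minimum agreement factor).
#'
#' @param per_chain list of character vectors (detections per chain).
#' @param gamma minimum number of agreeing chains, in 1..n_chains.
#' @param ids optional universe of isoform ids (those never detected get
#'   frequency 0).
#' @return list with \code{consensus} (ids with frequency >= gamma) and
#'   \code{frequency} (named integer vector over \code{ids}).
#' @export
consensus_detections <- function(per_chain, gamma, ids = NULL) {
  n_chains <- length(per_chain)
  if (gamma < 1 || gamma > n_chains)
    stop("gamma must lie in 1..", n_chains)
  ids <- ids %||% sort(unique(unlist(per_chain)))
  freq <- vapply(ids, function(id)
    sum(vapply(per_chain, function(d) id %in% d, logical(1))), integer(1))
  names(freq) <- ids
  list(consensus = ids[freq >= gamma], frequency = freq)
}

#' Filter isoforms by cross-chain stability of their abundance estimate
#'
#' For each isoform, takes the per-chain mean abundance (already averaged
#' over samples), computes its variance over chains, and retains the
#' isoform when that variance falls below the threshold. Isoforms whose
#' abundance estimate depends on the chain are unreliable and excluded from
#' downstream correlation analyses.
#'
#' @param per_chain_means chains x q matrix of per-chain mean abundances.
#' @param threshold retain when variance < threshold; default 1.
#' @return named logical keep mask of length q.
#' @export
chain_stability_filter <- function(per_chain_means, threshold = 1) {
  per_chain_means <- as.matrix(per_chain_means)
  if (nrow(per_chain_means) < 2)
    stop("stability filtering needs at least 2 chains")
  v <- apply(per_chain_means, 2, stats::var)
  stats::setNames(v < threshold,
                  colnames(per_chain_means) %||%
                    as.character(seq_len(ncol(per_chain_means))))
}

#' Empirical posterior summary
#'
#' @param draws numeric vector of posterior draws (>= 2).
#' @param level central credible level, default 0.95.
#' @return list with \code{mean}, \code{sd}, \code{lower}, \code{upper}
#'   (equal-tailed interval).
#' @export
summarize_posterior <- function(draws, level = 0.95) {
  if (length(draws) < 2) stop("need at least two draws to summarize")
  qs <- stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(mean = mean(draws), sd = stats::sd(draws),
       lower = qs[1], upper = qs[2])
}

#' Differential-abundance results table
#'
#' Combines the chains of a fit into the standard results table. Posterior
#' mean and SD of each condition effect pool the draws of all chains;
#' detection follows each chain's own LFSR (the \code{detection_count}
#' column), with the \code{detected} flag requiring agreement of at least
#' \code{gamma} chains. Setting \code{pooled = TRUE} instead flags
#' detection from the pooled-draw LFSR.
#'
#' @param chains list of \code{iso_draws} (or an \code{isofactor} fit).
#' @param alpha LFSR threshold, default 0.05.
#' @param gamma minimum agreement count; default is a strict majority of
#'   chains.
#' @param pooled logical; base the \code{detected} flag on pooled draws.
#' @return data.frame with columns \code{isoform_id}, \code{post_mean_D},
#'   \code{post_sd_D}, \code{lfsr} (pooled draws), \code{pip} (spike-and-
#'   slab only, else NA), \code{detected}, \code{detection_count}.
#' @export
differential_results <- function(chains, alpha = 0.05, gamma = NULL,
                                 pooled = FALSE) {
  if (inherits(chains, "isofactor")) chains <- chains$chains
  if (is.null(chains[[1]]$D))
    stop("no condition effects in these draws (condition vector was absent)")
  n_chains <- length(chains)
  gamma <- gamma %||% (floor(n_chains / 2) + 1L)
  ids <- colnames(chains[[1]]$D)
  q <- length(ids)

  Dall <- do.call(rbind, lapply(chains, `[[`, "D"))
  per_chain_lfsr <- vapply(chains, function(ch)
    apply(ch$D, 2, lfsr), numeric(q))
  per_chain_lfsr <- matrix(per_chain_lfsr, nrow = q)
  counts <- rowSums(per_chain_lfsr <= alpha)
  pooled_lfsr <- apply(Dall, 2, lfsr)

  pip <- if (!is.null(chains[[1]]$gamma_ind))
    colMeans(do.call(rbind, lapply(chains, `[[`, "gamma_ind")))
  else rep(NA_real_, q)

  detected <- if (pooled) pooled_lfsr <= alpha else counts >= gamma
  data.frame(
    isoform_id = ids,
    post_mean_D = colMeans(Dall),
    post_sd_D = apply(Dall, 2, stats::sd),
    lfsr = pooled_lfsr,
    pip = pip,
    detected = detected,
    detection_count = as.integer(counts),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
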