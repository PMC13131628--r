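#' Fit the Bayesian supervised isoform factor model
#'
#' Estimates latent protein-isoform abundances from peptide-level
#' mass-spectrometry data, optionally supervised by matched transcript
#' expression, via Gibbs sampling of the two-layer model
#' \deqn{I = I^0 + TW + AD^\top + E_I, \qquad P = IZ + E_P,}
#' where \eqn{I} (n x q) are the latent isoform abundances, \eqn{W} a
#' diagonal matrix of transcript-to-isoform conversion weights, \eqn{D} the
#' vector of binary-condition effects, \eqn{Z} the masked q x r
#' detectability matrix, \eqn{E_I} unit-variance Gaussian noise and
#' \eqn{E_P} heteroskedastic Gaussian noise with per-peptide variances.
#' Priors are described in [prior_config()]. Transcripts and condition are
#' optional: the model runs from peptides and a compatibility mask alone.
#'
#' Before sampling, the dataset is validated ([validate_dataset()]),
#' isoforms with identical peptide support are rolled up into groups
#' ([group_isoforms()]; a group's transcript column is the mean of its
#' members'), and the mask is decomposed into independent blocks
#' ([decompose_blocks()]) sampled with separate deterministic random
#' streams.
#'
#' @param peptides n x r peptide abundance matrix (log scale), or an
#'   [iso_dataset()] (in which case \code{mask}, \code{transcripts},
#'   \code{condition} are ignored).
#' @param mask q x r binary compatibility matrix.
#' @param transcripts optional n x q transcript matrix (log scale).
#' @param condition optional length-n 0/1 vector.
#' @param prior an [iso_prior][prior_config()].
#' @param chains,iter,burnin,thin,seed sampler settings; see
#'   [chain_config()]. Defaults: 10 chains of 3000 iterations with 2000
#'   burn-in.
#' @param alpha LFSR threshold used by the summary methods.
#' @param group roll up isoforms with identical peptide support (default
#'   TRUE).
#' @param bounds_nonpositive how [truncation_bounds()] treats nonpositive
#'   peptide column means: \code{"abs"} (default for fitting; ratio of
#'   absolute means) or \code{"error"}.
#' @param sweep_mode forwarded to [run_chain()].
#' @return an object of class \code{isofactor}: a list with the
#'   (post-grouping) \code{data}, \code{groups} map, \code{blocks},
#'   \code{prior}, \code{config}, the list of per-chain draws
#'   (\code{chains}), the cross-chain differential table
#'   (\code{differential}), pooled posterior means \code{I_mean} (n x q)
#'   and \code{Z_mean} (q x r), and the \code{call}.
#' @examples
#' sim <- simulate_easy(n = 60, effect = 1, seed = 1)
#' fit <- isofactor(sim$data, chains = 2, iter = 400, burnin = 200, seed = 1)
#' coef(fit)$D
#' summary(fit)
#' @export
isofactor <- function(peptides, mask = NULL, transcripts = NULL,
                      condition = NULL, prior = prior_config(),
                      chains = 10, iter = 3000, burnin = 2000, thin = 1,
                      seed = 1, alpha = 0.05, group = TRUE,
                      bounds_nonpositive = c("abs", "error"),
                      sweep_mode = "block") {
  cl <- match.call()
  bounds_nonpositive <- match.arg(bounds_nonpositive)
  data <- if (inherits(peptides, "iso_dataset")) peptides
          else iso_dataset(peptides, mask, transcripts, condition)

  rep0 <- validate_dataset(data)
  if (nrow(rep0) > 0)
    stop("dataset fails validation:\n  ",
         paste(rep0$check, rep0$detail, sep = ": ", collapse = "\n  "))

  groups <- NULL
  if (group) {
    g <- group_isoforms(data$mask)
    if (nrow(g$mask) < data$q) {
      groups <- g
      # a group's transcript column is the mean of its members' columns, so
      # grouped isoforms keep transcript supervision
      Tg <- NULL
      if (!is.null(data$T)) {
        Tg <- vapply(rownames(g$mask), function(gid) {
          members <- g$groups$member_id[g$groups$group_id == gid]
          rowMeans(data$T[, members, drop = FALSE])
        }, numeric(data$n))
      }
      data <- iso_dataset(data$P, g$mask, Tg, data$A,
                          sample_ids = data$sample_ids,
                          isoform_ids = rownames(g$mask),
                          peptide_ids = data$peptide_ids)
    }
  }

  cc <- chain_config(n_iter = iter, burn_in = burnin, n_chains = chains,
                     base_seed = seed, thinning = thin)
  draws <- run_chains(data, prior, cc, sweep_mode = sweep_mode,
                      nonpositive = bounds_nonpositive)

  q <- data$q
  r <- data$r
  Z_mean <- Reduce(`+`, lapply(draws, zbar_matrix, q = q, r = r)) /
    length(draws)
  dimnames(Z_mean) <- dimnames(data$mask)
  I_mean <- Reduce(`+`, lapply(draws, `[[`, "I_mean")) / length(draws)

  differential <- if (!is.null(data$A))
    differential_results(draws, alpha = alpha)

  structure(
    list(call = cl, data = data, groups = groups,
         blocks = decompose_blocks(data$mask), prior = prior, config = cc,
         chains = draws, differential = differential,
         I_mean = I_mean, Z_mean = Z_mean, alpha = alpha),
    class = "isofactor"
  )
}

#' @export
print.isofactor <- function(x, ...) {
  d <- x$data
  cat("Bayesian isoform factor model fit\n")
  cat(sprintf("  %d samples, %d isoforms, %d peptides, %d blocks\n",
              d$n, d$q, d$r, length(x$blocks)))
  cat(sprintf("  %d chain(s) x %d iterations (%d burn-in), %s prior\n",
              x$config$n_chains, x$config$n_iter, x$config$burn_in,
              x$prior$family))
  if (!is.null(x$differential)) {
    cat(sprintf("  %d isoform(s) detected at LFSR <= %g (>= %d of %d chains)\n",
                sum(x$differential$detected), x$alpha,
                floor(x$config$n_chains / 2) + 1L, x$config$n_chains))
  } else {
    cat("  no condition vector: differential analysis unavailable\n")
  }
  invisible(x)
}

#' @export
summary.isofactor <- function(object, ...) {
  out <- list(fit = object, differential = object$differential,
              W = if (!is.null(object$data$T)) pooled_summary(object, "W"),
              I0 = pooled_summary(object, "I0"))
  class(out) <- "summary.isofactor"
  out
}

pooled_summary <- function(object, param) {
  M <- do.call(rbind, lapply(object$chains, `[[`, param))
  data.frame(isoform_id = colnames(M), mean = colMeans(M),
             sd = apply(M, 2, stats::sd), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @export
print.summary.isofactor <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$differential)) {
    cat("\nCondition effects (pooled draws):\n")
    print(utils::head(x$differential[order(x$differential$lfsr), ], 10),
          digits = 3, row.names = FALSE)
  }
  if (!is.null(x$W)) {
    cat("\nConversion weights W:\n")
    print(utils::head(x$W, 5), digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.isofactor <- function(object, ...) {
  out <- list(I0 = colMeans(do.call(rbind,
                                    lapply(object$chains, `[[`, "I0"))))
  if (!is.null(object$data$T))
    out$W <- colMeans(do.call(rbind, lapply(object$chains, `[[`, "W")))
  if (!is.null(object$data$A))
    out$D <- colMeans(do.call(rbind, lapply(object$chains, `[[`, "D")))
  out$Z <- object$Z_mean
  out
}

#' @export
fitted.isofactor <- function(object, ...) object$I_mean

#' @export
residuals.isofactor <- function(object, ...) {
  object$data$P - object$I_mean %*% object$Z_mean
}

#' Predict latent isoform (or peptide) abundances for new samples
#'
#' Uses pooled posterior means of the structural parameters:
#' \eqn{\hat I = \hat I^0 + T\hat W + A\hat D^\top}, and for
#' \code{layer = "peptide"} additionally \eqn{\hat P = \hat I \hat Z}.
#'
#' @param object an \code{isofactor} fit.
#' @param transcripts,condition new observed layers (either may be NULL,
#'   matching the fitted model).
#' @param layer \code{"isoform"} (default) or \code{"peptide"}.
#' @param ... unused.
#' @export
predict.isofactor <- function(object, transcripts = NULL, condition = NULL,
                              layer = c("isoform", "peptide"), ...) {
  layer <- match.arg(layer)
  co <- coef(object)
  n <- if (!is.null(transcripts)) nrow(transcripts)
       else if (!is.null(condition)) length(condition)
       else object$data$n
  I_hat <- matrix(rep(co$I0, each = n), n, object$data$q,
                  dimnames = list(NULL, object$data$isoform_ids))
  if (!is.null(transcripts) && !is.null(co$W))
    I_hat <- I_hat + sweep(as.matrix(transcripts), 2, co$W, `*`)
  if (!is.null(condition) && !is.null(co$D))
    I_hat <- I_hat + outer(as.numeric(condition), co$D)
  if (layer == "isoform") I_hat else I_hat %*% co$Z
}

#' Posterior-predictive peptide data
#'
#' Draws replicate peptide matrices from the posterior predictive: a
#' retained draw of (Z, sigma2) is sampled per replicate and combined with
#' the pooled posterior mean of the latent abundances.
#'
#' @param object an \code{isofactor} fit.
#' @param nsim number of replicates.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of n x r matrices.
#' @export
simulate.isofactor <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$data
  lapply(seq_len(nsim), function(s) {
    ch <- object$chains[[sample.int(length(object$chains), 1)]]
    it <- sample.int(ch$n_draws, 1)
    Z <- matrix(0, d$q, d$r)
    Z[ch$Z_support] <- ch$Z[it, ]
    mu <- object$I_mean %*% Z
    mu + matrix(stats::rnorm(d$n * d$r, sd = rep(sqrt(ch$sigma2[it, ]),
                                                 each = d$n)),
                d$n, d$r)
  })
}

#' Plot condition-effect posteriors
#'
#' Shows the pooled posterior mean of each condition effect with its
#' central 95% interval, colored by detection status.
#'
#' @param x an \code{isofactor} fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.isofactor <- function(x, ...) {
  if (is.null(x$differential))
    stop("nothing to plot: fit has no condition effects")
  Dall <- do.call(rbind, lapply(x$chains, `[[`, "D"))
  qs <- apply(Dall, 2, stats::quantile, probs = c(0.025, 0.975))
  m <- colMeans(Dall)
  q <- length(m)
  cols <- ifelse(x$differential$detected, "firebrick", "grey40")
  graphics::plot(seq_len(q), m, ylim = range(qs), pch = 19, col = cols,
                 xlab = "isoform", ylab = "condition effect D",
                 xaxt = if (q <= 30) "n" else "s", ...)
  if (q <= 30)
    graphics::axis(1, at = seq_len(q), labels = colnames(Dall), las = 2,
                   cex.axis = 0.7)
  graphics::segments(seq_len(q), qs[1, ], seq_len(q), qs[2, ], col = cols)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
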