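#' Prior configuration for the isoform factor model
#'
#' The model places conjugate priors on every parameter so that all Gibbs
#' full conditionals are closed-form:
#' \itemize{
#'   \item conversion weights \eqn{W_{jj} \sim N(1, \tau_w)} -- prior mean 1
#'     encodes proportionality between a transcript and its isoform;
#'   \item condition effects \eqn{D_j \sim N(0, \tau_d)}, or under the
#'     spike-and-slab family \eqn{\theta N(0, \tau_d) + (1-\theta)\delta_0};
#'   \item detectability coefficients \eqn{Z_{jk}} on the mask support
#'     \eqn{\sim} truncated \eqn{N(1, \tau_z)} on data-driven bounds
#'     (see [truncation_bounds()]); off support they are exactly 0;
#'   \item intercepts \eqn{I^0_j \sim N(\mu_0, \tau_{i0})}, where \eqn{\mu_0}
#'     can carry external average expression levels;
#'   \item latent abundances \eqn{I_{ij} \sim N(I^0_j + T_{ij}W_{jj} +
#'     A_i D_j, 1)} -- unit variance, fixed;
#'   \item peptide noise variances \eqn{\sigma^2_k \sim}
#'     InverseGamma(\code{noise_a0}, \code{noise_b0}).
#' }
#'
#' All \code{tau_*} arguments accept a scalar (broadcast over isoforms) or a
#' length-q vector.
#'
#' @param family \code{"normal"} (default, recommended) or
#'   \code{"spike_slab"} for sparser, more conservative effect inference.
#' @param tau_w,tau_d,tau_z,tau_i0 positive prior variances.
#' @param theta spike-and-slab prior inclusion probability, in (0, 1].
#' @param noise_a0,noise_b0 positive inverse-gamma shape/rate for the
#'   peptide noise variances.
#' @param i0_mean prior mean for the intercepts (scalar or length q).
#' @return an object of class \code{iso_prior}.
#' @export
prior_config <- function(family = c("normal", "spike_slab"),
                         tau_w = 1, tau_d = 1, tau_z = 1, tau_i0 = 1,
                         theta = 0.5, noise_a0 = 1, noise_b0 = 1,
                         i0_mean = 0) {
  family <- match.arg(family)
  for (nm in c("tau_w", "tau_d", "tau_z", "tau_i0")) {
    v <- get(nm)
    if (any(!is.finite(v)) || any(v <= 0))
      stop("prior variance `", nm, "` must be positive and finite")
  }
  if (theta <= 0 || theta > 1) stop("`theta` must lie in (0, 1]")
  if (noise_a0 <= 0 || noise_b0 <= 0)
    stop("noise hyperparameters must be positive")
  structure(
    list(family = family, tau_w = tau_w, tau_d = tau_d, tau_z = tau_z,
         tau_i0 = tau_i0, theta = theta, noise_a0 = noise_a0,
         noise_b0 = noise_b0, i0_mean = i0_mean),
    class = "iso_prior"
  )
}

# broadcast a scalar-or-vector prior parameter to isoform j
prior_at <- function(x, j) if (length(x) == 1L) x else x[[j]]

#' @export
print.iso_prior <- function(x, ...) {
  cat("iso_prior (", x$family, " family)\n", sep = "")
  cat(sprintf("  tau_w=%s tau_d=%s tau_z=%s tau_i0=%s\n",
              paste(signif(x$tau_w, 3), collapse = ","),
              paste(signif(x$tau_d, 3), collapse = ","),
              paste(signif(x$tau_z, 3), collapse = ","),
              paste(signif(x$tau_i0, 3), collapse = ",")))
  if (x$family == "spike_slab") cat("  theta =", x$theta, "\n")
  cat(sprintf("  noise ~ InvGamma(%g, %g)\n", x$noise_a0, x$noise_b0))
  invisible(x)
}

#' Data-driven truncation bounds for detectability coefficients
#'
#' For isoform j, the prior on each on-support detectability coefficient is
#' a normal truncated to \eqn{[\bar l_j, \bar u_j]} where
#' \eqn{\bar l_j = \bar P_j^{min} / \bar P_j^{max}} is the ratio of the
#' smallest to the largest per-peptide column mean among peptides compatible
#' with j, and \eqn{\bar u_j = 1 / \bar l_j}. The bounds tie the scale of
#' the latent isoform to the observed peptide level: an isoform cannot map
#' onto its peptides with relative weights more extreme than the peptides'
#' observed relative abundances.
#'
#' The ratio only makes sense when the compatible column means are positive
#' on the working scale. By default a nonpositive mean is an error telling
#' the caller to shift or rescale; \code{nonpositive = "abs"} instead forms
#' the ratio of absolute means, which keeps the bounds bracketing 1.
#'
#' @param P n x r peptide matrix on the working (log) scale.
#' @param mask q x r compatibility mask.
#' @param j isoform index (row of \code{mask}).
#' @param nonpositive \code{"error"} (default) or \code{"abs"}.
#' @return list with \code{lower} and \code{upper}; always
#'   \code{0 < lower <= 1 <= upper} and \code{lower * upper == 1}.
#' @examples
#' P <- cbind(rep(2, 4), rep(8, 4))
#' truncation_bounds(P, matrix(1, 1, 2), 1)  # lower 0.25, upper 4
#' @export
truncation_bounds <- function(P, mask, j, nonpositive = c("error", "abs")) {
  nonpositive <- match.arg(nonpositive)
  ks <- which(mask[j, ] != 0)
  if (length(ks) == 0)
    stop("isoform ", j, " has no compatible peptide")
  m <- colMeans(P[, ks, drop = FALSE])
  if (any(m <= 0)) {
    if (nonpositive == "error")
      stop("nonpositive peptide column mean for isoform ", j,
           "; shift or rescale the peptide matrix to a positive working scale")
    m <- abs(m)
    if (any(m == 0))
      stop("zero peptide column mean for isoform ", j,
           "; bounds are undefined")
  }
  l <- min(m) / max(m)
  list(lower = l, upper = 1 / l)
}

# bounds for every isoform at once; returns list(lower, upper) length-q
all_truncation_bounds <- function(P, mask, nonpositive = "error") {
  q <- nrow(mask)
  lower <- upper <- numeric(q)
  for (j in seq_len(q)) {
    b <- truncation_bounds(P, mask, j, nonpositive)
    lower[j] <- b$lower
    upper[j] <- b$upper
  }
  list(lower = lower, upper = upper)
}

#' Joint log prior density of a model state
#'
#' Sums the log densities of the five structural prior layers: the
#' conversion weights W (when transcripts are present), the condition
#' effects D (normal, or spike-and-slab through the inclusion indicators),
#' the on-support detectability coefficients Z (truncated normal; any
#' on-support value outside its truncation bounds, or any off-support value
#' other than 0, gives \code{-Inf}), the intercepts I0, and the latent
#' abundances I around their structural mean \eqn{I^0 + TW + AD} with unit
#' variance. The inverse-gamma density of the peptide noise variances is not
#' part of this sum (it belongs to the likelihood layer's hyperprior).
#'
#' @param state list with elements \code{I0}, \code{W}, \code{D}, \code{Z},
#'   \code{I}, and for the spike-and-slab family \code{gamma_ind}.
#' @param data an [iso_dataset()].
#' @param prior an [iso_prior][prior_config()].
#' @param bounds optional precomputed [truncation_bounds()] (list of
#'   \code{lower}/\code{upper} vectors); computed from \code{data} if absent.
#' @return scalar log density; \code{-Inf} for states violating the Z
#'   support/truncation contract.
#' @export
log_prior_density <- function(state, data, prior, bounds = NULL) {
  stopifnot(inherits(data, "iso_dataset"), inherits(prior, "iso_prior"))
  q <- data$q
  if (is.null(bounds))
    bounds <- all_truncation_bounds(data$P, data$mask, "error")

  lp <- 0
  tw <- rep(prior$tau_w, length.out = q)
  td <- rep(prior$tau_d, length.out = q)
  tz <- rep(prior$tau_z, length.out = q)
  ti <- rep(prior$tau_i0, length.out = q)
  m0 <- rep(prior$i0_mean, length.out = q)

  if (!is.null(data$T) && !is.null(state$W))
    lp <- lp + sum(stats::dnorm(state$W, 1, sqrt(tw), log = TRUE))

  if (!is.null(data$A) && !is.null(state$D)) {
    if (prior$family == "spike_slab") {
      g <- state$gamma_ind %||% as.numeric(state$D != 0)
      th <- rep(prior$theta, length.out = q)
      for (j in seq_len(q)) {
        if (g[j] == 1) {
          lp <- lp + log(th[j]) +
            stats::dnorm(state$D[j], 0, sqrt(td[j]), log = TRUE)
        } else {
          if (state$D[j] != 0) return(-Inf)
          lp <- lp + log1p(-th[j])
        }
      }
    } else {
      lp <- lp + sum(stats::dnorm(state$D, 0, sqrt(td), log = TRUE))
    }
  }

  for (j in seq_len(q)) {
    on <- data$mask[j, ] != 0
    if (any(state$Z[j, !on] != 0)) return(-Inf)
    z <- state$Z[j, on]
    if (any(z < bounds$lower[j] | z > bounds$upper[j])) return(-Inf)
    lp <- lp + sum(dtnorm(z, 1, sqrt(tz[j]),
                          bounds$lower[j], bounds$upper[j], log = TRUE))
  }

  lp <- lp + sum(stats::dnorm(state$I0, m0, sqrt(ti), log = TRUE))

  mu <- latent_mean(state, data)
  lp <- lp + sum(stats::dnorm(state$I, mu, 1, log = TRUE))
  lp
}

# structural mean of the latent abundances: I0 + T W + A D^T (terms present
# as the corresponding observed layers are present)
latent_mean <- function(state, data) {
  mu <- matrix(rep(state$I0, each = data$n), data$n, data$q)
  if (!is.null(data$T) && !is.null(state$W))
    mu <- mu + sweep(data$T, 2, state$W, `*`)
  if (!is.null(data$A) && !is.null(state$D))
    mu <- mu + outer(data$A, state$D)
  mu
}
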