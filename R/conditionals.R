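#' Gibbs full conditionals
#'
#' Closed-form full conditional distributions for every parameter of the
#' two-layer model. Each function returns the parameters of the conditional
#' distribution given the current \code{state} and the observed
#' \code{data}; the sampler draws from them in a fixed sweep order. They
#' are exported so the conditional algebra can be inspected and checked
#' against independent numerical integration.
#'
#' All conditionals follow from conjugate Gaussian algebra with the latent
#' layer \eqn{I_{ij} \sim N(I^0_j + T_{ij}W_{jj} + A_iD_j, 1)} acting as the
#' "likelihood" for the first-layer parameters, and the peptide layer
#' \eqn{P_{ik} \sim N(\sum_j I_{ij}Z_{jk}, \sigma^2_k)} for the second.
#'
#' @param j isoform index; \code{k} peptide index; \code{i} sample index.
#' @param state model state list (\code{I0}, \code{W}, \code{D}, \code{Z},
#'   \code{I}, \code{sigma2}, optionally \code{gamma_ind}).
#' @param data an [iso_dataset()]; for [cond_z()] it must carry precomputed
#'   \code{$bounds} (as produced by the fitting pipeline) or bounds are
#'   derived on the fly.
#' @param prior an [iso_prior][prior_config()].
#' @return a list describing the conditional: \code{mean}/\code{var} for the
#'   Gaussian ones, plus \code{pip} for the spike-and-slab effect, bounds
#'   for the truncated [cond_z()], \code{shape}/\code{rate} for the
#'   inverse-gamma [cond_noise()], and \code{mean} (vector) /\code{cov}
#'   (matrix) for [cond_i_row()].
#' @name conditionals
NULL

#' @rdname conditionals
#' @export
cond_w <- function(j, state, data, prior) {
  tau <- prior_at(prior$tau_w, j)
  if (tau <= 0) stop("tau_w must be positive")
  Tj <- data$T[, j]
  R <- state$I[, j] - state$I0[j]
  if (!is.null(data$A) && !is.null(state$D)) R <- R - data$A * state$D[j]
  prec <- 1 / tau + sum(Tj^2)
  list(mean = (1 / tau + sum(Tj * R)) / prec, var = 1 / prec)
}

#' @rdname conditionals
#' @export
cond_d <- function(j, state, data, prior) {
  tau <- prior_at(prior$tau_d, j)
  if (tau <= 0) stop("tau_d must be positive")
  A <- data$A
  R <- state$I[, j] - state$I0[j]
  if (!is.null(data$T) && !is.null(state$W)) R <- R - data$T[, j] * state$W[j]
  prec <- 1 / tau + sum(A^2)
  m <- sum(A * R) / prec
  out <- list(mean = m, var = 1 / prec)
  if (prior$family == "spike_slab") {
    theta <- prior_at(prior$theta, j)
    # log Bayes factor of the slab against the point mass at zero
    logbf <- 0.5 * (log(1 / tau) - log(prec)) + 0.5 * m^2 * prec
    lodds <- log(theta) - log1p(-theta) + logbf
    out$pip <- if (theta >= 1) 1 else stats::plogis(lodds)
  }
  out
}

#' @rdname conditionals
#' @export
cond_i0 <- function(j, state, data, prior) {
  tau <- prior_at(prior$tau_i0, j)
  m0 <- prior_at(prior$i0_mean, j)
  R <- state$I[, j]
  if (!is.null(data$T) && !is.null(state$W)) R <- R - data$T[, j] * state$W[j]
  if (!is.null(data$A) && !is.null(state$D)) R <- R - data$A * state$D[j]
  prec <- 1 / tau + data$n
  list(mean = (m0 / tau + sum(R)) / prec, var = 1 / prec)
}

#' @rdname conditionals
#' @export
cond_z <- function(j, k, state, data, prior) {
  if (data$mask[j, k] == 0)
    stop("cond_z called off the mask support (j=", j, ", k=", k, ")")
  tau <- prior_at(prior$tau_z, j)
  b <- data$bounds %||% all_truncation_bounds(data$P, data$mask, "error")
  Ij <- state$I[, j]
  # partial residual excluding isoform j's contribution to peptide k
  ptilde <- data$P[, k] - state$I %*% state$Z[, k] + Ij * state$Z[j, k]
  s2 <- state$sigma2[k]
  prec <- 1 / tau + sum(Ij^2) / s2
  m <- (1 / tau + sum(Ij * ptilde) / s2) / prec
  list(mean = m, var = 1 / prec, lower = b$lower[j], upper = b$upper[j])
}

#' @rdname conditionals
#' @export
cond_noise <- function(k, state, data, prior) {
  e <- data$P[, k] - state$I %*% state$Z[, k]
  list(shape = prior$noise_a0 + data$n / 2,
       rate = prior$noise_b0 + sum(e^2) / 2)
}

#' @rdname conditionals
#' @export
cond_i_row <- function(i, state, data, prior) {
  ci <- cond_i_all(state, data)
  V <- chol2inv(ci$chol_prec)
  list(mean = ci$mean[i, ], cov = V)
}

# Vectorized conditional for all rows of I at once. The precision matrix
# Lambda = I_q + Z diag(1/sigma2) Z' is shared across samples; only the
# linear term differs by row:
#   Lambda m_i = mu_i + Z diag(1/sigma2) p_i
# Returns the n x q matrix of means and the upper Cholesky factor of Lambda.
cond_i_all <- function(state, data) {
  q <- data$q
  Zs <- sweep(state$Z, 2, state$sigma2, `/`)        # Z diag(1/sigma2), q x r
  Lambda <- diag(q) + Zs %*% t(state$Z)
  U <- chol(Lambda)
  mu <- latent_mean(state, data)
  rhs <- mu + data$P %*% t(Zs)                       # n x q
  M <- t(backsolve(U, forwardsolve(t(U), t(rhs))))   # solve Lambda M' = rhs'
  list(mean = M, chol_prec = U)
}
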