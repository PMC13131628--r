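# Independent numerical oracles used to check the closed-form algebra.
# They share no code with the package internals they validate.

# posterior moments by midpoint quadrature of prior(x) * likelihood(x)
grid_posterior <- function(logpost, lower, upper, step = 1e-3) {
  g <- seq(lower + step / 2, upper - step / 2, by = step)
  lp <- vapply(g, logpost, numeric(1))
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  m <- sum(g * w)
  list(mean = m, var = sum((g - m)^2 * w))
}

# brute-force union-find over the bipartite isoform-peptide graph
uf_blocks <- function(mask) {
  q <- nrow(mask); r <- ncol(mask)
  parent <- seq_len(q + r)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (j in seq_len(q)) for (k in seq_len(r)) {
    if (mask[j, k] != 0) {
      a <- find(j); b <- find(q + k)
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(q), find, integer(1))
  split(seq_len(q), roots)
}

# analytic moments of a truncated normal (textbook formulas), used to turn
# a (mean, var, bounds) conditional into comparable posterior moments
tnorm_moments <- function(mu, sd, l, u) {
  a <- (l - mu) / sd
  b <- (u - mu) / sd
  Zc <- pnorm(b) - pnorm(a)
  m <- mu + sd * (dnorm(a) - dnorm(b)) / Zc
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Zc -
                 ((dnorm(a) - dnorm(b)) / Zc)^2)
  list(mean = m, var = v)
}

# tiny single-isoform dataset with fixed truncation bounds attached, for
# exercising conditionals and sweeps directly
toy_data <- function(n = 2, r = 2, T = NULL, A = NULL, P = NULL,
                     bounds = list(lower = 0.5, upper = 2)) {
  P <- P %||% matrix(seq_len(n * r), n, r)
  d <- isofactor::iso_dataset(P, matrix(1, 1, r), T, A)
  d$bounds <- list(lower = rep(bounds$lower, 1), upper = rep(bounds$upper, 1))
  d
}

toy_state <- function(data, I0 = 0, W = NULL, D = NULL, Z = NULL, I = NULL,
                      sigma2 = NULL) {
  list(
    I0 = I0,
    W = W %||% (if (!is.null(data$T)) 1),
    D = D %||% (if (!is.null(data$A)) 0),
    Z = Z %||% matrix(1, 1, data$r),
    I = I %||% matrix(0, data$n, 1),
    sigma2 = sigma2 %||% rep(1, data$r)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Geweke-style successive-conditional simulator on a fixed-covariate toy:
# draw the full parameter state from its prior, then alternate one Gibbs
# sweep with regenerating the peptide data from the current state. The
# stationary distribution of the parameters is the prior. Covariates are
# kept small in magnitude: the W | I conditional has precision ~ sum(T^2),
# and large T creates a near-unit-root direction in the (W, I) chain whose
# autocorrelation would break the iid assumption of the KS check.
geweke_draws <- function(n_sweeps = 5000, thin = 10, seed = 20) {
  set.seed(seed)
  n <- 4L
  Tm <- matrix(rnorm(n, 0, 1), n, 1)
  A <- rep(c(1, 0), each = 2)
  d <- toy_data(n = n, r = 2, T = Tm, A = A)
  prior <- isofactor::prior_config()

  draw_prior_state <- function() {
    st <- list(
      I0 = rnorm(1, prior$i0_mean, sqrt(prior$tau_i0)),
      W = rnorm(1, 1, sqrt(prior$tau_w)),
      D = rnorm(1, 0, sqrt(prior$tau_d)),
      Z = matrix(isofactor:::rtnorm(2, 1, sqrt(prior$tau_z),
                                    d$bounds$lower, d$bounds$upper), 1, 2),
      sigma2 = 1 / rgamma(2, prior$noise_a0, rate = prior$noise_b0)
    )
    st$I <- isofactor:::latent_mean(st, d) + matrix(rnorm(n), n, 1)
    st
  }

  state <- draw_prior_state()
  keep <- seq(thin, n_sweeps, by = thin)
  W <- D <- numeric(length(keep))
  ptr <- 0L
  for (s in seq_len(n_sweeps)) {
    # regenerate data given the state, then one sweep of all conditionals
    d$P <- state$I %*% state$Z +
      matrix(rnorm(n * 2, sd = rep(sqrt(state$sigma2), each = n)), n, 2)
    state <- isofactor:::gibbs_sweep(state, d, prior)
    if (s %% thin == 0) {
      ptr <- ptr + 1L
      W[ptr] <- state$W
      D[ptr] <- state$D
    }
  }
  list(W = W, D = D, prior = prior)
}
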