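#' Chain configuration
#'
#' Defaults match the sampling protocol used throughout the package's
#' analyses: 3000 iterations per chain with the first 2000 discarded as
#' burn-in, so each chain summarizes its posterior with 1000 retained
#' draws, and 10 chains for consensus/stability analyses.
#'
#' @param n_iter total Gibbs iterations per chain.
#' @param burn_in iterations discarded before retention.
#' @param n_chains number of independent chains.
#' @param base_seed integer; chain c derives its stream from
#'   \code{base_seed + c}, and each block within a chain gets its own
#'   deterministic sub-stream, so results are invariant to block execution
#'   order.
#' @param thinning keep every \code{thinning}-th post-burn-in draw.
#' @return an object of class \code{chain_config}.
#' @export
chain_config <- function(n_iter = 3000, burn_in = 2000, n_chains = 10,
                         base_seed = 1, thinning = 1) {
  stopifnot(burn_in < n_iter, n_chains >= 1, thinning >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 n_chains = as.integer(n_chains),
                 base_seed = as.integer(base_seed),
                 thinning = as.integer(thinning)),
            class = "chain_config")
}

# deterministic 31-bit seed for (chain stream, block)
block_seed <- function(chain_seed, block_idx) {
  as.integer((as.double(chain_seed) * 48271 +
                as.double(block_idx) * 15485863) %% 2147483629)
}

# prior-mode initialization: a valid state for any dataset
init_state <- function(data, prior) {
  q <- data$q
  bounds <- data$bounds
  Z <- matrix(0, q, data$r)
  for (j in seq_len(q)) {
    on <- data$mask[j, ] != 0
    Z[j, on] <- (bounds$lower[j] + bounds$upper[j]) / 2
  }
  st <- list(
    I0 = rep(prior$i0_mean, length.out = q),
    W = if (!is.null(data$T)) rep(1, q) else NULL,
    D = if (!is.null(data$A)) rep(0, q) else NULL,
    Z = Z,
    sigma2 = rep(1, data$r),
    gamma_ind = if (prior$family == "spike_slab") rep(1, q) else NULL
  )
  st$I <- latent_mean(st, data)
  st
}

# one full Gibbs sweep over a (block-restricted) dataset, fixed scan order
# I0 -> W -> D -> Z -> sigma2 -> I
gibbs_sweep <- function(state, data, prior) {
  q <- data$q
  for (j in seq_len(q)) {
    fc <- cond_i0(j, state, data, prior)
    state$I0[j] <- stats::rnorm(1, fc$mean, sqrt(fc$var))
  }
  if (!is.null(data$T)) {
    for (j in seq_len(q)) {
      fc <- cond_w(j, state, data, prior)
      state$W[j] <- stats::rnorm(1, fc$mean, sqrt(fc$var))
    }
  }
  if (!is.null(data$A)) {
    for (j in seq_len(q)) {
      fc <- cond_d(j, state, data, prior)
      if (prior$family == "spike_slab") {
        inc <- stats::runif(1) < fc$pip
        state$gamma_ind[j] <- as.numeric(inc)
        state$D[j] <- if (inc) stats::rnorm(1, fc$mean, sqrt(fc$var)) else 0
      } else {
        state$D[j] <- stats::rnorm(1, fc$mean, sqrt(fc$var))
      }
    }
  }
  for (j in seq_len(q)) {
    for (k in which(data$mask[j, ] != 0)) {
      fc <- cond_z(j, k, state, data, prior)
      state$Z[j, k] <- rtnorm(1, fc$mean, sqrt(fc$var), fc$lower, fc$upper)
    }
  }
  for (k in seq_len(data$r)) {
    fc <- cond_noise(k, state, data, prior)
    state$sigma2[k] <- 1 / stats::rgamma(1, shape = fc$shape, rate = fc$rate)
  }
  ci <- cond_i_all(state, data)
  noise <- matrix(stats::rnorm(data$n * q), q, data$n)
  state$I <- ci$mean + t(backsolve(ci$chol_prec, noise))
  state
}

# run all iterations for one block with its own RNG stream; returns retained
# draws plus a running posterior mean of I
run_chain_block <- function(data, prior, cc, seed) {
  set.seed(seed)
  state <- init_state(data, prior)
  keep <- seq(cc$burn_in + 1L, cc$n_iter, by = cc$thinning)
  nkeep <- length(keep)
  q <- data$q
  Z_support <- which(data$mask != 0, arr.ind = TRUE)
  colnames(Z_support) <- c("isoform", "peptide")

  draws <- list(
    I0 = matrix(NA_real_, nkeep, q),
    W = if (!is.null(data$T)) matrix(NA_real_, nkeep, q),
    D = if (!is.null(data$A)) matrix(NA_real_, nkeep, q),
    Z = matrix(NA_real_, nkeep, nrow(Z_support)),
    sigma2 = matrix(NA_real_, nkeep, data$r),
    gamma_ind = if (prior$family == "spike_slab") matrix(NA_real_, nkeep, q)
  )
  I_sum <- matrix(0, data$n, q)
  ptr <- 0L
  for (it in seq_len(cc$n_iter)) {
    state <- gibbs_sweep(state, data, prior)
    check_finite_state(state, it)
    if (it > cc$burn_in && (it - cc$burn_in - 1L) %% cc$thinning == 0L) {
      ptr <- ptr + 1L
      draws$I0[ptr, ] <- state$I0
      if (!is.null(draws$W)) draws$W[ptr, ] <- state$W
      if (!is.null(draws$D)) draws$D[ptr, ] <- state$D
      draws$Z[ptr, ] <- state$Z[Z_support]
      draws$sigma2[ptr, ] <- state$sigma2
      if (!is.null(draws$gamma_ind)) draws$gamma_ind[ptr, ] <- state$gamma_ind
      I_sum <- I_sum + state$I
    }
  }
  draws$I_mean <- I_sum / nkeep
  draws$Z_support <- Z_support
  draws$n_draws <- nkeep
  draws
}

check_finite_state <- function(state, it) {
  for (nm in c("I0", "W", "D", "Z", "sigma2", "I")) {
    v <- state[[nm]]
    if (!is.null(v) && any(!is.finite(v)))
      stop("non-finite draw in parameter ", nm, " at iteration ", it)
  }
}

#' Run one Gibbs chain
#'
#' Decomposes the compatibility mask into independent blocks and samples
#' each block with its own deterministic random stream derived from the
#' chain seed. Because the posterior factorizes over blocks, per-block
#' sampling is exact -- \code{sweep_mode = "interleaved"} performs
#' whole-matrix sweeps (one pass over every block per iteration, swapping
#' RNG streams) and yields draw-for-draw identical results.
#'
#' @param data a validated [iso_dataset()].
#' @param prior an [iso_prior][prior_config()].
#' @param cc a [chain_config()].
#' @param chain_id integer chain index (determines the seed stream).
#' @param sweep_mode \code{"block"} (default) or \code{"interleaved"}.
#' @param nonpositive forwarded to [truncation_bounds()].
#' @return an object of class \code{iso_draws}: retained draws per
#'   parameter (\code{W}, \code{D}, \code{I0} as draws x q; \code{sigma2}
#'   draws x r; \code{Z} draws x support with \code{Z_support} indices;
#'   \code{gamma_ind} under the spike-and-slab family), the running
#'   posterior mean \code{I_mean} (n x q), the chain id and seed.
#' @export
run_chain <- function(data, prior, cc = chain_config(), chain_id = 1L,
                      sweep_mode = c("block", "interleaved"),
                      nonpositive = "error") {
  sweep_mode <- match.arg(sweep_mode)
  chain_seed <- cc$base_seed + as.integer(chain_id)
  blocks <- decompose_blocks(data$mask)
  if (any(vapply(blocks, function(b) length(b$isoforms) == 0, logical(1))))
    stop("mask contains peptides with no compatible isoform; run validate_dataset()")

  bdata <- lapply(blocks, function(b) subset_block(data, b, nonpositive))
  seeds <- vapply(seq_along(blocks), function(b) block_seed(chain_seed, b),
                  integer(1))

  bdraws <- if (sweep_mode == "block") {
    lapply(seq_along(blocks), function(b)
      run_chain_block(bdata[[b]], subset_prior(prior, blocks[[b]]$isoforms),
                      cc, seeds[[b]]))
  } else {
    run_interleaved(bdata, blocks, prior, cc, seeds)
  }

  assemble_draws(bdraws, blocks, data, prior, cc, chain_id, chain_seed)
}

# whole-matrix sweeps: every iteration visits each block once, restoring and
# saving that block's RNG state so draws match per-block execution exactly
run_interleaved <- function(bdata, blocks, prior, cc, seeds) {
  nb <- length(blocks)
  states <- vector("list", nb)
  rng <- vector("list", nb)
  priors <- lapply(blocks, function(b) subset_prior(prior, b$isoforms))
  for (b in seq_len(nb)) {
    set.seed(seeds[[b]])
    rng[[b]] <- .Random.seed
    states[[b]] <- init_state(bdata[[b]], priors[[b]])
  }
  keep <- seq(cc$burn_in + 1L, cc$n_iter, by = cc$thinning)
  store <- lapply(seq_len(nb), function(b) {
    d <- bdata[[b]]
    Z_support <- which(d$mask != 0, arr.ind = TRUE)
    colnames(Z_support) <- c("isoform", "peptide")
    list(I0 = matrix(NA_real_, length(keep), d$q),
         W = if (!is.null(d$T)) matrix(NA_real_, length(keep), d$q),
         D = if (!is.null(d$A)) matrix(NA_real_, length(keep), d$q),
         Z = matrix(NA_real_, length(keep), nrow(Z_support)),
         sigma2 = matrix(NA_real_, length(keep), d$r),
         gamma_ind = if (prior$family == "spike_slab")
           matrix(NA_real_, length(keep), d$q),
         Z_support = Z_support, I_sum = matrix(0, d$n, d$q), ptr = 0L)
  })
  for (it in seq_len(cc$n_iter)) {
    for (b in seq_len(nb)) {
      assign(".Random.seed", rng[[b]], envir = globalenv())
      states[[b]] <- gibbs_sweep(states[[b]], bdata[[b]], priors[[b]])
      rng[[b]] <- get(".Random.seed", envir = globalenv())
      check_finite_state(states[[b]], it)
      if (it > cc$burn_in && (it - cc$burn_in - 1L) %% cc$thinning == 0L) {
        s <- store[[b]]
        s$ptr <- s$ptr + 1L
        s$I0[s$ptr, ] <- states[[b]]$I0
        if (!is.null(s$W)) s$W[s$ptr, ] <- states[[b]]$W
        if (!is.null(s$D)) s$D[s$ptr, ] <- states[[b]]$D
        s$Z[s$ptr, ] <- states[[b]]$Z[s$Z_support]
        s$sigma2[s$ptr, ] <- states[[b]]$sigma2
        if (!is.null(s$gamma_ind)) s$gamma_ind[s$ptr, ] <- states[[b]]$gamma_ind
        s$I_sum <- s$I_sum + states[[b]]$I
        store[[b]] <- s
      }
    }
  }
  lapply(store, function(s) {
    s$I_mean <- s$I_sum / length(keep)
    s$n_draws <- length(keep)
    s[setdiff(names(s), c("I_sum", "ptr"))]
  })
}

# stitch per-block draws back into whole-problem arrays
assemble_draws <- function(bdraws, blocks, data, prior, cc, chain_id, seed) {
  nkeep <- bdraws[[1]]$n_draws
  q <- data$q
  r <- data$r
  out <- list(
    I0 = matrix(NA_real_, nkeep, q, dimnames = list(NULL, data$isoform_ids)),
    W = if (!is.null(data$T))
      matrix(NA_real_, nkeep, q, dimnames = list(NULL, data$isoform_ids)),
    D = if (!is.null(data$A))
      matrix(NA_real_, nkeep, q, dimnames = list(NULL, data$isoform_ids)),
    sigma2 = matrix(NA_real_, nkeep, r,
                    dimnames = list(NULL, data$peptide_ids)),
    gamma_ind = if (prior$family == "spike_slab")
      matrix(NA_real_, nkeep, q, dimnames = list(NULL, data$isoform_ids)),
    I_mean = matrix(NA_real_, data$n, q,
                    dimnames = list(data$sample_ids, data$isoform_ids))
  )
  zs <- list()
  zv <- list()
  for (b in seq_along(blocks)) {
    js <- blocks[[b]]$isoforms
    ks <- blocks[[b]]$peptides
    d <- bdraws[[b]]
    out$I0[, js] <- d$I0
    if (!is.null(out$W)) out$W[, js] <- d$W
    if (!is.null(out$D)) out$D[, js] <- d$D
    out$sigma2[, ks] <- d$sigma2
    if (!is.null(out$gamma_ind)) out$gamma_ind[, js] <- d$gamma_ind
    out$I_mean[, js] <- d$I_mean
    sup <- d$Z_support
    zs[[b]] <- cbind(isoform = js[sup[, "isoform"]],
                     peptide = ks[sup[, "peptide"]])
    zv[[b]] <- d$Z
  }
  out$Z_support <- do.call(rbind, zs)
  out$Z <- do.call(cbind, zv)
  ord <- order(out$Z_support[, "isoform"], out$Z_support[, "peptide"])
  out$Z_support <- out$Z_support[ord, , drop = FALSE]
  out$Z <- out$Z[, ord, drop = FALSE]
  out$n_draws <- nkeep
  out$chain_id <- chain_id
  out$seed <- seed
  structure(out, class = "iso_draws")
}

#' @export
print.iso_draws <- function(x, ...) {
  cat("iso_draws: chain", x$chain_id, "with", x$n_draws, "retained draws\n")
  cat("  parameters:",
      paste(intersect(c("I0", "W", "D", "Z", "sigma2", "gamma_ind"),
                      names(Filter(Negate(is.null), x))), collapse = ", "),
      "\n")
  invisible(x)
}

#' Run multiple independent chains
#'
#' @inheritParams run_chain
#' @return list of [run_chain()] results, one per chain; chain c uses seed
#'   stream \code{base_seed + c}.
#' @export
run_chains <- function(data, prior, cc = chain_config(),
                       sweep_mode = "block", nonpositive = "error") {
  lapply(seq_len(cc$n_chains), function(c_id) {
    tryCatch(
      run_chain(data, prior, cc, chain_id = c_id, sweep_mode = sweep_mode,
                nonpositive = nonpositive),
      error = function(e) stop("chain ", c_id, ": ", conditionMessage(e),
                               call. = FALSE)
    )
  })
}

#' Posterior mean of the detectability matrix from one chain
#' @param draws an \code{iso_draws} object.
#' @param q,r dimensions of the full detectability matrix.
#' @return q x r matrix of posterior means (exact zeros off support).
#' @export
zbar_matrix <- function(draws, q, r) {
  Z <- matrix(0, q, r)
  Z[draws$Z_support] <- colMeans(draws$Z)
  Z
}
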