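test_that("pair correlations hit the algebraic fixed points and flag tails", {
  set.seed(2)
  x <- matrix(rnorm(60), 20, 3)
  I_hat <- cbind(x[, 1], -x[, 2], x[, 3] * 0.01 + rnorm(20, sd = 1))
  colnames(I_hat) <- colnames(x) <- c("a", "b", "c")
  tab <- pair_correlations(I_hat, x)
  expect_equal(tab$r[1], 1)
  expect_equal(tab$r[2], -1)
  expect_equal(tab$tail[1:2], c("strong_positive", "strong_negative"))
  # zero-variance pair dropped with a warning
  I_hat2 <- I_hat
  I_hat2[, 3] <- 5
  expect_warning(tab2 <- pair_correlations(I_hat2, x), "zero-variance")
  expect_equal(nrow(tab2), 2)
})

test_that("tail flags use strict bounds at |r| = 0.3", {
  n <- 10
  base <- scale(rnorm(n))[, 1]
  make_r <- function(target) {
    y <- target * base + sqrt(1 - target^2) * scale(resid(lm(rnorm(n) ~ base)))[, 1]
    cbind(y)
  }
  for (target in c(0.2999, 0.32)) {
    tab <- pair_correlations(make_r(target), cbind(base))
    expect_equal(tab$tail,
                 if (target > 0.3) "strong_positive" else "neutral",
                 info = paste("r =", target))
  }
})

test_that("mapping classification follows shared-peptide structure", {
  expect_true(all(classify_mapping(diag(4)) == "unique"))
  # one shared peptide makes both isoforms ambiguous
  mask <- rbind(a = c(1, 1, 0), b = c(0, 1, 1))
  expect_equal(unname(classify_mapping(mask)), c("ambiguous", "ambiguous"))
  # partition property and brute-force column-sum oracle on random masks
  set.seed(6)
  for (rep in 1:20) {
    m <- matrix(rbinom(6 * 9, 1, 0.25), 6, 9)
    m[rowSums(m) == 0, 1] <- 1
    cls <- classify_mapping(m)
    expect_length(cls, 6)
    oracle <- vapply(1:6, function(j)
      any(m[j, ] == 1 & colSums(m) >= 2), logical(1))
    expect_equal(unname(cls == "ambiguous"), oracle)
  }
})

test_that("analytic null tail matches simulation and is monotone", {
  # Monte-Carlo check at n = 103, threshold 0.30
  set.seed(12)
  nrep <- 40000
  rs <- vapply(seq_len(nrep), function(i) cor(rnorm(103), rnorm(103)),
               numeric(1))
  mc <- mean(abs(rs) > 0.30)
  an <- null_tail_fraction(103, 0.30)
  se <- sqrt(an * (1 - an) / nrep)
  expect_lt(abs(mc - an), 4 * se + 1e-12)

  # strictly decreasing in n and in the threshold
  ns <- c(10, 30, 103, 300)
  expect_true(all(diff(vapply(ns, null_tail_fraction,
                              numeric(1), threshold = 0.3)) < 0))
  ths <- c(0.1, 0.2, 0.3, 0.5)
  expect_true(all(diff(vapply(ths, function(t)
    null_tail_fraction(103, t), numeric(1))) < 0))
  # threshold -> 0 gives probability -> 1
  expect_equal(null_tail_fraction(103, 1e-8), 1, tolerance = 1e-4)
})

test_that("expected tail counts scale linearly in the number of pairs", {
  expect_equal(expected_tail_count(0, 103, 0.3), 0)
  e1 <- expected_tail_count(7107, 103, 0.3)
  expect_equal(expected_tail_count(2 * 7107, 103, 0.3), 2 * e1)
  expect_equal(e1, 7107 * null_tail_fraction(103, 0.3) / 2)
})

test_that("eGene variance explained is 2f(1-f)b^2", {
  expect_equal(egene_variance_explained(0.5, 1), 0.5)
  expect_equal(egene_variance_explained(0, 3), 0)
  expect_equal(egene_variance_explained(0.2, 2), 1.28)
  expect_equal(egene_variance_explained(c(0.5, 0.2), c(1, 2)), c(0.5, 1.28))
  expect_error(egene_variance_explained(1.2, 1), "allele frequency")
})

test_that("correlation regression recovers exact fits and rejects collinearity", {
  set.seed(15)
  X <- as.data.frame(matrix(rnorm(40 * 5), 40, 5))
  names(X) <- c("dx_iso", "dx_tx", "age_iso", "age_tx", "egene")
  # exact linear combination -> R^2 = 1
  y <- 0.2 + 1 * X$dx_iso - 2 * X$age_tx
  # lm warns about the (intentionally) perfect fit
  expect_equal(suppressWarnings(fit_correlation_model(y, X)$r_squared), 1)
  # independent outcome -> R^2 near 0
  y2 <- rnorm(40)
  expect_lt(fit_correlation_model(y2, X)$r_squared, 0.3)
  # collinear predictors named in the error
  Xc <- X
  Xc$egene <- Xc$dx_iso * 2
  expect_error(fit_correlation_model(y, Xc), "collinear")
  expect_error(fit_correlation_model(y[1:4], X[1:4, ]), "at least 6")
})

test_that("two-predictor fit matches hand-solved normal equations", {
  x1 <- c(1, 2, 3, 4, 5, 6)
  x2 <- c(1, 0, 1, 0, 1, 0)
  y <- c(2.1, 3.9, 6.2, 7.8, 10.1, 12.2)
  got <- fit_correlation_model(y, data.frame(x1 = x1, x2 = x2))
  X <- cbind(1, x1, x2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(got$coefficients[, "Estimate"]), c(beta),
               tolerance = 1e-10)
})

test_that("control-pair sampling is seeded and respects the bound", {
  set.seed(3)
  r <- runif(300, -1, 1)
  idx <- sample_control_pairs(r, size = 10, bound = 0.05, seed = 7)
  expect_length(idx, 10)
  expect_true(all(abs(r[idx]) < 0.05))
  expect_identical(idx, sample_control_pairs(r, 10, 0.05, seed = 7))
  expect_error(sample_control_pairs(r, 1000, 0.05, seed = 7), "available")
})

test_that("null transcript-isoform pairs rarely show strong correlations end-to-end", {
  # W = 0 variant with transcripts withheld at fit time: the estimates are
  # then statistically independent of the transcripts, so fitted-vs-
  # transcript correlations follow the analytic null at n = 103. (Fitting
  # WITH transcript supervision leaks prior structure into weakly
  # identified isoforms and inflates the tail; see the methods vignette.)
  hits <- 0L
  pairs <- 0L
  for (s in 1:5) {
    sim <- suppressMessages(simulate_difficult(n = 103, seed = s,
                                               w_zero = TRUE))
    blind <- sim$data
    blind$T <- NULL
    fit <- isofactor(blind, chains = 1, iter = 1000, burnin = 500, seed = s)
    tab <- pair_correlations(fitted(fit), sim$data$T, mask = sim$data$mask)
    hits <- hits + sum(tab$tail == "strong_positive")
    pairs <- pairs + nrow(tab)
  }
  p0 <- null_tail_fraction(103, 0.3) / 2
  # within 3 Monte-Carlo SDs of the analytic null (counts are tiny)
  expect_lte(hits, pairs * p0 + 3 * sqrt(pairs * p0 * (1 - p0)) + 1)
})
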