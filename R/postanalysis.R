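#' Transcript-isoform pair correlations
#'
#' Pearson correlation, over samples, between each transcript column and
#' the matched (posterior-mean) isoform abundance column, with tail flags
#' at the conventional |r| > 0.3 bound: \code{strong_positive} for
#' r > 0.3, \code{strong_negative} for r < -0.3, \code{neutral} otherwise
#' (strict inequalities).
#'
#' @param I_hat n x q matrix of estimated isoform abundances.
#' @param transcripts n x q transcript matrix, columns matched to
#'   \code{I_hat}.
#' @param mask optional q x r compatibility mask; when given, a
#'   \code{mapping} column ([classify_mapping()]) is added.
#' @return data.frame with columns \code{isoform_id}, \code{r},
#'   \code{tail}, and optionally \code{mapping}. Zero-variance pairs are
#'   dropped with a warning.
#' @export
pair_correlations <- function(I_hat, transcripts, mask = NULL) {
  I_hat <- as.matrix(I_hat)
  transcripts <- as.matrix(transcripts)
  stopifnot(ncol(I_hat) == ncol(transcripts), nrow(I_hat) >= 3)
  ids <- colnames(I_hat) %||% paste0("iso", seq_len(ncol(I_hat)))
  sds_i <- apply(I_hat, 2, stats::sd)
  sds_t <- apply(transcripts, 2, stats::sd)
  ok <- sds_i > 0 & sds_t > 0
  if (any(!ok))
    warning("dropping ", sum(!ok), " zero-variance pair(s): ",
            paste(ids[!ok], collapse = ", "))
  r <- vapply(which(ok), function(j)
    stats::cor(transcripts[, j], I_hat[, j]), numeric(1))
  out <- data.frame(
    isoform_id = ids[ok],
    r = r,
    tail = ifelse(r > 0.3, "strong_positive",
                  ifelse(r < -0.3, "strong_negative", "neutral")),
    stringsAsFactors = FALSE
  )
  if (!is.null(mask)) {
    mp <- classify_mapping(mask)
    out$mapping <- mp[match(out$isoform_id,
                            names(mp) %||% as.character(seq_along(mp)))]
  }
  out
}

#' Classify isoforms by peptide-mapping ambiguity
#'
#' An isoform is \code{unique} when every peptide compatible with it is
#' compatible with it alone, and \code{ambiguous} when any of its peptides
#' could trace to two or more isoforms.
#'
#' @param mask q x r compatibility matrix.
#' @return named character vector (\code{"unique"}/\code{"ambiguous"}) of
#'   length q.
#' @export
classify_mapping <- function(mask) {
  mask <- as.matrix(mask) != 0
  shared <- colSums(mask) >= 2
  cls <- ifelse(apply(mask, 1, function(row) any(row & shared)),
                "ambiguous", "unique")
  stats::setNames(cls, rownames(mask) %||% paste0("iso", seq_len(nrow(mask))))
}

#' Null tail probability of a sample correlation
#'
#' Exact two-sided probability that an empirical Pearson correlation of n
#' independent sample pairs exceeds \code{threshold} in absolute value when
#' the true correlation is zero, via the t-transform of the null
#' correlation density: \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} has a
#' t-distribution with n-2 degrees of freedom.
#'
#' At n = 103 samples and threshold 0.30 this gives about 0.002 (0.2%): the
#' yardstick for judging whether observed transcript-isoform correlation
#' tails are compatible with no true correlation.
#'
#' @param n number of samples behind each correlation (>= 4).
#' @param threshold correlation bound in (0, 1).
#' @return P(|r| > threshold) under the null.
#' @export
null_tail_fraction <- function(n, threshold) {
  stopifnot(n >= 4, threshold > 0, threshold < 1)
  tstat <- threshold * sqrt(n - 2) / sqrt(1 - threshold^2)
  2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
}

#' Expected null count per correlation tail
#'
#' Among \code{n_pairs} independent transcript-isoform pairs with zero true
#' correlation, the expected number of pairs exceeding the bound in one
#' given tail.
#'
#' @param n_pairs number of pairs.
#' @inheritParams null_tail_fraction
#' @return expected count per tail (\code{n_pairs} times half the
#'   two-sided tail probability).
#' @export
expected_tail_count <- function(n_pairs, n, threshold) {
  stopifnot(n_pairs >= 0)
  n_pairs * null_tail_fraction(n, threshold) / 2
}

#' Variance in expression explained by an eGene variant
#'
#' For a biallelic variant with allele frequency f and regression slope b
#' on expression, the explained variance is \eqn{2f(1-f)b^2} (the variance
#' of a binomial genotype dosage times the squared slope).
#'
#' @param f allele frequency in [0, 1] (vectorized).
#' @param b slope estimate (vectorized).
#' @return explained variance, recycled to the common length.
#' @export
egene_variance_explained <- function(f, b) {
  if (any(f < 0 | f > 1)) stop("allele frequency must lie in [0, 1]")
  2 * f * (1 - f) * b^2
}

#' Regress pair correlations on biological-variation predictors
#'
#' Ordinary least squares of observed transcript-isoform correlations on
#' five predictors of biological variation (mean case-control difference
#' for isoform and for transcript abundances, the age coefficient for
#' each, and eGene variance explained). Reports the coefficient table with
#' t-statistics and the model R^2.
#'
#' @param r numeric outcome vector of pair correlations.
#' @param predictors data.frame (or matrix) of predictor columns; rows with
#'   missing values in outcome or predictors are dropped, and at least 6
#'   complete rows are required.
#' @return list with \code{coefficients} (estimate, std error, t, p),
#'   \code{r_squared}, \code{n}, and the underlying \code{lm} fit.
#' @export
fit_correlation_model <- function(r, predictors) {
  predictors <- as.data.frame(predictors)
  stopifnot(length(r) == nrow(predictors))
  keep <- stats::complete.cases(r, predictors)
  r <- r[keep]
  predictors <- predictors[keep, , drop = FALSE]
  if (length(r) < 6)
    stop("need at least 6 complete rows; got ", length(r))

  X <- stats::model.matrix(~ ., data = predictors)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear predictors; aliased set: ",
         paste(aliased, collapse = ", "))
  }
  fit <- stats::lm(r ~ ., data = data.frame(r = r, predictors))
  sm <- summary(fit)
  list(coefficients = stats::coef(sm), r_squared = sm$r.squared,
       n = length(r), fit = fit)
}

#' Sample a low-correlation control set of pairs
#'
#' Draws, without replacement and with a fixed seed, a control set of pairs
#' whose correlation magnitude is below \code{bound}, for contrasting
#' against a strong-correlation set in [fit_correlation_model()].
#'
#' @param r numeric vector of pair correlations.
#' @param size number of controls to draw.
#' @param bound magnitude bound, default 0.05.
#' @param seed integer seed.
#' @return integer indices into \code{r}.
#' @export
sample_control_pairs <- function(r, size, bound = 0.05, seed = 1) {
  pool <- which(abs(r) < bound)
  if (length(pool) < size)
    stop("only ", length(pool), " pairs with |r| < ", bound,
         " available; asked for ", size)
  set.seed(as.integer(seed))
  sort(sample(pool, size))
}
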