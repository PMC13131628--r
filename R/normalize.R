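#' Normalize raw peptide abundances
#'
#' Standard preprocessing for labeled (e.g. TMT) peptide quantification
#' prior to modelling:
#' \enumerate{
#'   \item scale each sample's raw intensities so its total equals the
#'     median per-sample total (removes loading differences);
#'   \item log2-transform;
#'   \item fit, per peptide, an ordinary-least-squares model on the labeling
#'     batch ("plex") plus the biological covariates diagnosis, age and
#'     postmortem interval;
#'   \item subtract only the fitted plex effects, so technical batch
#'     variation is removed while diagnosis/age/PMI variation (and all
#'     residual biological variation) is retained.
#' }
#' Fitting the biological covariates alongside plex keeps the batch
#' estimates from absorbing biology confounded with batch; only the plex
#' component is subtracted.
#'
#' @param raw n x r matrix of strictly positive raw peptide intensities.
#' @param covariates data.frame with one row per sample, containing at
#'   least \code{plex} (factor-like); \code{diagnosis}, \code{age},
#'   \code{pmi} are included in the OLS fit when present. Extra columns are
#'   ignored.
#' @return n x r matrix of plex-adjusted log2 abundances.
#' @export
normalize_peptides <- function(raw, covariates) {
  raw <- as.matrix(raw)
  if (any(raw <= 0))
    stop("raw peptide intensities must be strictly positive before log2")
  if (!"plex" %in% names(covariates))
    stop("covariates must contain a `plex` column")

  totals <- rowSums(raw)
  scaled <- raw * (stats::median(totals) / totals)
  logp <- log2(scaled)

  plex <- factor(covariates$plex)
  if (nlevels(plex) < 2) return(logp)  # single batch: nothing to subtract

  vars <- intersect(c("diagnosis", "age", "pmi"), names(covariates))
  df <- data.frame(plex = plex, covariates[, vars, drop = FALSE])
  X <- stats::model.matrix(
    stats::reformulate(c("plex", vars)), data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qrX, logp)                       # p x r coefficients
  plex_cols <- grep("^plex", colnames(X))
  adj <- logp - X[, plex_cols, drop = FALSE] %*%
    beta[plex_cols, , drop = FALSE]
  dimnames(adj) <- dimnames(raw)
  adj
}

#' Normalize transcript counts to log2 CPM
#'
#' Converts nonnegative counts to counts-per-million, log2-transforms with
#' a pseudocount, and optionally removes technical covariate effects by
#' OLS (all supplied covariate effects are subtracted, keeping intercept
#' plus residual).
#'
#' @param counts n x q matrix of nonnegative counts (samples in rows).
#' @param covariates optional data.frame of technical covariates to regress
#'   out.
#' @param pseudocount added before log2; default 1.
#' @return n x q matrix of log2 CPM values.
#' @export
normalize_transcripts <- function(counts, covariates = NULL,
                                  pseudocount = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  lib <- rowSums(counts)
  if (any(lib == 0)) stop("zero library size in sample(s) ",
                          paste(which(lib == 0), collapse = ", "))
  cpm <- counts * (1e6 / lib)
  lc <- log2(cpm + pseudocount)
  if (is.null(covariates)) return(lc)

  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qrX, lc)
  tech_cols <- setdiff(seq_len(ncol(X)), 1L)  # keep the intercept
  adj <- lc - X[, tech_cols, drop = FALSE] %*% beta[tech_cols, , drop = FALSE]
  dimnames(adj) <- dimnames(counts)
  adj
}
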