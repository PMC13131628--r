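#' Read and write the package's TSV matrix format
#'
#' Matrices travel as TSV with a header row of feature ids and a first
#' column of sample ids (for the mask: isoform ids in the first column,
#' peptide ids in the header).
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  as.matrix(df)
}

#' @rdname read_matrix_tsv
#' @param x matrix to write.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(id = rownames(x) %||% seq_len(nrow(x)),
                   as.data.frame(x, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the differential-abundance results table
#'
#' @param fit an \code{isofactor} fit (or a [differential_results()]
#'   data.frame).
#' @param path output TSV path.
#' @export
write_differential_tsv <- function(fit, path) {
  tab <- if (inherits(fit, "isofactor")) fit$differential else fit
  if (is.null(tab)) stop("fit has no differential results")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reproducibility manifest for a fit
#'
#' Records everything needed to reproduce a run bit-identically: the
#' sampler configuration (seeds included), prior settings, data dimensions
#' and input checksums.
#'
#' @param fit an \code{isofactor} fit.
#' @param inputs optional named character vector of input file paths to
#'   checksum (md5 via [tools::md5sum()]).
#' @param path optional JSON output path; when NULL the manifest list is
#'   returned invisibly without writing.
#' @return the manifest list, invisibly.
#' @export
run_manifest <- function(fit, inputs = NULL, path = NULL) {
  stopifnot(inherits(fit, "isofactor"))
  man <- list(
    package = "isofactor",
    version = as.character(utils::packageVersion("isofactor")),
    config = unclass(fit$config),
    prior = unclass(fit$prior),
    dims = list(n = fit$data$n, q = fit$data$q, r = fit$data$r,
                blocks = length(fit$blocks)),
    chain_seeds = vapply(fit$chains, `[[`, integer(1), "seed")
  )
  if (!is.null(inputs))
    man$input_md5 <- as.list(tools::md5sum(inputs))
  if (!is.null(path))
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(man)
}
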