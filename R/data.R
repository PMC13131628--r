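#' Assemble an observed multi-omic dataset
#'
#' Bundles the observed layer of the two-layer isoform model: a peptide
#' abundance matrix, the peptide-isoform compatibility mask, and (optionally)
#' transcript expression for the same samples plus a binary condition label.
#' All abundance matrices are expected on a log scale with samples in rows.
#'
#' The model can run from peptides and a mask alone; transcripts supervise
#' the latent isoform abundances when available, and the condition vector
#' enables differential-abundance inference.
#'
#' @param peptides numeric matrix, n samples x r peptides.
#' @param mask binary matrix, q isoforms x r peptides; \code{mask[j, k] == 1}
#'   means peptide k can derive from isoform j.
#' @param transcripts optional numeric matrix, n x q, column j being the
#'   transcript matched to isoform j.
#' @param condition optional length-n vector of 0/1 condition labels.
#' @param sample_ids,isoform_ids,peptide_ids optional identifier vectors;
#'   defaults come from dimnames or are generated.
#' @return an object of class \code{iso_dataset}: a list with elements
#'   \code{P}, \code{mask}, \code{T} (or \code{NULL}), \code{A} (or
#'   \code{NULL}), the id vectors and the dimensions \code{n}, \code{q},
#'   \code{r}.
#' @seealso [validate_dataset()] for structural checks, [isofactor()] to fit.
#' @export
iso_dataset <- function(peptides, mask, transcripts = NULL, condition = NULL,
                        sample_ids = NULL, isoform_ids = NULL,
                        peptide_ids = NULL) {
  P <- as.matrix(peptides)
  mask <- as.matrix(mask)
  storage.mode(mask) <- "double"
  n <- nrow(P)
  r <- ncol(P)
  q <- nrow(mask)

  sample_ids <- sample_ids %||% rownames(P) %||% paste0("s", seq_len(n))
  peptide_ids <- peptide_ids %||% colnames(P) %||% colnames(mask) %||%
    paste0("pep", seq_len(r))
  isoform_ids <- isoform_ids %||% rownames(mask) %||% paste0("iso", seq_len(q))

  Tm <- if (!is.null(transcripts)) as.matrix(transcripts) else NULL
  A <- if (!is.null(condition)) as.numeric(condition) else NULL

  dimnames(P) <- list(sample_ids, peptide_ids)
  dimnames(mask) <- list(isoform_ids, peptide_ids)
  if (!is.null(Tm)) dimnames(Tm) <- list(sample_ids, isoform_ids)

  structure(
    list(P = P, mask = mask, T = Tm, A = A,
         sample_ids = sample_ids, isoform_ids = isoform_ids,
         peptide_ids = peptide_ids, n = n, q = q, r = r),
    class = "iso_dataset"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.iso_dataset <- function(x, ...) {
  cat("iso_dataset:", x$n, "samples,", x$q, "isoforms,", x$r, "peptides\n")
  cat("  transcripts:", if (is.null(x$T)) "absent" else "present", "\n")
  cat("  condition:  ",
      if (is.null(x$A)) "absent"
      else paste0(sum(x$A == 1), " / ", x$n, " in condition 1"), "\n")
  cat("  mask support:", sum(x$mask != 0), "of", x$q * x$r, "entries\n")
  invisible(x)
}

#' Structural validation of an observed dataset
#'
#' Checks the invariants the sampler relies on: matching sample counts,
#' binary condition labels, no isoform without a compatible peptide, no
#' peptide without a compatible isoform, and -- per connected block of the
#' compatibility graph -- no more isoforms than peptides (the model is only
#' estimable when each block has q_b <= r_b).
#'
#' Validation never throws: it returns a report that callers inspect and act
#' on. [isofactor()] aborts when the report is non-empty.
#'
#' @param data an [iso_dataset()].
#' @return a data.frame with columns \code{check}, \code{detail}; zero rows
#'   when the dataset is structurally sound.
#' @export
validate_dataset <- function(data) {
  stopifnot(inherits(data, "iso_dataset"))
  bad <- list()
  note <- function(check, detail) {
    bad[[length(bad) + 1L]] <<- data.frame(check = check, detail = detail,
                                           stringsAsFactors = FALSE)
  }

  if (!is.null(data$T)) {
    if (nrow(data$T) != data$n)
      note("dim", sprintf("transcripts have %d rows, peptides %d",
                          nrow(data$T), data$n))
    if (ncol(data$T) != data$q)
      note("dim", sprintf("transcripts have %d columns, mask %d isoforms",
                          ncol(data$T), data$q))
  }
  if (!is.null(data$A)) {
    if (length(data$A) != data$n)
      note("dim", sprintf("condition has length %d, expected %d",
                          length(data$A), data$n))
    if (!all(data$A %in% c(0, 1)))
      note("condition", "condition labels must be 0/1")
  }
  if (ncol(data$mask) != data$r)
    note("dim", sprintf("mask has %d columns, peptides %d",
                        ncol(data$mask), data$r))
  if (!all(data$mask %in% c(0, 1)))
    note("mask", "mask entries must be 0/1")

  empty_iso <- which(rowSums(data$mask != 0) == 0)
  for (j in empty_iso)
    note("mask", sprintf("isoform with no peptide: %s", data$isoform_ids[j]))
  empty_pep <- which(colSums(data$mask != 0) == 0)
  for (k in empty_pep)
    note("mask", sprintf("peptide with no isoform: %s", data$peptide_ids[k]))

  # per-block estimability: more isoforms than peptides cannot be resolved
  if (length(empty_iso) == 0 && length(empty_pep) == 0) {
    blocks <- decompose_blocks(data$mask)
    for (b in blocks) {
      if (length(b$isoforms) > length(b$peptides))
        note("block", sprintf(
          "q>r in block: %d isoforms (%s%s) vs %d peptides",
          length(b$isoforms),
          paste(utils::head(data$isoform_ids[b$isoforms], 3), collapse = ","),
          if (length(b$isoforms) > 3) ",..." else "",
          length(b$peptides)))
    }
  }

  if (length(bad) == 0)
    data.frame(check = character(), detail = character(),
               stringsAsFactors = FALSE)
  else
    do.call(rbind, bad)
}
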