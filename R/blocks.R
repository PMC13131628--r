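#' Merge isoforms with identical peptide support into groups
#'
#' Isoforms whose mask rows are bit-identical are observationally
#' indistinguishable at the peptide level: only their joint abundance is
#' estimable. They are rolled up into a single isoform group whose id is the
#' sorted member ids joined with \code{"+"}; isoforms with a unique support
#' pattern pass through unchanged.
#'
#' @param mask q x r binary compatibility matrix with isoform row names.
#' @return list with \code{mask} (the deduplicated mask, one row per group,
#'   rows ordered by first member occurrence), \code{groups} (data.frame
#'   \code{group_id}, \code{member_id}) and \code{map} (named vector,
#'   member id -> group id).
#' @export
group_isoforms <- function(mask) {
  mask <- as.matrix(mask)
  ids <- rownames(mask) %||% paste0("iso", seq_len(nrow(mask)))
  key <- apply(mask != 0, 1, paste, collapse = "")
  first <- !duplicated(key)
  group_of_key <- vapply(split(ids, key), function(members)
    paste(sort(members), collapse = "+"), character(1))
  map <- stats::setNames(group_of_key[key], ids)

  gmask <- mask[first, , drop = FALSE]
  rownames(gmask) <- unname(map[ids[first]])
  groups <- data.frame(group_id = unname(map), member_id = ids,
                       stringsAsFactors = FALSE)
  list(mask = gmask, groups = groups, map = map)
}

#' Decompose the compatibility mask into independent blocks
#'
#' The isoform-peptide compatibility structure is a bipartite graph; its
#' connected components partition both isoforms and peptides into blocks
#' that share no peptide across block boundaries. Because the detectability
#' matrix is block-diagonal under this partition, the posterior factorizes
#' over blocks and the sampler runs each block independently.
#'
#' @param mask q x r binary matrix.
#' @return list of blocks, each a list with integer vectors \code{isoforms}
#'   and \code{peptides} (indices into mask rows/columns); blocks are
#'   ordered by their smallest isoform index. Peptides compatible with no
#'   isoform form peptide-only blocks appended at the end.
#' @export
decompose_blocks <- function(mask) {
  mask <- as.matrix(mask)
  q <- nrow(mask)
  r <- ncol(mask)
  g <- igraph::graph_from_biadjacency_matrix(mask != 0)
  comp <- igraph::components(g)$membership
  iso_comp <- comp[seq_len(q)]
  pep_comp <- comp[q + seq_len(r)]

  out <- list()
  for (cid in unique(iso_comp[order(seq_len(q))])) {
    out[[length(out) + 1L]] <- list(
      isoforms = which(iso_comp == cid),
      peptides = which(pep_comp == cid)
    )
  }
  # deterministic ordering by smallest isoform index
  out <- out[order(vapply(out, function(b) min(b$isoforms), integer(1)))]
  # orphan peptides (no compatible isoform) -- structurally invalid, but
  # surfaced rather than silently dropped
  orphan <- setdiff(seq_len(r), unlist(lapply(out, `[[`, "peptides")))
  for (k in orphan)
    out[[length(out) + 1L]] <- list(isoforms = integer(0), peptides = k)
  out
}

# restrict a dataset to one block; bounds are computed on the restricted
# matrices (identical to full-data bounds since compatibility never crosses
# block boundaries)
subset_block <- function(data, block, nonpositive = "error") {
  js <- block$isoforms
  ks <- block$peptides
  d <- iso_dataset(
    peptides = data$P[, ks, drop = FALSE],
    mask = data$mask[js, ks, drop = FALSE],
    transcripts = if (!is.null(data$T)) data$T[, js, drop = FALSE],
    condition = data$A,
    sample_ids = data$sample_ids,
    isoform_ids = data$isoform_ids[js],
    peptide_ids = data$peptide_ids[ks]
  )
  d$bounds <- all_truncation_bounds(d$P, d$mask, nonpositive)
  d
}

# restrict scalar-or-vector prior parameters to a block's isoforms
subset_prior <- function(prior, js) {
  p <- prior
  for (nm in c("tau_w", "tau_d", "tau_z", "tau_i0", "theta", "i0_mean"))
    if (length(p[[nm]]) > 1L) p[[nm]] <- p[[nm]][js]
  p
}
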