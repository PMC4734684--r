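# Relevance sampling: a candidate training motif is "relevant" to a query
# when at least one of the three aligned variable positions carries residues
# from the same side-chain category.  A per-query model trained only on
# relevant motifs avoids diluting the fit with unrelated chemistry.

#' Is a candidate motif relevant to a query?
#'
#' True when at least one aligned variable position has query and candidate
#' residues in the same amino-acid category (identical residues trivially
#' qualify).  Both motifs must come from the same terminal: the opposite
#' terminal is all-wildcard and carries no information.
#'
#' @param query,candidate 7-character motif strings (or 3-letter residue
#'   triples accepted by [motif_string()] semantics via `terminal`).
#' @param categories Category table, as from [aa_category_table()].
#' @return Logical.
#' @examples
#' is_relevant("RAFsXXX", "RGQsXXX")  # TRUE: P-3 both positive-charged
#' is_relevant("RAFsXXX", "EEEsXXX")  # FALSE: no position shares a category
#' @export
is_relevant <- function(query, candidate, categories = aa_category_table()) {
  stopifnot(length(query) == 1L, length(candidate) == 1L)
  if (motif_terminal(query) != motif_terminal(candidate)) {
    stop("query and candidate must come from the same terminal")
  }
  qc <- categories[motif_residues(query)[1L, ]]
  cc <- categories[motif_residues(candidate)[1L, ]]
  any(qc == cc)
}

# Vectorized core: indices of candidate rows relevant to a residue triple.
relevant_indices <- function(query_res, cand_res, categories) {
  qc <- categories[query_res]
  m <- matrix(categories[cand_res], ncol = 3L)
  which(m[, 1L] == qc[1L] | m[, 2L] == qc[2L] | m[, 3L] == qc[3L])
}

#' Select relevant training records for a query
#'
#' Order-preserving filter of `candidates` by [is_relevant()].  When the
#' filter would leave nothing (possible only for queries outside the
#' factorial library), the full candidate list is returned with a warning:
#' a broad training set beats an empty one.
#'
#' @param query 7-character motif string.
#' @param candidates Data.frame of affinity records (columns `terminal`,
#'   `sequence`, ...) sharing the query's terminal.  The caller excludes
#'   the query itself when doing leave-one-out.
#' @param categories Category table.
#' @return The relevant subset of `candidates`, original order kept.
#' @export
select_relevant <- function(query, candidates,
                            categories = aa_category_table()) {
  if (nrow(candidates) == 0L) return(candidates)
  if (any(candidates$terminal != motif_terminal(query))) {
    stop("candidates must share the query's terminal")
  }
  idx <- relevant_indices(motif_residues(query)[1L, ],
                          motif_residues(candidates$sequence), categories)
  if (length(idx) == 0L) {
    warning("no relevant candidates for ", query,
            "; falling back to the full candidate list")
    return(candidates)
  }
  candidates[idx, , drop = FALSE]
}
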