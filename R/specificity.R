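# Downstream specificity analyses: top binders, position weight matrices,
# cross-isoform consensus and isoform-specific calls, similarity scoring
# against reference binders, and a randomization test.

.ALL_POSITIONS <- c("P-3", "P-2", "P-1", "P+1", "P+2", "P+3")

#' Top-k binders by affinity
#'
#' @param records Data.frame of affinity records.
#' @param k Number of motifs to keep (`0 < k <= nrow(records)`).
#' @return The k records with highest affinity, in descending affinity
#'   order; ties broken by lexicographically smaller motif string, so the
#'   result is deterministic.
#' @export
top_k <- function(records, k) {
  stopifnot(k > 0L, k <= nrow(records))
  ord <- order(-records$affinity, records$sequence)
  records[ord[seq_len(k)], , drop = FALSE]
}

#' Position-wise amino-acid frequencies (PWM)
#'
#' Per covered position, the relative frequency of each amino acid among
#' the motifs, optionally weighted by affinity ("affinity-weighted" mode,
#' the default used for scoring-matrix displays of top binders; equal
#' weights reproduce plain frequencies).  Positions of a terminal not
#' present in the input are returned as `NA` rows, not zeros.
#'
#' @param records Data.frame with a `sequence` column (and `affinity` if
#'   `mode = "affinity-weighted"`), or a character vector of motifs.
#' @param mode `"frequency"` or `"affinity-weighted"`.
#' @param weights Optional explicit non-negative weights overriding both
#'   modes.
#' @return A 6 x 20 matrix of class `pep_pwm` (positions P-3..P+3 by amino
#'   acid); each covered row sums to 1.
#' @export
position_frequencies <- function(records,
                                 mode = c("frequency", "affinity-weighted"),
                                 weights = NULL) {
  mode <- match.arg(mode)
  if (is.character(records)) {
    records <- data.frame(sequence = records, stringsAsFactors = FALSE)
  }
  n <- nrow(records)
  if (n == 0L) stop("no motifs to tabulate")
  if (is.null(weights)) {
    weights <- if (mode == "affinity-weighted") {
      stopifnot(!is.null(records$affinity))
      records$affinity
    } else rep(1, n)
  }
  stopifnot(length(weights) == n, all(is.finite(weights)), all(weights >= 0))
  if (sum(weights) <= 0) stop("weights sum to zero")
  res <- motif_residues(records$sequence)
  term <- motif_terminal(records$sequence)
  W <- matrix(NA_real_, 6L, 20L, dimnames = list(.ALL_POSITIONS, .AA20))
  for (t in intersect(c("N", "C"), unique(term))) {
    rows <- term == t
    pos <- motif_positions(t)
    for (j in 1:3) {
      tab <- tapply(weights[rows], factor(res[rows, j], levels = .AA20), sum)
      tab[is.na(tab)] <- 0
      W[pos[j], ] <- tab / sum(tab)
    }
  }
  structure(W, class = c("pep_pwm", "matrix"), mode = mode)
}

#' @export
print.pep_pwm <- function(x, digits = 3, ...) {
  cat("Position weight matrix (", attr(x, "mode"), " mode)\n", sep = "")
  covered <- !apply(is.na(unclass(x)), 1L, all)
  print(round(unclass(x)[covered, , drop = FALSE], digits))
  if (any(!covered)) {
    cat("positions not covered by the input:",
        paste(rownames(x)[!covered], collapse = " "), "\n")
  }
  invisible(x)
}

#' Consensus binders across isoforms
#'
#' Motifs present in every isoform's top-binder list.  Order follows the
#' first list (after deduplication), so the result is deterministic.
#'
#' @param top_lists Named list (one element per isoform) of character
#'   vectors of motif strings; at least 2 lists.
#' @return Character vector of consensus motifs.
#' @export
consensus_binders <- function(top_lists) {
  stopifnot(is.list(top_lists), length(top_lists) >= 2L)
  Reduce(intersect, lapply(top_lists, unique))
}

#' Isoform-specific binders
#'
#' Motifs in the target isoform's top-binder list that appear in no other
#' isoform's list.
#'
#' @inheritParams consensus_binders
#' @param target Name of the isoform of interest (e.g. `"sigma"`).
#' @return Character vector of target-only motifs, in the target list's
#'   order.
#' @export
isoform_specific <- function(top_lists, target) {
  if (!target %in% names(top_lists)) stop("unknown isoform: ", target)
  others <- unique(unlist(top_lists[setdiff(names(top_lists), target)]))
  setdiff(unique(top_lists[[target]]), others)
}

as_residue_triple <- function(x) {
  if (length(x) == 3L) {
    x <- toupper(as.character(x))
  } else if (length(x) == 1L && nchar(x) == 7L) {
    x <- motif_residues(x)[1L, ]
  } else if (length(x) == 1L && nchar(x) == 3L) {
    x <- strsplit(x, "")[[1]]
  } else {
    stop("expected a residue triple, a 3-letter string, or a motif string")
  }
  assert_canonical(x)
  x
}

#' Similarity score against a reference binder
#'
#' Position-wise 3/1/0 rule over the three aligned variable positions:
#' 3 for an identical residue, 1 for a different residue of the same
#' side-chain category, 0 otherwise.  The total ranges 0..9; a motif scored
#' against itself gives 9, and the score is symmetric.
#'
#' @param motif Motif string, 3-letter string, or residue triple.
#' @param reference Reference residue triple aligned to the same terminal
#'   (same accepted forms).
#' @param categories Category table.
#' @return List of class `similarity_score` with `total` and
#'   `per_position` (each element 0, 1 or 3).
#' @examples
#' similarity_score("FGP", "LLR")$total  # 1
#' @export
similarity_score <- function(motif, reference,
                             categories = aa_category_table()) {
  a <- as_residue_triple(motif)
  b <- as_residue_triple(reference)
  per <- ifelse(a == b, 3L,
                ifelse(categories[a] == categories[b], 1L, 0L))
  structure(list(total = sum(per), per_position = unname(per)),
            class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat("similarity", paste(x$per_position, collapse = "+"),
      "=", x$total, "\n")
  invisible(x)
}

#' Randomization test for a similarity score
#'
#' Draws `n_iter` random residue triples (each position uniform over its
#' null alphabet), scores each against the reference, and reports
#' `p = #(null total >= observed) / n_iter`.
#'
#' @param observed Observed similarity total.
#' @param reference Reference residue triple (any form accepted by
#'   [similarity_score()]).
#' @param null_alphabets `"full"` (20 amino acids at every position),
#'   `"blocks"` (the building-block alphabets, outermost position first for
#'   `terminal = "N"`, last for `"C"`), or a list of 3 character vectors.
#' @param terminal Terminal used to orient the building-block alphabets
#'   when `null_alphabets = "blocks"`.
#' @param n_iter Number of random draws (>= 1).
#' @param seed Optional integer seed.
#' @param categories Category table.
#' @return The Monte-Carlo p-value in `[0, 1]`.
#' @export
randomization_pvalue <- function(observed, reference,
                                 null_alphabets = "full",
                                 terminal = c("N", "C"),
                                 n_iter = 1000L, seed = NULL,
                                 categories = aa_category_table()) {
  terminal <- match.arg(terminal)
  stopifnot(n_iter >= 1L)
  if (identical(null_alphabets, "full")) {
    alphabets <- rep(list(.AA20), 3L)
  } else if (identical(null_alphabets, "blocks")) {
    ab <- sublibrary_alphabet("blocks")
    alphabets <- if (terminal == "N") list(ab$p3, ab$p12, ab$p12)
                 else list(ab$p12, ab$p12, ab$p3)
  } else {
    stopifnot(is.list(null_alphabets), length(null_alphabets) == 3L)
    alphabets <- null_alphabets
  }
  if (any(lengths(alphabets) == 0L)) stop("empty null alphabet")
  for (a in alphabets) assert_canonical(a)
  ref <- as_residue_triple(reference)
  refcat <- categories[ref]
  totals <- with_seed(seed, {
    tot <- integer(n_iter)
    for (j in 1:3) {
      draw <- sample(alphabets[[j]], n_iter, replace = TRUE)
      tot <- tot + ifelse(draw == ref[j], 3L,
                          ifelse(categories[draw] == refcat[j], 1L, 0L))
    }
    tot
  })
  mean(totals >= observed)
}
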