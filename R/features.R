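# Feature extraction: each motif maps to 54 values.
#
# Block 1 (27): the standardized value of each of the 9 physicochemical
# properties at each of the 3 variable positions (written N-to-C order).
# Block 2 (27): for each property, the auto-cross covariance of each
# unordered position pair (1,2), (1,3), (2,3) -- the product of the two
# positions' deviations from that property's mean over the three positions.
# The pS/pT center and the wildcard terminal contribute nothing.

feature_names <- function() {
  c(paste0(rep(paste0("p", 1:3), each = 9L), "_", rep(.PROPERTIES, 3L)),
    paste0(rep(paste0("ac", c("12", "13", "23")), each = 9L), "_",
           rep(.PROPERTIES, 3L)))
}

#' Positional physicochemical features
#'
#' @param sequence A single 7-character motif string.
#' @param norm Standardized property table from [normalize_properties()].
#' @return Named numeric vector of 27 values (position x property).
#' @export
positional_features <- function(sequence, norm = default_norm_table()) {
  featurize(sequence, norm)[1:27]
}

#' Auto-cross covariance features
#'
#' For property j with standardized values x1, x2, x3 at the three variable
#' positions and m their mean, the pair (m, n) contributes
#' (xm - m) * (xn - m).  A constant residue triple gives 27 zeros, and for
#' every motif the three pair terms of one property sum to
#' -(1/2) * sum_i (xi - m)^2 <= 0.
#'
#' @inheritParams positional_features
#' @return Named numeric vector of 27 values (pair x property).
#' @export
ac_features <- function(sequence, norm = default_norm_table()) {
  featurize(sequence, norm)[28:54]
}

#' Featurize one motif
#'
#' @inheritParams positional_features
#' @return Named numeric vector of 54 values: 27 positional then 27
#'   auto-cross covariance, in the frozen order of [feature_names()].
#' @export
featurize <- function(sequence, norm = default_norm_table()) {
  stopifnot(length(sequence) == 1L)
  featurize_motifs(sequence, norm)[1L, ]
}

#' Featurize many motifs
#'
#' @param sequence Character vector of 7-character motif strings.
#' @param norm Standardized property table.
#' @return An n x 54 numeric matrix, columns named by [feature_names()].
#' @export
featurize_motifs <- function(sequence, norm = default_norm_table()) {
  stopifnot(inherits(norm, "aa_norm_table"))
  res <- motif_residues(sequence)
  P <- norm$values
  a1 <- P[res[, 1L], , drop = FALSE]
  a2 <- P[res[, 2L], , drop = FALSE]
  a3 <- P[res[, 3L], , drop = FALSE]
  mu <- (a1 + a2 + a3) / 3
  d1 <- a1 - mu; d2 <- a2 - mu; d3 <- a3 - mu
  out <- cbind(a1, a2, a3, d1 * d2, d1 * d3, d2 * d3)
  dimnames(out) <- list(NULL, feature_names())
  out
}
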