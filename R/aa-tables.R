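# Amino-acid category partition and physicochemical property table.
#
# Both tables ship as plain TSV under inst/extdata and are validated on load
# against frozen md5 checksums, so a silently edited data file fails loudly.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.PROPERTIES <- c("H1", "H2", "H3", "V", "P1", "P2", "SASA", "NCI", "MASS")

.CHECKSUMS <- c(
  aa_properties.tsv = "c6f89c411e0e9f7f4cb00a212626480a",
  aa_categories.tsv = "95b31a8565f9b1de2e14c5916123a541"
)

pep_extdata <- function(file) {
  path <- system.file("extdata", file, package = "pep1433", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(.CHECKSUMS[[file]]))) {
    stop("checksum mismatch for shipped table '", file,
         "': file has been modified", call. = FALSE)
  }
  path
}

#' The 20 canonical amino acids
#'
#' One-letter codes in alphabetical order; the row order used by every table
#' and feature block in this package.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() .AA20

assert_canonical <- function(aa, what = "residue") {
  bad <- setdiff(unique(aa), .AA20)
  if (length(bad) > 0) {
    stop("non-canonical ", what, " symbol(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  invisible(aa)
}

#' Five-way amino-acid category partition
#'
#' Side-chain classes: positive-charged (R, H, K), negative-charged (D, E),
#' polar-uncharged (S, T, N, Q), hydrophobic (A, I, L, M, F, W, Y, V) and
#' special (C, G, P).  The five classes partition the 20 canonical amino
#' acids; the relevance-sampling rule and the similarity score are both
#' defined on this partition.
#'
#' @return Named character vector mapping one-letter code to category label.
#' @export
aa_category_table <- function() {
  if (!is.null(.pep_cache$categories)) return(.pep_cache$categories)
  tab <- utils::read.delim(pep_extdata("aa_categories.tsv"),
                           stringsAsFactors = FALSE)
  cats <- stats::setNames(tab$category, tab$aa)
  if (!setequal(names(cats), .AA20) || anyDuplicated(names(cats)) > 0) {
    stop("category table must assign each of the 20 amino acids exactly once")
  }
  cats <- cats[.AA20]
  .pep_cache$categories <- cats
  cats
}

#' Category of an amino acid
#'
#' @param aa Character vector of one-letter amino-acid codes.
#' @param categories Category table, as from [aa_category_table()].
#' @return Character vector of category labels.
#' @examples
#' category_of(c("R", "A", "G"))
#' @export
category_of <- function(aa, categories = aa_category_table()) {
  assert_canonical(aa)
  unname(categories[aa])
}

#' The 20 x 9 physicochemical property table
#'
#' Nine descriptors per amino acid, in fixed column order: hydrophobicity
#' (H1), hydrophilicity (H2), hydrogen bond (H3), side-chain volume (V),
#' polarity (P1), polarizability (P2), solvent-accessible surface area
#' (SASA), net charge index of side chains (NCI) and average residue mass
#' (MASS).  Values are shipped verbatim; note Q and R carry identical P1,
#' P2, SASA and NCI entries in the source table and are kept as printed.
#'
#' @return A 20 x 9 numeric matrix, rows named by amino acid.
#' @export
aa_property_table <- function() {
  if (!is.null(.pep_cache$properties)) return(.pep_cache$properties)
  tab <- utils::read.delim(pep_extdata("aa_properties.tsv"),
                           stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, .PROPERTIES])
  rownames(mat) <- tab$aa
  if (!identical(rownames(mat), .AA20) || any(!is.finite(mat))) {
    stop("property table must have one finite row per canonical amino acid")
  }
  .pep_cache$properties <- mat
  mat
}

#' Column-standardize a property table
#'
#' Each property column is shifted and scaled to zero mean and unit standard
#' deviation over the 20 amino acids.  The divisor is the population SD
#' (n = 20): the canonical amino acids are the whole population, not a
#' sample.  Means and SDs are retained so the transform is invertible.
#'
#' @param raw 20 x 9 numeric property matrix, as from [aa_property_table()].
#' @param divisor `"population"` (default, divisor n) or `"sample"`
#'   (divisor n - 1).
#' @return An object of class `aa_norm_table`: list with `values` (20 x 9
#'   standardized matrix), `center`, `scale` (per-column mean and SD) and
#'   `divisor`.
#' @export
normalize_properties <- function(raw = aa_property_table(),
                                 divisor = c("population", "sample")) {
  divisor <- match.arg(divisor)
  stopifnot(is.matrix(raw), nrow(raw) == 20L, ncol(raw) == 9L)
  if (any(!is.finite(raw))) stop("property table contains non-finite entries")
  n <- nrow(raw)
  ctr <- colMeans(raw)
  dev <- sweep(raw, 2L, ctr)
  scl <- sqrt(colSums(dev^2) / if (divisor == "population") n else n - 1L)
  if (any(scl <= 0)) {
    stop("property column(s) with zero standard deviation: ",
         paste(colnames(raw)[scl <= 0], collapse = ", "))
  }
  structure(
    list(values = sweep(dev, 2L, scl, "/"), center = ctr, scale = scl,
         divisor = divisor),
    class = "aa_norm_table")
}

default_norm_table <- function() {
  if (is.null(.pep_cache$norm)) {
    .pep_cache$norm <- normalize_properties(aa_property_table())
  }
  .pep_cache$norm
}

#' @export
print.aa_norm_table <- function(x, ...) {
  cat("Standardized amino-acid property table (", x$divisor,
      " SD divisor)\n", sep = "")
  print(round(x$values, 3))
  invisible(x)
}
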