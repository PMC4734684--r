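# Hexapeptide phosphomotifs and combinatorial sublibraries.
#
# A motif is one terminal's three variable residues around a fixed pS/pT
# center; the opposite terminal is wildcard.  Text encoding is a 7-character
# string: three residues, then a lowercase center ("s", "t", or "x" when
# unspecified), then three residues, with the wildcard side written "XXX".
# An N-terminal Arg-Ala-Phe motif is "RAFsXXX"; a C-terminal Phe-Gly-Pro
# motif is "XXXsFGP".  Residues are always written N-to-C, i.e. P-3 P-2 P-1
# for the N terminal and P+1 P+2 P+3 for the C terminal.

.BLOCKS_P12 <- c("R", "E", "F", "L", "Q", "A", "G", "V", "K", "P")
.BLOCKS_P3 <- c("R", "E", "F", "L", "P")

.POSITIONS_N <- c("P-3", "P-2", "P-1")
.POSITIONS_C <- c("P+1", "P+2", "P+3")

#' Build motif strings from residue triples
#'
#' @param residues Character vector of 3-letter residue strings (e.g.
#'   `"RAF"`) or a matrix/data.frame with 3 columns of one-letter codes,
#'   written N-to-C.
#' @param terminal `"N"` or `"C"`: which sublibrary the residues occupy.
#' @param center `"s"`, `"t"` or `"x"` (phospho-serine, phospho-threonine,
#'   unspecified).  The center is metadata only; it never enters features.
#' @return Character vector of 7-character motif strings.
#' @examples
#' motif_string("RAF", "N")  # "RAFsXXX"
#' @export
motif_string <- function(residues, terminal = c("N", "C"), center = "s") {
  terminal <- match.arg(terminal)
  if (is.matrix(residues) || is.data.frame(residues)) {
    stopifnot(ncol(residues) == 3L)
    residues <- apply(as.matrix(residues), 1L, paste0, collapse = "")
  }
  stopifnot(all(nchar(residues) == 3L), center %in% c("s", "t", "x"))
  assert_canonical(unlist(strsplit(residues, "")))
  if (terminal == "N") paste0(residues, center, "XXX")
  else paste0("XXX", center, residues)
}

#' Terminal of a motif string
#'
#' @param sequence Character vector of 7-character motif strings.
#' @return Character vector of `"N"` / `"C"`.
#' @export
motif_terminal <- function(sequence) {
  validate_motif(sequence)
  ifelse(substr(sequence, 5L, 7L) == "XXX", "N", "C")
}

validate_motif <- function(sequence) {
  ok <- nchar(sequence) == 7L
  left <- substr(sequence, 1L, 3L)
  right <- substr(sequence, 5L, 7L)
  ctr <- substr(sequence, 4L, 4L)
  is_n <- right == "XXX" & left != "XXX"
  is_c <- left == "XXX" & right != "XXX"
  var <- ifelse(is_n, left, right)
  ok <- ok & (is_n | is_c) & ctr %in% c("s", "t", "x") &
    !grepl("[^A-Z]", var) &
    vapply(strsplit(var, ""), function(r) all(r %in% .AA20), logical(1))
  if (any(!ok)) {
    stop("malformed motif string(s): ",
         paste(sQuote(sequence[!ok][seq_len(min(5, sum(!ok)))]),
               collapse = ", "), call. = FALSE)
  }
  invisible(sequence)
}

#' Variable residues of motif strings
#'
#' @param sequence Character vector of 7-character motif strings.
#' @return An n x 3 character matrix of one-letter codes, columns in written
#'   (N-to-C) order.
#' @export
motif_residues <- function(sequence) {
  validate_motif(sequence)
  var <- ifelse(substr(sequence, 5L, 7L) == "XXX",
                substr(sequence, 1L, 3L), substr(sequence, 5L, 7L))
  out <- matrix(unlist(strsplit(var, ""), use.names = FALSE),
                ncol = 3L, byrow = TRUE)
  rownames(out) <- NULL
  out
}

#' Position labels of a terminal
#'
#' @param terminal `"N"` or `"C"`.
#' @return The three position labels in written order
#'   (`"P-3" "P-2" "P-1"` or `"P+1" "P+2" "P+3"`).
#' @export
motif_positions <- function(terminal = c("N", "C")) {
  terminal <- match.arg(terminal)
  if (terminal == "N") .POSITIONS_N else .POSITIONS_C
}

#' Building-block alphabets of a sublibrary
#'
#' The experimental fragment library uses ten building blocks
#' (R, E, F, L, Q, A, G, V, K, P) at the two positions adjacent to the
#' phospho-center and five (R, E, F, L, P) at the outermost position; the
#' "full" design opens every position to all 20 amino acids.
#'
#' @param alphabet `"blocks"`, `"full"`, or a list with components `p12`
#'   and `p3` giving custom alphabets.
#' @return List with character vectors `p12` (adjacent positions) and `p3`
#'   (outermost position), each sorted.
#' @export
sublibrary_alphabet <- function(alphabet = "blocks") {
  if (is.list(alphabet)) {
    stopifnot(all(c("p12", "p3") %in% names(alphabet)))
    ab <- list(p12 = sort(unique(alphabet$p12)),
               p3 = sort(unique(alphabet$p3)))
  } else if (identical(alphabet, "blocks")) {
    ab <- list(p12 = sort(.BLOCKS_P12), p3 = sort(.BLOCKS_P3))
  } else if (identical(alphabet, "full")) {
    ab <- list(p12 = .AA20, p3 = .AA20)
  } else {
    stop("alphabet must be \"blocks\", \"full\", or a list(p12 =, p3 =)")
  }
  if (length(ab$p12) == 0L || length(ab$p3) == 0L) {
    stop("empty building-block alphabet")
  }
  assert_canonical(c(ab$p12, ab$p3), "building block")
  ab
}

#' Enumerate a factorial sublibrary
#'
#' Full Cartesian product of the per-position alphabets for one terminal:
#' |p3| x |p12|^2 motifs (500 for the default building blocks, 8000 per
#' terminal for the full 20-amino-acid design).  Order is deterministic:
#' alphabets sorted, outermost position varying slowest, innermost fastest.
#'
#' @inheritParams motif_string
#' @inheritParams sublibrary_alphabet
#' @return A data.frame with columns `motif_id`, `terminal`, `sequence`.
#' @examples
#' nrow(enumerate_sublibrary("N"))           # 500
#' nrow(enumerate_sublibrary("C", "full"))   # 8000
#' @export
enumerate_sublibrary <- function(terminal = c("N", "C"), alphabet = "blocks",
                                 center = "s") {
  terminal <- match.arg(terminal)
  ab <- sublibrary_alphabet(alphabet)
  # expand.grid varies the first factor fastest; put the innermost there
  g <- expand.grid(inner = ab$p12, mid = ab$p12, outer = ab$p3,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  res <- if (terminal == "N") paste0(g$outer, g$mid, g$inner)
         else paste0(g$inner, g$mid, g$outer)
  data.frame(
    motif_id = sprintf("%s%05d", terminal, seq_len(nrow(g))),
    terminal = terminal,
    sequence = motif_string(res, terminal, center),
    stringsAsFactors = FALSE)
}

#' Read / write motif affinity tables
#'
#' Plain TSV with header columns `motif_id`, `terminal`, `sequence`,
#' `affinity`.  Affinities are arbitrary non-negative intensity units; an
#' empty affinity field marks a prediction input and is read as `NA`.
#' Writing then reading reproduces records exactly (affinities serialized
#' with 17 significant digits).
#'
#' @param path File path.
#' @return `read_affinity_table`: data.frame with the four columns above.
#' @export
read_affinity_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  need <- c("motif_id", "terminal", "sequence", "affinity")
  if (!all(need %in% names(tab))) {
    stop("affinity table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  fail <- function(i, msg) {
    stop("line ", i + 1L, " of ", path, ": ", msg, call. = FALSE)
  }
  for (i in seq_len(nrow(tab))) {
    if (!tab$terminal[i] %in% c("N", "C")) {
      fail(i, paste0("unknown terminal tag ", sQuote(tab$terminal[i])))
    }
    ok <- tryCatch({validate_motif(tab$sequence[i]); TRUE},
                   error = function(e) FALSE)
    if (!ok) fail(i, paste0("malformed motif ", sQuote(tab$sequence[i])))
    if (motif_terminal(tab$sequence[i]) != tab$terminal[i]) {
      fail(i, "terminal tag does not match sequence")
    }
    a <- tab$affinity[i]
    if (!is.na(a) && nzchar(a)) {
      v <- suppressWarnings(as.numeric(a))
      if (is.na(v) || !is.finite(v)) fail(i, paste0("bad affinity ", sQuote(a)))
      if (v < 0) fail(i, paste0("negative affinity ", a))
    }
  }
  tab$affinity <- suppressWarnings(
    as.numeric(ifelse(nzchar(tab$affinity), tab$affinity, NA)))
  tab
}

#' @rdname read_affinity_table
#' @param records Data.frame with columns `motif_id`, `terminal`,
#'   `sequence`, `affinity`.
#' @export
write_affinity_table <- function(records, path) {
  need <- c("motif_id", "terminal", "sequence", "affinity")
  stopifnot(all(need %in% names(records)))
  out <- records[, need]
  out$affinity <- ifelse(is.na(out$affinity), "",
                         sprintf("%.17g", out$affinity))
  write_atomic(out, path)
  invisible(path)
}

# Write a TSV atomically: temp file in the target directory, then rename.
write_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tsv")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
}
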