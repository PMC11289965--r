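# Sequence normalization and dot-bracket structure utilities.

#' @useDynLib sparsefold, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# normalize an RNA sequence: uppercase, T -> U; error on anything outside
# A/C/G/U.  Returns the normalized character string.
normalize_sequence <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("sequence must be a single character string")
  s <- chartr("acgut", "ACGUU", seq)
  s <- chartr("T", "U", s)
  if (!nzchar(s)) stop("sequence must have length >= 1")
  if (grepl("[^ACGU]", s))
    stop("invalid residue(s) in sequence after normalization: ",
         paste(unique(strsplit(gsub("[ACGU]", "", s), "")[[1]]),
               collapse = ", "))
  s
}

# integer base codes 0=N 1=A 2=C 3=G 4=U, 1-based along the sequence
seq_codes <- function(s) {
  match(strsplit(s, "")[[1]], c("A", "C", "G", "U"))
}

#' Pair type of two bases
#'
#' Classifies an ordered base pair (5' base, 3' base) into one of the six
#' canonical types CG, GC, GU, UG, AU, UA, or \code{NA} when the bases are
#' not complementary (Watson-Crick or wobble).
#'
#' @param b5,b3 Single characters in \code{A,C,G,U} (case-insensitive,
#'   \code{T} accepted as \code{U}).
#' @return A character scalar naming the pair type, or \code{NA_character_}.
#' @examples
#' pair_type("G", "C")  # "GC"
#' pair_type("A", "G")  # NA
#' @export
pair_type <- function(b5, b3) {
  codes <- c("A", "C", "G", "U")
  c5 <- seq_codes(normalize_sequence(b5))
  c3 <- seq_codes(normalize_sequence(b3))
  if (length(c5) != 1L || length(c3) != 1L)
    stop("b5 and b3 must be single bases")
  types <- c("CG", "GC", "GU", "UG", "AU", "UA")
  key <- paste0(codes[c5], codes[c3])
  out <- types[match(key, types)]
  out
}

#' Convert dot-bracket notation to a partner table
#'
#' @param db Dot-bracket string using \code{(}, \code{)} and \code{.}.
#' @return Integer vector \code{pt} with \code{pt[i]} the partner of
#'   position \code{i} (0 when unpaired).
#' @examples
#' db_to_pairs("(((....))).")
#' @export
db_to_pairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  bad <- setdiff(unique(ch), c("(", ")", "."))
  if (length(bad))
    stop("invalid character(s) in dot-bracket string: ",
         paste(bad, collapse = ", "))
  pt <- integer(length(ch))
  stack <- integer(0)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      stack <- c(stack, k)
    } else if (ch[k] == ")") {
      if (!length(stack)) stop("unbalanced ')' at position ", k)
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- k
      pt[k] <- i
    }
  }
  if (length(stack)) stop("unbalanced '(' at position ", stack[1])
  pt
}

#' Convert a partner table to dot-bracket notation
#'
#' @param pt Integer partner table as returned by [db_to_pairs()].
#' @return Dot-bracket string.
#' @export
pairs_to_db <- function(pt) {
  ch <- rep(".", length(pt))
  ch[pt > seq_along(pt)] <- "("
  ch[pt > 0 & pt < seq_along(pt)] <- ")"
  paste(ch, collapse = "")
}

# validate a partner table against a sequence; checks involution, minimum
# hairpin distance and absence of crossing pairs
validate_structure <- function(pt, n, m = 3L) {
  if (length(pt) != n) stop("structure length does not match sequence length")
  idx <- which(pt > 0)
  if (any(pt[pt[idx]] != idx)) stop("partner table is not an involution")
  op <- which(pt > seq_along(pt))
  if (any(pt[op] - op <= m))
    stop("base pair violates the minimum hairpin loop size")
  if (length(op) > 1) {
    for (i in op) {
      j <- pt[i]
      inside <- op[op > i & op < j]
      if (any(pt[inside] > j)) stop("crossing base pairs (pseudoknot)")
    }
  }
  invisible(TRUE)
}
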