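# Hard structural constraints: per-position requirements that restrict the
# folding search space.  The text dialect uses '.' (unconstrained), 'x'
# (forced unpaired) and matched '(' ')' (forced base pair).

#' Parse a hard-constraint string
#'
#' @param text Constraint string over \code{. x ( )}, same length as the
#'   sequence.  Matched brackets force a base pair; \code{x} forces a
#'   position to stay unpaired.
#' @param seq RNA sequence the constraints apply to.
#' @param m Minimum hairpin loop size used to validate forced pairs.
#' @return An object of class \code{rna_constraints}: list with \code{n},
#'   \code{partner} (integer vector: 0 free, -1 forced unpaired, otherwise
#'   the forced partner) and \code{text}.
#' @examples
#' parse_constraints("(.........)", "GGGAAAACCCC")
#' @export
parse_constraints <- function(text, seq, m = 3L) {
  s <- normalize_sequence(seq)
  n <- nchar(s)
  if (!is.character(text) || length(text) != 1L)
    stop("constraint must be a single character string")
  if (nchar(text) != n)
    stop("constraint length ", nchar(text),
         " does not match sequence length ", n)
  ch <- strsplit(text, "")[[1]]
  bad <- which(!ch %in% c(".", "x", "(", ")"))
  if (length(bad))
    stop("invalid constraint character '", ch[bad[1]], "' at position ",
         bad[1])
  partner <- integer(n)
  partner[ch == "x"] <- -1L
  stack <- integer(0)
  for (k in seq_len(n)) {
    if (ch[k] == "(") stack <- c(stack, k)
    if (ch[k] == ")") {
      if (!length(stack)) stop("unbalanced ')' in constraint at position ", k)
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- k
      partner[k] <- i
    }
  }
  if (length(stack))
    stop("unbalanced '(' in constraint at position ", stack[1])
  bases <- strsplit(s, "")[[1]]
  for (i in which(partner > seq_len(n))) {
    j <- partner[i]
    if (is.na(pair_type(bases[i], bases[j])))
      stop("forced pair ", i, ".", j, " (", bases[i], "-", bases[j],
           ") is not canonical")
    if (j - i <= m)
      stop("forced pair ", i, ".", j, " violates the minimum hairpin loop")
  }
  structure(list(n = n, partner = partner, text = text),
            class = "rna_constraints")
}

# coerce NULL / string / rna_constraints into the partner vector consumed by
# the engines
as_constraint_partner <- function(constraints, seq) {
  if (is.null(constraints)) return(integer(0))
  if (is.character(constraints)) constraints <- parse_constraints(constraints, seq)
  if (!inherits(constraints, "rna_constraints"))
    stop("constraints must be NULL, a constraint string or an 'rna_constraints' object")
  if (constraints$n != nchar(normalize_sequence(seq)))
    stop("constraint length does not match sequence length")
  constraints$partner
}

#' Is a pair allowed by the constraints?
#'
#' \code{pair_allowed} reports whether positions i and j may pair:
#' false when either end is forced unpaired or forced to a different
#' partner.  \code{region_unpaired_ok} reports whether the region
#' \code{[i, j]} contains no forced-paired position; both run in O(1) via a
#' prefix count of forced-paired positions.
#'
#' @param i,j Positions, \code{1 <= i <= j <= n}.
#' @param constraints An \code{rna_constraints} object.
#' @return Logical scalar.
#' @export
pair_allowed <- function(i, j, constraints) {
  p <- constraints$partner
  if (p[i] == -1L || p[j] == -1L) return(FALSE)
  if (p[i] > 0L && p[i] != j) return(FALSE)
  if (p[j] > 0L && p[j] != i) return(FALSE)
  TRUE
}

#' @rdname pair_allowed
#' @export
region_unpaired_ok <- function(i, j, constraints) {
  if (i > j) return(TRUE)
  pfx <- cumsum(c(0L, constraints$partner > 0L))
  pfx[j + 1L] - pfx[i] == 0L
}

#' Random pseudoknot-free constraint generator
#'
#' Draws two random indices at a time; a pair is kept when the bases are
#' complementary, the ends are far enough apart, neither end is already
#' used, and the pair does not cross a previously accepted one.  The number
#' of forced pairs is capped at \code{floor(0.5 * log2(n))}; sampling stops
#' after \code{10 *} cap attempts.
#'
#' @param seq RNA sequence (length >= 8).
#' @param seed Integer seed; the generator is a pure function of
#'   \code{(seq, seed)}.
#' @param m Minimum separation: accepted pairs satisfy \code{j - i > m}.
#' @return An \code{rna_constraints} object (possibly with no forced pairs).
#' @examples
#' random_constraints(random_sequence(64, seed = 7), seed = 1)
#' @export
random_constraints <- function(seq, seed, m = 3L) {
  s <- normalize_sequence(seq)
  n <- nchar(s)
  if (n < 8L) stop("sequence too short for constraint generation (n >= 8)")
  cap <- floor(0.5 * log2(n))
  bases <- strsplit(s, "")[[1]]
  partner <- integer(n)
  with_preserved_seed(seed, {
    attempts <- 0L
    while (sum(partner > 0L) / 2L < cap && attempts < 10L * cap) {
      attempts <- attempts + 1L
      ij <- sort(sample.int(n, 2L))
      i <- ij[1]; j <- ij[2]
      if (j - i <= m) next
      if (partner[i] != 0L || partner[j] != 0L) next
      if (is.na(pair_type(bases[i], bases[j]))) next
      # reject crossings with accepted pairs
      op <- which(partner > seq_len(n))
      crosses <- any((op < i & partner[op] > i & partner[op] < j) |
                     (op > i & op < j & partner[op] > j))
      if (crosses) next
      partner[i] <- j
      partner[j] <- i
    }
  })
  ch <- rep(".", n)
  ch[partner > seq_len(n)] <- "("
  ch[partner > 0L & partner < seq_len(n)] <- ")"
  structure(list(n = n, partner = partner, text = paste(ch, collapse = "")),
            class = "rna_constraints")
}

#' @export
print.rna_constraints <- function(x, ...) {
  cat("RNA hard constraints (n = ", x$n, ")\n", sep = "")
  cat(" ", x$text, "\n", sep = "")
  cat("  forced pairs: ", sum(x$partner > 0) / 2,
      ", forced unpaired: ", sum(x$partner == -1), "\n", sep = "")
  invisible(x)
}
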