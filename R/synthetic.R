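# Deterministic generators for test inputs: i.i.d. random sequences,
# dinucleotide-preserving shuffles, and the worked-example fixtures.

# run code with R's RNG seeded to `seed`, restoring the caller's RNG state
with_preserved_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a random RNA sequence
#'
#' Draws residues i.i.d. from the given base composition.  A fixed seed
#' yields an identical sequence; the caller's RNG state is left untouched.
#'
#' @param length Sequence length (>= 1).
#' @param seed Integer seed.
#' @param composition Base frequencies for A, C, G, U; must be non-negative
#'   and sum to 1 (tolerance 1e-9).
#' @return Character string over A/C/G/U.
#' @examples
#' random_sequence(20, seed = 42)
#' @export
random_sequence <- function(length, seed,
                            composition = c(A = 0.25, C = 0.25,
                                            G = 0.25, U = 0.25)) {
  if (length < 1) stop("length must be >= 1")
  if (length(composition) != 4L || any(composition < 0))
    stop("composition must be 4 non-negative frequencies")
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition must sum to 1")
  with_preserved_seed(seed, {
    paste(sample(c("A", "C", "G", "U"), length, replace = TRUE,
                 prob = composition), collapse = "")
  })
}

#' Dinucleotide-preserving shuffle
#'
#' Produces a random permutation of the input that preserves the exact
#' multiset of dinucleotide counts (and hence the first and last residue),
#' using the Eulerian-path construction: the sequence is viewed as a walk on
#' the base graph whose edges are dinucleotides; a random arborescence
#' toward the final base fixes each vertex's last outgoing edge, remaining
#' edges are shuffled, and the walk is rebuilt.
#'
#' @param seq RNA sequence (length >= 2).
#' @param seed Integer seed; deterministic for a fixed seed.
#' @return Shuffled sequence with identical dinucleotide counts.
#' @examples
#' dinucleotide_shuffle("GGGAAAACCCC", seed = 1)
#' @export
dinucleotide_shuffle <- function(seq, seed) {
  s <- normalize_sequence(seq)
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n < 2) stop("sequence must have length >= 2")
  bases <- c("A", "C", "G", "U")
  with_preserved_seed(seed, {
    # adjacency lists of the dinucleotide multigraph
    adj <- lapply(bases, function(b) ch[which(ch[-n] == b) + 1L])
    names(adj) <- bases
    last <- ch[n]
    repeat {
      # sample a candidate arborescence: for each vertex with out-edges
      # (except the final vertex) pick the edge reserved for last use
      lastout <- vapply(bases, function(b) {
        if (b == last || !length(adj[[b]])) NA_character_
        else sample(adj[[b]], 1L)
      }, "")
      # verify: following reserved edges from every vertex must reach `last`
      ok <- TRUE
      for (b in bases) {
        if (is.na(lastout[[b]])) next
        seen <- character(0)
        v <- b
        while (v != last && !is.na(lastout[[v]])) {
          if (v %in% seen) break
          seen <- c(seen, v)
          v <- lastout[[v]]
        }
        if (v != last) { ok <- FALSE; break }
      }
      if (ok) break
    }
    # shuffle the remaining edges, appending the reserved edge last
    pools <- lapply(bases, function(b) {
      e <- adj[[b]]
      if (!is.na(lastout[[b]])) {
        e <- e[-match(lastout[[b]], e)]
        c(sample(e), lastout[[b]])
      } else if (length(e)) sample(e) else e
    })
    names(pools) <- bases
    nxt <- stats::setNames(rep(1L, 4L), bases)
    out <- character(n)
    out[1] <- ch[1]
    for (k in 2:n) {
      v <- out[k - 1L]
      out[k] <- pools[[v]][nxt[[v]]]
      nxt[[v]] <- nxt[[v]] + 1L
    }
    paste(out, collapse = "")
  })
}

#' Worked-example fixtures
#'
#' Named folding fixtures with known minimum free energies and structures
#' under the bundled Turner 2004 parameters, used throughout the test suite:
#' the 11-mer whose exclusive-dangle optimum uses a 3' dangle on a shifted
#' outer pair, its hard-constrained variant, and a pair-free sequence.
#'
#' @return A list of fixtures; each has \code{seq}, \code{model},
#'   \code{constraints} (or NULL), \code{mfe} (kcal/mol) and
#'   \code{structure}.
#' @examples
#' fold_fixtures()$shifted_dangle
#' @export
fold_fixtures <- function() {
  list(
    shifted_dangle = list(
      seq = "GGGAAAACCCC", model = "d1", constraints = NULL,
      mfe = -2.9, structure = "(((....)))."),
    forced_outer = list(
      seq = "GGGAAAACCCC", model = "d1", constraints = "(.........)",
      mfe = -2.4, structure = "(((.....)))"),
    empty = list(
      seq = "AAAAAAAAAA", model = "d2", constraints = NULL,
      mfe = 0, structure = "..........")
  )
}
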