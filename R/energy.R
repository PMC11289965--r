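# User-facing energy queries: single-loop energies, dangle table lookups,
# and loop-decomposition evaluation of whole structures.  All quantities
# come from the same C++ energy core the folding engines use.

as_params <- function(params) {
  if (is.null(params)) return(turner2004_params())
  if (!inherits(params, "rna_params"))
    stop("params must be an 'rna_params' object (see read_energy_params)")
  params
}

#' Hairpin loop energy
#'
#' Energy of a hairpin loop closed by pair i.j: length initiation (with
#' logarithmic extrapolation past 30 unpaired bases), closing-pair mismatch
#' or terminal AU/GU penalty, and special tri-/tetra-/hexaloop bonuses.
#' Infinite when the loop is shorter than the minimum hairpin size or the
#' closing pair is not canonical.
#'
#' @param seq RNA sequence.
#' @param i,j Closing pair positions, 1 <= i < j <= n.
#' @param params Energy parameters (default: bundled Turner 2004).
#' @return Integer energy in dekacal/mol (\code{energy_inf()} = forbidden).
#' @examples
#' hairpin_energy("GGGAAAACCCC", 3, 8)
#' @export
hairpin_energy <- function(seq, i, j, params = NULL) {
  params <- as_params(params)
  s <- normalize_sequence(seq)
  n <- nchar(s)
  stopifnot(i >= 1, i < j, j <= n)
  cpp_energy_hairpin(seq_codes(s), s, as.integer(i), as.integer(j),
                     unclass(params))
}

#' Interior loop, bulge or stack energy
#'
#' Energy of the loop between closing pair i.j and inner pair p.q:
#' a stacked pair when both sides are empty, a bulge when one side is
#' empty, otherwise an interior loop with the 1x1/2x1/2x2 special tables,
#' length initiation and capped asymmetry penalty.  Infinite when
#' \code{p - i + j - q - 2} exceeds the loop-size bound M or either pair is
#' not canonical.
#'
#' @param seq RNA sequence.
#' @param i,j Closing pair; \code{i < p < q < j}.
#' @param p,q Inner pair.
#' @inheritParams hairpin_energy
#' @return Integer energy in dekacal/mol.
#' @examples
#' interior_energy("GGGAAAACCCC", 1, 11, 2, 10)  # a stack
#' @export
interior_energy <- function(seq, i, j, p, q, params = NULL) {
  params <- as_params(params)
  s <- normalize_sequence(seq)
  stopifnot(i < p, p < q, q < j, j <= nchar(s))
  cpp_energy_interior(seq_codes(s), s, as.integer(i), as.integer(j),
                      as.integer(p), as.integer(q), unclass(params))
}

#' Dangling-end energy terms
#'
#' Table lookup for the stacking interaction between a helix-closing pair
#' and adjacent unpaired bases: \code{kind = "d5"} is the 5'-side dangle
#' (base at position p-1 for an external-loop pair p.q), \code{"d3"} the
#' 3'-side dangle (base q+1), and \code{"d53"} the both-sides term, which
#' uses the exterior/multiloop mismatch table of the parameter file (or the
#' dangle5+dangle3 sum if \code{sum53} is set, the mapping used by the
#' exclusive-dangle both-sides case).  Dangling positions outside
#' \code{[1, n]} contribute exactly 0.
#'
#' @param seq RNA sequence.
#' @param params Energy parameters.
#' @param kind One of \code{"d5"}, \code{"d3"}, \code{"d53"}.
#' @param pair Integer vector \code{c(p, q)}: the pair the base(s) dangle
#'   on, seen from the loop that contains the dangle.
#' @param dangling Dangling position(s): one position for d5/d3, two (5'
#'   then 3') for d53; defaults to the positions adjacent to the pair.
#' @param context \code{"exterior"} or \code{"multiloop"}: which mismatch
#'   table the both-sides term reads.
#' @param sum53 Use dangle5+dangle3 instead of the mismatch table for d53.
#' @return Integer energy in dekacal/mol.
#' @examples
#' dangle_terms("GGGAAAACCCC", kind = "d3", pair = c(1, 10))
#' @export
dangle_terms <- function(seq, params = NULL, kind = c("d5", "d3", "d53"),
                         pair, dangling = NULL,
                         context = c("exterior", "multiloop"),
                         sum53 = FALSE) {
  kind <- match.arg(kind)
  context <- match.arg(context)
  params <- as_params(params)
  s <- normalize_sequence(seq)
  n <- nchar(s)
  codes <- c(seq_codes(s))
  base_at <- function(pos) {
    if (is.null(pos) || is.na(pos) || pos < 1 || pos > n) 0L else codes[pos]
  }
  p <- pair[1]; q <- pair[2]
  t <- pair_type(substr(s, p, p), substr(s, q, q))
  if (is.na(t)) stop("pair ", p, ".", q, " is not canonical")
  ti <- match(t, c("CG", "GC", "GU", "UG", "AU", "UA"))
  look <- function(tab, b) {
    if (b == 0L) return(0L)  # off-sequence: contributes 0
    params[[tab]][(ti - 1L) * 5L + b + 1L]
  }
  look2 <- function(tab, b5, b3) {
    if (b5 == 0L && b3 == 0L) return(0L)
    if (b5 == 0L) return(look("dangle3", b3))
    if (b3 == 0L) return(look("dangle5", b5))
    params[[tab]][((ti - 1L) * 5L + b5) * 5L + b3 + 1L]
  }
  if (kind == "d5") {
    pos <- if (is.null(dangling)) p - 1L else dangling[1]
    look("dangle5", base_at(pos))
  } else if (kind == "d3") {
    pos <- if (is.null(dangling)) q + 1L else dangling[1]
    look("dangle3", base_at(pos))
  } else {
    pos5 <- if (is.null(dangling)) p - 1L else dangling[1]
    pos3 <- if (is.null(dangling)) q + 1L else dangling[2]
    b5 <- base_at(pos5); b3 <- base_at(pos3)
    if (sum53) return(look("dangle5", b5) + look("dangle3", b3))
    tab <- if (context == "exterior") "mismatch_exterior" else "mismatch_multi"
    look2(tab, b5, b3)
  }
}

#' Evaluate the free energy of a fixed structure
#'
#' Loop-decomposition energy of a secondary structure: the sum of its
#' hairpin, interior/stack, multiloop (a + b per branch + c per unpaired
#' base) and external-loop terms, with dangling-end contributions according
#' to the selected model.  Under the exclusive-dangle model the dangle
#' assignment within each loop is optimized exactly, subject to every
#' unpaired base serving at most one adjacent stem end.
#'
#' @param seq RNA sequence.
#' @param structure Dot-bracket string or partner table.
#' @param model Dangle model: \code{"d0"} (no dangles), \code{"d1"}
#'   (exclusive) or \code{"d2"} (always).
#' @param params Energy parameters.
#' @return Energy in kcal/mol.
#' @examples
#' evaluate_structure("GGGAAAACCCC", "(((....))).", model = "d1")  # -2.9
#' @export
evaluate_structure <- function(seq, structure, model = c("d2", "d0", "d1"),
                               params = NULL) {
  model <- match.arg(model)
  params <- as_params(params)
  s <- normalize_sequence(seq)
  n <- nchar(s)
  pt <- if (is.character(structure)) db_to_pairs(structure)
        else as.integer(structure)
  validate_structure(pt, n, m = params$m)
  e <- cpp_eval_structure(seq_codes(s), s, pt,
                          match(model, c("d0", "d1", "d2")) - 1L,
                          unclass(params), d53_sum = d53_uses_sum())
  if (e >= energy_inf() / 2) stop("structure contains a forbidden loop")
  e / 100
}

# table mapping of the exclusive-dangle both-sides case; fixed package-wide
d53_uses_sum <- function() FALSE
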