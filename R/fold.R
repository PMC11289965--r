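# Main user interface: minimum free energy folding of an RNA sequence,
# returning a classed result with print / summary / plot methods.

#' Fold an RNA sequence by free energy minimization
#'
#' Predicts the pseudoknot-free secondary structure with minimum free
#' energy under the Turner 2004 nearest-neighbor model.  The default engine
#' is the sparsified dynamic program (candidate lists, O(n) rolling energy
#' storage, trace arrows with garbage collection); \code{engine = "dense"}
#' runs the conventional Zuker-style algorithm over full matrices, which
#' serves as the package's internal correctness oracle.  Both engines
#' return bit-identical energies.
#'
#' @param seq RNA sequence (A/C/G/U, case-insensitive, T read as U).
#' @param model Dangle model: \code{"d2"} (always dangle, default),
#'   \code{"d0"} (no dangles) or \code{"d1"} (exclusive dangles: every
#'   unpaired base stacks on at most one adjacent helix end, and the
#'   recursion minimizes over the no/5'/3'/both-sides cases).
#' @param strategy Dangle-direction recovery strategy used by the sparse
#'   traceback under the exclusive model: \code{"standard"} stores
#'   bit-encoded context energies in each candidate, \code{"trace"} keeps a
#'   dedicated ed-trace-arrow per candidate, \code{"triplet"} stores
#'   un-dangled inner energies and re-adds dangle terms during traceback.
#' @param engine \code{"sparse"} (default) or \code{"dense"}.
#' @param constraints Optional hard constraints: a string over
#'   \code{. x ( )} or an object from [parse_constraints()] /
#'   [random_constraints()].  Forced pairs must appear in the result;
#'   forced-unpaired bases never pair.
#' @param params Energy parameters; default the bundled Turner 2004 set.
#' @param keep_matrices Also return the dynamic programming matrices
#'   (dense engine: all of W, Wp, V, Vd, WM, WMp, WM2, WMd; sparse engine:
#'   full mirrors of the rolling rows, for diagnostics/testing only).
#' @return An object of class \code{rna_fold}: list with \code{seq},
#'   \code{structure} (dot-bracket), \code{pt} (partner table), \code{mfe}
#'   (kcal/mol), \code{model}, \code{engine}, \code{strategy},
#'   \code{constraints}, and for the sparse engine \code{stats} (candidate
#'   count Z and per-column counts, trace-arrow peak/live/removed counts,
#'   ed-trace-arrow count, per-candidate payload bytes, peak dense-array
#'   cells) plus \code{candidates} (one row per candidate span).
#' @examples
#' f <- fold_rna("GGGAAAACCCC", model = "d1")
#' f$mfe         # -2.9
#' f$structure   # "(((....)))."
#' @export
fold_rna <- function(seq, model = c("d2", "d0", "d1"),
                     strategy = c("standard", "trace", "triplet"),
                     engine = c("sparse", "dense"),
                     constraints = NULL, params = NULL,
                     keep_matrices = FALSE) {
  model <- match.arg(model)
  strategy <- match.arg(strategy)
  engine <- match.arg(engine)
  params <- as_params(params)
  s <- normalize_sequence(seq)
  n <- nchar(s)
  cons <- as_constraint_partner(constraints, s)
  midx <- match(model, c("d0", "d1", "d2")) - 1L
  sidx <- match(strategy, c("trace", "standard", "triplet")) - 1L

  if (engine == "dense") {
    raw <- cpp_fold_dense(seq_codes(s), s, midx, unclass(params), cons,
                          keep_matrices, d53_uses_sum(), TRUE)
  } else {
    raw <- cpp_fold_sparse(seq_codes(s), s, midx, sidx, unclass(params),
                           cons, d53_uses_sum(), keep_matrices, TRUE)
  }
  if (raw$mfe >= energy_inf() / 2)
    stop("no admissible structure under the given constraints")
  pt <- if (!is.null(raw$pt)) raw$pt else integer(n)
  out <- list(
    seq = s, n = n,
    structure = pairs_to_db(pt), pt = pt,
    mfe = raw$mfe / 100,
    model = model, engine = engine,
    strategy = if (engine == "sparse") strategy else NA_character_,
    constraints = if (is.null(constraints)) NULL
                  else if (is.character(constraints))
                    parse_constraints(constraints, s) else constraints,
    stats = raw$stats, candidates = raw$candidates,
    matrices = raw$matrices)
  class(out) <- "rna_fold"
  out
}

#' Dense-engine folding with full matrices
#'
#' Convenience wrapper around [fold_rna()] with \code{engine = "dense"} and
#' \code{keep_matrices = TRUE}; the returned \code{matrices} element holds
#' the complete W, Wp, V, Vd, WM, WMp, WM2 and WMd tables (dekacal/mol,
#' upper triangle; \code{Vd}/\code{WMd} are the dangle-adjusted stem
#' energies in external-loop and multiloop context).
#'
#' @inheritParams fold_rna
#' @return An \code{rna_fold} object with a \code{matrices} element.
#' @export
fold_dense <- function(seq, model = c("d2", "d0", "d1"), constraints = NULL,
                       params = NULL) {
  fold_rna(seq, model = model, engine = "dense", constraints = constraints,
           params = params, keep_matrices = TRUE)
}

#' @export
print.rna_fold <- function(x, ...) {
  cat(x$seq, "\n", sep = "")
  cat(x$structure, sprintf(" (%.2f)\n", x$mfe), sep = "")
  invisible(x)
}

#' @export
summary.rna_fold <- function(object, ...) {
  x <- object
  cat("RNA MFE fold (", x$engine, " engine, ", x$model, " dangle model",
      if (!is.na(x$strategy)) paste0(", ", x$strategy, " strategy"), ")\n",
      sep = "")
  cat("  length: ", x$n, "   base pairs: ", sum(x$pt > 0) / 2, "\n", sep = "")
  cat("  MFE: ", sprintf("%.2f kcal/mol", x$mfe), "\n", sep = "")
  if (!is.null(x$constraints))
    cat("  constraints: ", x$constraints$text, "\n", sep = "")
  if (!is.null(x$stats)) {
    s <- x$stats
    cat(sprintf("  candidates Z = %d (%.4f of n(n-1)/2)\n", as.integer(s$Z),
                s$z_ratio))
    cat(sprintf("  trace arrows: peak %d, live %d, removed %d; ed arrows %d\n",
                as.integer(s$trace_arrows_peak),
                as.integer(s$trace_arrows_live),
                as.integer(s$trace_arrows_removed),
                as.integer(s$ed_trace_arrows)))
    cat(sprintf("  rolling storage: %d cells (%.1f per base)\n",
                as.integer(s$peak_dense_cells), s$peak_dense_cells / x$n))
  }
  invisible(x)
}

#' Arc diagram of a folded structure
#'
#' Draws the sequence on a horizontal line with one arc per base pair;
#' forced constraint pairs, when present, are highlighted.
#'
#' @param x An \code{rna_fold} object.
#' @param ... Further arguments passed to \code{plot}.
#' @return Invisibly, \code{x}.
#' @export
plot.rna_fold <- function(x, ...) {
  n <- x$n
  op <- which(x$pt > seq_len(n))
  hmax <- if (length(op)) max((x$pt[op] - op) / 2) else 1
  graphics::plot(NULL, xlim = c(1, n), ylim = c(-0.5, hmax * 1.05),
                 axes = FALSE, xlab = "position", ylab = "",
                 main = sprintf("MFE %.2f kcal/mol", x$mfe), ...)
  graphics::axis(1)
  graphics::segments(1, 0, n, 0)
  forced <- if (!is.null(x$constraints)) x$constraints$partner else integer(n)
  for (i in op) {
    j <- x$pt[i]
    r <- (j - i) / 2
    theta <- seq(0, pi, length.out = 48)
    col <- if (length(forced) && forced[i] == j) "firebrick" else "grey30"
    graphics::lines((i + j) / 2 + r * cos(theta), r * sin(theta), col = col)
  }
  if (n <= 60)
    graphics::text(seq_len(n), -0.4, strsplit(x$seq, "")[[1]], cex = 0.6)
  invisible(x)
}
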