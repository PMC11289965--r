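# Base-pair prediction accuracy: sensitivity, positive predictive value and
# their harmonic mean (F-measure), counted over exact pair identity.

#' Compare a predicted structure against a reference
#'
#' Counts base pairs by exact identity: TP are pairs present in both
#' structures, FP are predicted pairs absent from the reference, FN are
#' reference pairs missed by the prediction.  Sensitivity = TP/(TP+FN),
#' PPV = TP/(TP+FP), F = 2*PPV*Sens/(PPV+Sens).  Ratios with a zero
#' denominator are reported as 0.
#'
#' @param predicted,reference Dot-bracket strings or partner tables of equal
#'   length.
#' @return List with \code{tp}, \code{fp}, \code{fn}, \code{sensitivity},
#'   \code{ppv}, \code{f_measure}.
#' @examples
#' compare_structures("(((....))).", "(((.....)))")
#' @export
compare_structures <- function(predicted, reference) {
  as_pt <- function(x) if (is.character(x)) db_to_pairs(x) else as.integer(x)
  p <- as_pt(predicted)
  r <- as_pt(reference)
  if (length(p) != length(r))
    stop("predicted and reference structures have different lengths")
  pp <- which(p > seq_along(p))
  rp <- which(r > seq_along(r))
  tp <- sum(p[pp] == r[pp] & r[pp] > 0)
  fp <- length(pp) - tp
  fn <- length(rp) - tp
  ratio <- function(a, b) if (b == 0) 0 else a / b
  sens <- ratio(tp, tp + fn)
  ppv <- ratio(tp, tp + fp)
  f <- if (ppv + sens == 0) 0 else 2 * ppv * sens / (ppv + sens)
  list(tp = tp, fp = fp, fn = fn,
       sensitivity = sens, ppv = ppv, f_measure = f)
}
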