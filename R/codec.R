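# Bit packing of dynamic-programming energies with a 2-bit dangle code in
# the low bits; used by the "standard" traceback strategy to carry dangle
# directions inside candidate energy fields.

#' Encode an energy value with a dangle code
#'
#' Packs an integer energy and a 2-bit dangle code into one integer as
#' \code{enc = 4 * value + dangle} (two's-complement arithmetic, equivalent
#' to \code{(value << 2) | dangle}).  Codes: 0 = no dangle, 1 = 5' dangle,
#' 2 = 3' dangle, 3 = both sides.
#'
#' @param value Integer energy (dekacal/mol); must satisfy
#'   \code{abs(value) < 2^28}.
#' @param dangle Integer code in 0..3.
#' @return Encoded integer.
#' @examples
#' encode_energy(-24, 2)   # -94
#' decode_energy(-94)
#' @export
encode_energy <- function(value, dangle) {
  cpp_encode_energy(as.integer(value), as.integer(dangle))
}

#' @rdname encode_energy
#' @param enc Encoded integer produced by \code{encode_energy}.
#' @return \code{decode_energy}: named integer vector with elements
#'   \code{value} and \code{dangle}; the round trip is exact for all
#'   representable energies, negative values included.
#' @export
decode_energy <- function(enc) {
  cpp_decode_energy(as.integer(enc))
}

#' Branch-free interior-loop guard
#'
#' Returns \code{e} when both region flags are 1 and an effectively
#' infinite value otherwise, computed without conditional branching:
#' \code{e + (((left_ok - 1) | (right_ok - 1)) & inf)}.  With flags in
#' \{0, 1\}, \code{left_ok - 1} is 0 or -1 (all bits set), so the mask is 0
#' exactly when both flags are 1.
#'
#' @param left_ok,right_ok Integer flags in \{0, 1\}: is the region between
#'   the opening bases (resp. closing bases) of an interior loop free of
#'   forced-paired positions?
#' @param e Finite energy value.
#' @param inf The infinity sentinel to mask in (default the package's
#'   internal value).
#' @return \code{e} if both flags are 1, otherwise \code{e + inf}, which
#'   exceeds every reachable finite energy.
#' @examples
#' masked_energy(1, 1, -33)   # -33
#' masked_energy(0, 1, -33)   # effectively infinite
#' @export
masked_energy <- function(left_ok, right_ok, e, inf = energy_inf()) {
  stopifnot(left_ok %in% c(0L, 1L), right_ok %in% c(0L, 1L))
  cpp_masked_energy(as.integer(left_ok), as.integer(right_ok),
                    as.integer(e), as.integer(inf))
}

#' Internal infinity sentinel
#'
#' The integer used for forbidden states in the dynamic programming, chosen
#' so that twice its value is still far below the 32-bit overflow bound.
#' Any energy above half this value is treated as infinite.
#' @return Integer scalar.
#' @export
energy_inf <- function() 10000000L
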