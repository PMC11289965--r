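// Bit packing of energy values with a 2-bit dangle code in the low bits.
// The contract is arithmetic (enc = 4*V + d; d = enc mod 4 with non-negative
// remainder) so that it is independent of shift-operator semantics on
// negative integers; on two's-complement hardware it coincides with
// (V << 2) | d and an arithmetic right shift.
#include "energy.h"

using namespace Rcpp;

// [[Rcpp::export]]
int cpp_encode_energy(int v, int dangle) {
  if (dangle < 0 || dangle > 3) stop("dangle code must be in 0..3");
  if (v >= (1 << 28) || v <= -(1 << 28))
    stop("energy value %d outside the representable range", v);
  return 4 * v + dangle;
}

// [[Rcpp::export]]
IntegerVector cpp_decode_energy(int enc) {
  int d = enc % 4;
  if (d < 0) d += 4;
  int v = (enc - d) / 4;
  return IntegerVector::create(_["value"] = v, _["dangle"] = d);
}

// [[Rcpp::export]]
int cpp_masked_energy(int left_ok, int right_ok, int e, int inf) {
  return e + (((left_ok - 1) | (right_ok - 1)) & inf);
}

// branching reference logic of the original interior-loop guard
// [[Rcpp::export]]
int cpp_branching_energy(int left_ok, int right_ok, int e, int inf) {
  if (left_ok == 1 && right_ok == 1) return e;
  return e + inf;
}
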