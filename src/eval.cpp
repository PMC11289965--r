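// Loop-decomposition evaluation of a fixed secondary structure: the energy
// of a structure is the sum of its hairpin, interior/stack, multiloop and
// external-loop energies.  Under the exclusive-dangle model the dangle
// assignment inside each external loop / multiloop is itself a small
// optimization (each unpaired base may serve at most one adjacent stem end);
// it is solved exactly by a left-to-right scan over the loop's stems with a
// one-bit carry that records whether the base shared between two stems one
// apart has been consumed.
#include "energy.h"

using namespace Rcpp;

namespace {

struct Eval {
  Ctx ctx;
  std::vector<int> pt;

  // stems: list of (i, j) spans appearing in one loop, left to right.
  // closing: closing pair of a multiloop (0,0 for the external loop).
  // Under d0/d2 every stem contributes independently; under d1 run the
  // exclusive-assignment DP.
  int loop_stems(const std::vector<std::pair<int, int>>& stems,
                 int ci, int cj) {
    bool ml = ci > 0;
    int total = 0;
    if (ctx.model != 1) {
      for (auto& s : stems) {
        int t = ctx.pt(s.first, s.second);
        total += ctx.tau(t);
        if (ml) total += ctx.P.ml_intern;
        if (ctx.model == 2) {
          int b5 = (ml || s.first > 1) ? ctx.S[s.first - 1] : -1;
          int b3 = (ml || s.second < ctx.n) ? ctx.S[s.second + 1] : -1;
          total += ctx.stem_dangle(t, b5, b3, ml, false);
        }
      }
      if (ml) {
        int rt = ctx.pt(cj, ci);
        total += ctx.P.ml_closing + ctx.P.ml_intern + ctx.tau(rt);
        if (ctx.model == 2)
          total += ctx.stem_dangle(rt, ctx.S[cj - 1], ctx.S[ci + 1], true,
                                   false);
      }
      return total;
    }
    // exclusive dangle: condition on the closing stem's case, then scan
    int k = stems.size();
    int best = E_INF;
    int ncl = ml ? 4 : 1;
    for (int dc = 0; dc < ncl; ++dc) {
      int closing = 0;
      bool cl_use5 = false, cl_use3 = false;  // bases ci+1 / cj-1 from inside
      if (ml) {
        int rt = ctx.pt(cj, ci);
        closing = ctx.P.ml_closing + ctx.P.ml_intern + ctx.tau(rt);
        // from inside the loop, base ci+1 is 3' and base cj-1 is 5' of the
        // closing pair
        cl_use3 = (dc == 1 || dc == 3);
        cl_use5 = (dc == 2 || dc == 3);
        if (cl_use3 && (k == 0 || pt[ci + 1])) continue;  // base paired
        if (cl_use5 && (k == 0 || pt[cj - 1])) continue;
        if (dc == 1) closing += ctx.P.d3[rt][ctx.S[ci + 1]];
        if (dc == 2) closing += ctx.P.d5[rt][ctx.S[cj - 1]];
        if (dc == 3)
          closing += ctx.stem_dangle(rt, ctx.S[cj - 1], ctx.S[ci + 1], true,
                                     ctx.P.d53_sum);
      }
      // dp over stems; carry = previous stem (or closing) consumed the base
      // immediately left of the next stem when the gap is a single base
      int dp[2] = {closing, E_INF};
      // initial carry: closing consumed base ci+1 and first stem starts at
      // ci+2 (external loop: nothing to carry)
      if (ml && cl_use3 && k > 0 && stems[0].first == ci + 2) {
        dp[1] = dp[0]; dp[0] = E_INF;
      }
      for (int t = 0; t < k; ++t) {
        int i = stems[t].first, j = stems[t].second;
        int left = i - 1, right = j + 1;
        bool left_exists = ml ? (left > ci) : (left >= 1);
        bool right_exists = ml ? (right < cj) : (right <= ctx.n);
        bool left_un = left_exists && !pt[left];
        bool right_un = right_exists && !pt[right];
        // does the NEXT consumer share our right base? (gap of one)
        int next_left = (t + 1 < k) ? stems[t + 1].first - 1
                                    : (ml ? cj - 1 : -100);
        bool share_right = right_un && (right == next_left);
        int ndp[2] = {E_INF, E_INF};
        for (int carry = 0; carry < 2; ++carry) {
          if (dp[carry] >= E_BAR) continue;
          bool can5 = left_un && !carry;
          for (int d = 0; d < 4; ++d) {
            if ((d == 1 || d == 3) && !can5) continue;
            if ((d == 2 || d == 3) && !right_un) continue;
            int tt = ctx.pt(i, j);
            int e = dp[carry] + ctx.tau(tt) + (ml ? ctx.P.ml_intern : 0);
            if (d == 1) e += ctx.P.d5[tt][ctx.S[left]];
            if (d == 2) e += ctx.P.d3[tt][ctx.S[right]];
            if (d == 3)
              e += ctx.stem_dangle(tt, ctx.S[left], ctx.S[right], ml,
                                   ctx.P.d53_sum);
            int used_right = (d == 2 || d == 3) ? 1 : 0;
            int nc = share_right ? used_right : 0;
            if (e < ndp[nc]) ndp[nc] = e;
          }
        }
        dp[0] = ndp[0]; dp[1] = ndp[1];
      }
      // carry into the closing pair's 5' inner base (cj-1): if the closing
      // stem consumed it, the last branch must not have (dp[1] with
      // share_right pointing at cj-1 means the branch consumed it)
      int e = std::min(dp[0], cl_use5 ? E_INF : dp[1]);
      if (cl_use5 && dp[0] < E_BAR) e = dp[0];
      if (e < best) best = e;
    }
    return best >= E_BAR ? E_INF : best;
  }

  int run() {
    int n = ctx.n;
    int total = 0;
    // external loop
    std::vector<std::pair<int, int>> ext;
    for (int i = 1; i <= n; ++i)
      if (pt[i] > i) { ext.push_back({i, pt[i]}); i = pt[i]; }
    total = eadd(total, loop_stems(ext, 0, 0));
    // loops closed by each pair
    for (int i = 1; i <= n; ++i) {
      int j = pt[i];
      if (j <= i) continue;
      std::vector<std::pair<int, int>> inner;
      int unpaired = 0;
      for (int k = i + 1; k < j; ++k) {
        if (pt[k] > k) { inner.push_back({k, pt[k]}); k = pt[k]; }
        else ++unpaired;
      }
      if (inner.empty()) {
        total = eadd(total, ctx.e_hairpin(i, j));
      } else if (inner.size() == 1) {
        int e = ctx.e_intloop(i, j, inner[0].first, inner[0].second);
        total = eadd(total, e);
      } else {
        int e = ctx.P.ml_base * unpaired;
        e = eadd(e, loop_stems(inner, i, j));
        total = eadd(total, e);
      }
    }
    return total;
  }
};

}  // namespace

// [[Rcpp::export]]
int cpp_eval_structure(IntegerVector seq, std::string chars,
                       IntegerVector pairtab, int model, List par,
                       bool d53_sum) {
  Eval E;
  ctx_init(E.ctx, seq, chars, model, par, IntegerVector(0), d53_sum);
  E.pt.assign(E.ctx.n + 2, 0);
  for (int i = 1; i <= E.ctx.n; ++i) E.pt[i] = pairtab[i - 1];
  return E.run();
}
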