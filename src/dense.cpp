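// Dense O(n^3)-time, O(n^2)-space energy minimization over pseudoknot-free
// structures, with all three dangle models and hard constraints.  This
// engine materializes every matrix and serves as the correctness oracle for
// the sparse engine; clarity is preferred over speed throughout.
#include "energy.h"

#include <array>

using namespace Rcpp;

namespace {

struct Dense {
  Ctx ctx;
  int n;
  std::vector<int> W, Wp, V, Vd, WM, WMp, WM2, WMd;

  int& at(std::vector<int>& M_, int i, int j) { return M_[i * (n + 2) + j]; }
  int get(const std::vector<int>& M_, int i, int j) const {
    return M_[i * (n + 2) + j];
  }
  int Wv(int i, int j) const { return j < i ? 0 : get(W, i, j); }

  void fill() {
    n = ctx.n;
    size_t sz = (size_t)(n + 2) * (n + 2);
    W.assign(sz, 0); Wp.assign(sz, E_INF); V.assign(sz, E_INF);
    Vd.assign(sz, E_INF); WM.assign(sz, E_INF); WMp.assign(sz, E_INF);
    WM2.assign(sz, E_INF); WMd.assign(sz, E_INF);
    const Params& P = ctx.P;

    for (int i = n; i >= 1; --i) {
      at(W, i, i) = ctx.C.up_ok(i) ? 0 : E_INF;
      for (int j = i + 1; j <= n; ++j) {
        // --- V ---
        int v = E_INF;
        if (j - i > P.m && ctx.pt(i, j) && ctx.C.pair_ok(i, j)) {
          if (ctx.C.region_ok(i + 1, j - 1)) v = ctx.e_hairpin(i, j);
          // interior loops, p ascending then q ascending
          int pmax = std::min(i + P.M + 1, j - P.m - 2);
          for (int p = i + 1; p <= pmax; ++p) {
            int lok = ctx.C.region_ok(i + 1, p - 1) ? 1 : 0;
            int qmin = std::max(p + P.m + 1, j - 1 - (P.M - (p - i - 1)));
            for (int q = qmin; q <= j - 1; ++q) {
              int vin = get(V, p, q);
              if (vin >= E_BAR) continue;
              int rok = ctx.C.region_ok(q + 1, j - 1) ? 1 : 0;
              int e = il_guard(lok, rok, eadd(ctx.e_intloop(i, j, p, q), vin));
              if (e < v) v = e;
            }
          }
          // multiloop closing
          for (int d = 0; d < ctx.n_ml_cases(); ++d) {
            Ctx::MLClose mc = ctx.ml_close_case(i, j, d);
            if (!mc.valid || mc.b2 - mc.a2 < 2 * P.m + 3) continue;
            int e = eadd(get(WM2, mc.a2, mc.b2), mc.extra);
            if (e < v) v = e;
          }
        }
        at(V, i, j) = v;

        // --- context stem energies (dangle-model dependent) ---
        Ctx::StemE ext = ctx.ctx_stem(i, j, v, get(V, i + 1, j),
                                      get(V, i, j - 1), get(V, i + 1, j - 1),
                                      false);
        Ctx::StemE mls = ctx.ctx_stem(i, j, v, get(V, i + 1, j),
                                      get(V, i, j - 1), get(V, i + 1, j - 1),
                                      true);
        at(Vd, i, j) = ext.e;
        at(WMd, i, j) = mls.e;

        // --- WM2 ---
        // finite only from j - i = 2m+3 on: two minimal stems need
        // 2(m+2) positions
        int wm2 = E_INF;
        if (j - i >= 2 * P.m + 3) {
          for (int k = i + 1; k < j; ++k) {
            int e = eadd(get(WM, i, k - 1), get(WM, k, j));
            if (e < wm2) wm2 = e;
          }
        }
        at(WM2, i, j) = wm2;

        // --- WM ---
        int wmp = E_INF;
        if (ctx.C.up_ok(i)) wmp = eadd(get(WM, i + 1, j), P.ml_base);
        if (ctx.C.up_ok(j)) {
          int e = eadd(get(WM, i, j - 1), P.ml_base);
          if (e < wmp) wmp = e;
        }
        if (wm2 < wmp) wmp = wm2;
        at(WMp, i, j) = wmp;
        at(WM, i, j) = std::min(wmp, mls.e);

        // --- W ---
        int wp = ctx.C.up_ok(j) ? Wv(i, j - 1) : E_INF;
        for (int k = i + 1; k < j; ++k) {
          int e = eadd(Wv(i, k - 1), get(W, k, j));
          if (e < wp) wp = e;
        }
        at(Wp, i, j) = wp;
        at(W, i, j) = std::min(wp, ext.e);
      }
    }
  }

  // --- traceback -------------------------------------------------------
  // case evaluation follows the textual order of the recursions; the first
  // achiever is taken, which makes the trace deterministic
  std::vector<int> ptab;

  void err(const char* what, int i, int j) {
    stop("dense traceback: no %s case reproduces cell (%d,%d)", what, i, j);
  }

  void trace_stem(int i, int j, bool ml, int target,
                  std::vector<std::array<int, 4>>& stack);

  void trace() {
    ptab.assign(n + 1, 0);
    // tasks: {kind 0=W 1=V 2=WM 3=WM2, i, j, target}
    std::vector<std::array<int, 4>> stack;
    stack.push_back({0, 1, n, Wv(1, n)});
    while (!stack.empty()) {
      auto t = stack.back();
      stack.pop_back();
      int kind = t[0], i = t[1], j = t[2], target = t[3];
      if (kind == 0) {  // W
        while (j > i) {
          if (target >= E_BAR) err("W(INF)", i, j);
          if (ctx.C.up_ok(j) && target == Wv(i, j - 1)) { --j; target = Wv(i, j); continue; }
          int k = -1;
          for (int kk = i + 1; kk < j; ++kk)
            if (target == eadd(Wv(i, kk - 1), get(W, kk, j))) { k = kk; break; }
          if (k > 0) {
            stack.push_back({0, k, j, get(W, k, j)});
            j = k - 1; target = Wv(i, j); continue;
          }
          if (target == get(Vd, i, j)) { trace_stem(i, j, false, target, stack); break; }
          err("W", i, j);
        }
      } else if (kind == 1) {  // V; pair i.j is part of the structure
        ptab[i] = j; ptab[j] = i;
        int v = target;
        if (ctx.C.region_ok(i + 1, j - 1) && v == ctx.e_hairpin(i, j)) continue;
        bool done = false;
        int pmax = std::min(i + ctx.P.M + 1, j - ctx.P.m - 2);
        for (int p = i + 1; p <= pmax && !done; ++p) {
          if (!ctx.C.region_ok(i + 1, p - 1)) continue;
          int qmin = std::max(p + ctx.P.m + 1, j - 1 - (ctx.P.M - (p - i - 1)));
          for (int q = qmin; q <= j - 1; ++q) {
            if (!ctx.C.region_ok(q + 1, j - 1)) continue;
            if (v == eadd(ctx.e_intloop(i, j, p, q), get(V, p, q))) {
              stack.push_back({1, p, q, get(V, p, q)});
              done = true; break;
            }
          }
        }
        if (done) continue;
        for (int d = 0; d < ctx.n_ml_cases() && !done; ++d) {
          Ctx::MLClose mc = ctx.ml_close_case(i, j, d);
          if (!mc.valid || mc.b2 - mc.a2 < 2 * ctx.P.m + 3) continue;
          if (v == eadd(get(WM2, mc.a2, mc.b2), mc.extra)) {
            stack.push_back({3, mc.a2, mc.b2, get(WM2, mc.a2, mc.b2)});
            done = true;
          }
        }
        if (!done) err("V", i, j);
      } else if (kind == 2) {  // WM
        if (ctx.C.up_ok(i) && target == eadd(get(WM, i + 1, j), ctx.P.ml_base)) {
          stack.push_back({2, i + 1, j, get(WM, i + 1, j)});
        } else if (ctx.C.up_ok(j) &&
                   target == eadd(get(WM, i, j - 1), ctx.P.ml_base)) {
          stack.push_back({2, i, j - 1, get(WM, i, j - 1)});
        } else if (target == get(WM2, i, j)) {
          stack.push_back({3, i, j, target});
        } else if (target == get(WMd, i, j)) {
          trace_stem(i, j, true, target, stack);
        } else err("WM", i, j);
      } else {  // WM2
        bool done = false;
        for (int k = i + 1; k < j && !done; ++k) {
          if (target == eadd(get(WM, i, k - 1), get(WM, k, j))) {
            stack.push_back({2, i, k - 1, get(WM, i, k - 1)});
            stack.push_back({2, k, j, get(WM, k, j)});
            done = true;
          }
        }
        if (!done) err("WM2", i, j);
      }
    }
  }
};

void Dense::trace_stem(int i, int j, bool ml, int target,
                       std::vector<std::array<int, 4>>& stack) {
  // resolve the dangle case of a context stem in printed order
  for (int d = 0; d < (ctx.model == 1 ? 4 : 1); ++d) {
    int p, q;
    ctx.stem_inner(i, j, d, p, q);
    if (ctx.model == 1) {
      if ((d == 1 || d == 3) && !ctx.C.up_ok(i)) continue;
      if ((d == 2 || d == 3) && !ctx.C.up_ok(j)) continue;
    }
    if (q - p <= ctx.P.m || !ctx.pt(p, q)) continue;
    int vin = get(V, p, q);
    if (vin >= E_BAR) continue;
    if (target == eadd(vin, ctx.stem_case_terms(i, j, d, ml))) {
      stack.push_back({1, p, q, vin});
      return;
    }
  }
  err("stem", i, j);
}

}  // namespace

// [[Rcpp::export]]
List cpp_fold_dense(IntegerVector seq, std::string chars, int model,
                    List par, IntegerVector cons, bool keep_matrices,
                    bool d53_sum, bool do_trace) {
  Dense D;
  ctx_init(D.ctx, seq, chars, model, par, cons, d53_sum);
  D.fill();
  int n = D.n;
  int mfe = D.Wv(1, n);

  List out = List::create(
      _["mfe"] = mfe,
      _["n"] = n);
  if (do_trace && mfe < E_BAR) {
    D.trace();
    out["pt"] = IntegerVector(D.ptab.begin() + 1, D.ptab.end());
  }
  if (keep_matrices) {
    auto mat = [&](const std::vector<int>& M_) {
      IntegerMatrix R(n, n);
      for (int i = 1; i <= n; ++i)
        for (int j = 1; j <= n; ++j)
          R(i - 1, j - 1) = (j >= i) ? M_[i * (n + 2) + j] : NA_INTEGER;
      return R;
    };
    out["matrices"] = List::create(
        _["W"] = mat(D.W), _["Wp"] = mat(D.Wp), _["V"] = mat(D.V),
        _["Vd"] = mat(D.Vd), _["WM"] = mat(D.WM), _["WMp"] = mat(D.WMp),
        _["WM2"] = mat(D.WM2), _["WMd"] = mat(D.WMd));
  }
  return out;
}

// [[Rcpp::export]]
int cpp_energy_hairpin(IntegerVector seq, std::string chars, int i, int j,
                       List par) {
  Ctx ctx;
  ctx_init(ctx, seq, chars, 0, par, IntegerVector(0), false);
  return ctx.e_hairpin(i, j);
}

// [[Rcpp::export]]
int cpp_energy_interior(IntegerVector seq, std::string chars, int i, int j,
                        int p, int q, List par) {
  Ctx ctx;
  ctx_init(ctx, seq, chars, 0, par, IntegerVector(0), false);
  return ctx.e_intloop(i, j, p, q);
}
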