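// Sparsified MFE folding: time sparsification via candidate lists (only
// spans whose optimal structure is not optimally decomposable are enumerated
// at split points) and space sparsification via rolling O(n) energy rows, a
// bounded V band for the interior-loop window, and trace arrows for the
// interior-loop cases whose trace cannot be recomputed from candidates.
// Dangle handling under the exclusive model extends each candidate with its
// context energies for external loops (W) and multiloops (WM); three
// strategies recover the dangle direction during traceback: dedicated
// ed-trace-arrows, bit-encoded dangle codes, or re-addition of dangle terms
// to the stored un-dangled inner energy.
#include "energy.h"

#include <algorithm>
#include <array>
#include <unordered_map>

using namespace Rcpp;

namespace {

inline int64_t key(int i, int j) { return ((int64_t)i << 32) | (uint32_t)j; }

struct CandEntry {
  int i, V;
  int Wd, WMd;        // context stem energies (external / multiloop)
  uint8_t dW, dWM;    // dangle cases under the exclusive model
  int undW, undWM;    // V of the shifted inner pair per context (triplet)
};

struct Arrow { int p, q, V; };
struct EdArrow { uint8_t dW, dWM; };

constexpr int STRAT_TRACE = 0, STRAT_STANDARD = 1, STRAT_TRIPLET = 2;

struct Sparse {
  Ctx ctx;
  int n, strategy;
  bool debug;

  std::vector<std::vector<CandEntry>> cand;  // per column j, i descending
  std::unordered_map<int64_t, Arrow> arrows;
  std::unordered_map<int64_t, EdArrow> edarrows;
  std::unordered_map<int64_t, int> inbound;
  std::vector<std::vector<int64_t>> arrows_by_row;

  // rolling storage
  std::vector<std::vector<int>> Vband;  // M+2 rows
  std::vector<int> Wr, WMr, WM2r, WM2r1, WM2r2;

  // stats
  long Z = 0;
  size_t t_peak = 0;
  long arrows_removed = 0;
  std::vector<int> cand_per_col;

  // debug mirrors (n^2; test use only)
  std::vector<int> dbgW, dbgWp, dbgV, dbgWM, dbgWMp, dbgWM2;

  int mfe = 0;
  std::vector<int> ptab;

  int band_rows() const { return ctx.P.M + 2; }
  int& Vb(int p, int q) { return Vband[p % band_rows()][q]; }

  const CandEntry* find_cand(int p, int q) const {
    const auto& L = cand[q];
    auto it = std::lower_bound(
        L.begin(), L.end(), p,
        [](const CandEntry& e, int val) { return e.i > val; });
    if (it != L.end() && it->i == p) return &*it;
    return nullptr;
  }

  // context stem energy of a candidate as the forward recursions use it;
  // the standard strategy keeps these bit-encoded and decodes on access
  int entry_Wd(const CandEntry& e) const {
    if (strategy == STRAT_STANDARD && ctx.model == 1) {
      int enc = 4 * e.Wd + e.dW;
      int d = ((enc % 4) + 4) % 4;
      return (enc - d) / 4;
    }
    return e.Wd;
  }
  int entry_WMd(const CandEntry& e) const {
    if (strategy == STRAT_STANDARD && ctx.model == 1) {
      int enc = 4 * e.WMd + e.dWM;
      int d = ((enc % 4) + 4) % 4;
      return (enc - d) / 4;
    }
    return e.WMd;
  }

  // ---- forward fill ----------------------------------------------------

  struct ILRes { int e = E_INF; int p = 0, q = 0; };

  static void better(ILRes& r, int e, int p, int q) {
    if (e < r.e || (e == r.e && e < E_BAR &&
                    (p < r.p || (p == r.p && q < r.q))))
      r = {e, p, q};
  }

  // Interior-loop minimum restricted to candidate inner pairs; the V used
  // is the candidate's stored V payload (not a dangled value).
  ILRes il_cand(int i, int j) {
    ILRes best;
    const Params& P = ctx.P;
    int qlo = std::max(i + P.m + 2, j - 1 - P.M);
    for (int q = qlo; q <= j - 1; ++q) {
      const auto& L = cand[q];
      for (auto it = L.rbegin(); it != L.rend(); ++it) {
        int p = it->i;
        if (p <= i) continue;  // traceback-time lists span all rows
        if (p > i + P.M + 1) break;
        int u = (p - i - 1) + (j - q - 1);
        if (u > P.M || q - p <= P.m) continue;
        int lok = ctx.C.region_ok(i + 1, p - 1) ? 1 : 0;
        int rok = ctx.C.region_ok(q + 1, j - 1) ? 1 : 0;
        int e = il_guard(lok, rok,
                         eadd(ctx.e_intloop(i, j, p, q), it->V));
        better(best, e, p, q);
      }
    }
    if (best.e >= E_BAR) best = ILRes();
    return best;
  }

  // Interior-loop minimum over non-candidate inner pairs; V values come
  // from the rolling band, never from an n x n table.
  ILRes il_noncand(int i, int j) {
    ILRes best;
    const Params& P = ctx.P;
    int pmax = std::min(i + P.M + 1, j - P.m - 2);
    for (int p = i + 1; p <= pmax; ++p) {
      int lok = ctx.C.region_ok(i + 1, p - 1) ? 1 : 0;
      int qmin = std::max(p + P.m + 1, j - 1 - (P.M - (p - i - 1)));
      for (int q = qmin; q <= j - 1; ++q) {
        int vin = Vb(p, q);
        if (vin >= E_BAR || find_cand(p, q)) continue;
        int rok = ctx.C.region_ok(q + 1, j - 1) ? 1 : 0;
        int e = il_guard(lok, rok, eadd(ctx.e_intloop(i, j, p, q), vin));
        better(best, e, p, q);
      }
    }
    if (best.e >= E_BAR) best = ILRes();
    return best;
  }

  bool reachable_cell(int r, int c) const {
    if (find_cand(r, c)) return true;
    if (ctx.model == 1) {
      // shifted stem cases of ed-candidates can enter V(r,c)
      if (find_cand(r - 1, c)) return true;
      if (c + 1 <= n && (find_cand(r, c + 1) || find_cand(r - 1, c + 1)))
        return true;
    }
    auto it = inbound.find(key(r, c));
    return it != inbound.end() && it->second > 0;
  }

  void try_remove(int64_t k) {
    auto it = arrows.find(k);
    if (it == arrows.end()) return;
    int r = (int)(k >> 32), c = (int)(k & 0xffffffff);
    if (reachable_cell(r, c)) return;
    Arrow a = it->second;
    arrows.erase(it);
    ++arrows_removed;
    auto ib = inbound.find(key(a.p, a.q));
    if (ib != inbound.end() && --ib->second == 0) try_remove(key(a.p, a.q));
  }

  void gc_row(int r) {
    if (r < 1 || r > n) return;
    for (int64_t k : arrows_by_row[r]) try_remove(k);
  }

  void fill() {
    n = ctx.n;
    const Params& P = ctx.P;
    const int c = P.ml_base;
    cand.assign(n + 2, {});
    arrows_by_row.assign(n + 2, {});
    cand_per_col.assign(n + 1, 0);
    Vband.assign(band_rows(), std::vector<int>(n + 2, E_INF));
    Wr.assign(n + 2, 0);
    WMr.assign(n + 2, E_INF);
    WM2r.assign(n + 2, E_INF);
    WM2r1.assign(n + 2, E_INF);
    WM2r2.assign(n + 2, E_INF);
    if (debug) {
      size_t sz = (size_t)(n + 2) * (n + 2);
      dbgW.assign(sz, 0); dbgWp.assign(sz, E_INF); dbgV.assign(sz, E_INF);
      dbgWM.assign(sz, E_INF); dbgWMp.assign(sz, E_INF);
      dbgWM2.assign(sz, E_INF);
    }

    for (int i = n; i >= 1; --i) {
      std::swap(WM2r2, WM2r1);
      std::swap(WM2r1, WM2r);
      std::fill(WM2r.begin(), WM2r.end(), E_INF);
      std::fill(Vband[i % band_rows()].begin(),
                Vband[i % band_rows()].end(), E_INF);
      Wr[i] = ctx.C.up_ok(i) ? 0 : E_INF;
      WMr[i] = E_INF;
      auto Wv = [&](int j) { return j < i ? 0 : Wr[j]; };
      auto WMv = [&](int j) { return j < i ? E_INF : WMr[j]; };

      for (int j = i + 1; j <= n; ++j) {
        // ---- V ----
        int v = E_INF;
        int vcase = 0;  // 0 hairpin/none, 1 interior, 2 multiloop
        ILRes ril;
        bool il_noncandidate = false;
        if (j - i > P.m && ctx.pt(i, j) && ctx.C.pair_ok(i, j)) {
          if (ctx.C.region_ok(i + 1, j - 1)) v = ctx.e_hairpin(i, j);
          ILRes rc = il_cand(i, j), rn = il_noncand(i, j);
          il_noncandidate = rn.e < rc.e;
          ril = il_noncandidate ? rn : rc;
          if (ril.e < v) { v = ril.e; vcase = 1; }
          for (int d = 0; d < ctx.n_ml_cases(); ++d) {
            Ctx::MLClose mc = ctx.ml_close_case(i, j, d);
            if (!mc.valid || mc.b2 - mc.a2 < 2 * P.m + 3) continue;
            const std::vector<int>& row = (mc.a2 == i + 1) ? WM2r1 : WM2r2;
            int e = eadd(row[mc.b2], mc.extra);
            if (e < v) { v = e; vcase = 2; }
          }
        }
        Vb(i, j) = v;
        if (vcase == 1 && il_noncandidate) {
          arrows[key(i, j)] = {ril.p, ril.q, Vb(ril.p, ril.q)};
          inbound[key(ril.p, ril.q)]++;
          arrows_by_row[i].push_back(key(i, j));
          if (arrows.size() > t_peak) t_peak = arrows.size();
        }

        // ---- context stems ----
        int Vi1j = Vband[(i + 1) % band_rows()][j];
        int Vij1 = Vb(i, j - 1);
        int Vi1j1 = (j - 1 >= i + 1) ? Vband[(i + 1) % band_rows()][j - 1]
                                     : E_INF;
        Ctx::StemE ext = ctx.ctx_stem(i, j, v, Vi1j, Vij1, Vi1j1, false);
        Ctx::StemE mls = ctx.ctx_stem(i, j, v, Vi1j, Vij1, Vi1j1, true);

        // ---- sparsified W^p, WM2, WM^p ----
        int wp = ctx.C.up_ok(j) ? Wv(j - 1) : E_INF;
        for (const auto& e : cand[j]) {
          int x = eadd(Wv(e.i - 1), entry_Wd(e));
          if (x < wp) wp = x;
        }
        int wm2 = ctx.C.up_ok(j) ? eadd(WM2r[j - 1], c) : E_INF;
        for (const auto& e : cand[j]) {
          int x = eadd(WMv(e.i - 1), entry_WMd(e));
          if (x < wm2) wm2 = x;
        }
        WM2r[j] = wm2;
        int wmp = ctx.C.up_ok(j) ? eadd(WMv(j - 1), c) : E_INF;
        for (const auto& e : cand[j]) {
          if (!ctx.C.region_ok(i, e.i - 1)) continue;
          int x = eadd(c * (e.i - i), entry_WMd(e));
          if (x < wmp) wmp = x;
        }
        if (wm2 < wmp) wmp = wm2;
        Wr[j] = std::min(wp, ext.e);
        WMr[j] = std::min(wmp, mls.e);

        if (debug) {
          size_t off = (size_t)i * (n + 2) + j;
          dbgV[off] = v; dbgW[off] = Wr[j]; dbgWp[off] = wp;
          dbgWM[off] = WMr[j]; dbgWMp[off] = wmp; dbgWM2[off] = wm2;
          dbgW[(size_t)i * (n + 2) + i] = Wr[i];
        }

        // ---- candidate criterion ----
        if (ext.e < wp || mls.e < wmp) {
          CandEntry e;
          e.i = i; e.V = v;
          e.Wd = ext.e; e.WMd = mls.e;
          e.dW = (uint8_t)ext.d; e.dWM = (uint8_t)mls.d;
          // un-dangled payloads: V of the shifted inner pair per context
          e.undW = (ext.d == 0 || ctx.model != 1 || ext.e >= E_BAR)
                       ? v : ext.e - ctx.stem_case_terms(i, j, ext.d, false);
          e.undWM = (mls.d == 0 || ctx.model != 1 || mls.e >= E_BAR)
                        ? v : mls.e - ctx.stem_case_terms(i, j, mls.d, true);
          cand[j].push_back(e);
          ++Z;
          ++cand_per_col[j];
          if (strategy == STRAT_TRACE && ctx.model == 1)
            edarrows[key(i, j)] = {(uint8_t)ext.d, (uint8_t)mls.d};
        }
      }
      gc_row(i + P.M + 1);
    }
    mfe = Wr[n];
  }

  // ---- traceback -------------------------------------------------------

  void err(const char* what, int i, int j) {
    stop("sparse traceback (%s): no case reproduces cell (%d,%d)", what, i,
         j);
  }

  // recompute W / WM / WM2 of row a over columns a..bmax from candidates
  void rec_rows(int a, int bmax, std::vector<int>& W_, std::vector<int>& WM_,
                std::vector<int>& WM2_) {
    const int c = ctx.P.ml_base;
    size_t sz = (size_t)std::max(a, bmax) + 2;
    W_.assign(sz, 0);
    WM_.assign(sz, E_INF);
    WM2_.assign(sz, E_INF);
    if (a > bmax) return;
    W_[a] = ctx.C.up_ok(a) ? 0 : E_INF;
    auto Wv = [&](int j) { return j < a ? 0 : W_[j]; };
    auto WMv = [&](int j) { return j < a ? E_INF : WM_[j]; };
    for (int j = a + 1; j <= bmax; ++j) {
      int wp = ctx.C.up_ok(j) ? Wv(j - 1) : E_INF;
      int wm2 = ctx.C.up_ok(j) ? eadd(WM2_[j - 1], c) : E_INF;
      int wmp = ctx.C.up_ok(j) ? eadd(WMv(j - 1), c) : E_INF;
      for (const auto& e : cand[j]) {
        if (e.i < a) break;  // lists are i-descending
        int x = eadd(Wv(e.i - 1), entry_Wd(e));
        if (x < wp) wp = x;
        x = eadd(WMv(e.i - 1), entry_WMd(e));
        if (x < wm2) wm2 = x;
        if (ctx.C.region_ok(a, e.i - 1)) {
          x = eadd(c * (e.i - a), entry_WMd(e));
          if (x < wmp) wmp = x;
        }
      }
      WM2_[j] = wm2;
      if (wm2 < wmp) wmp = wm2;
      W_[j] = wp;
      WM_[j] = wmp;
    }
  }

  // tasks are V cells with known target energies
  std::vector<std::array<int, 3>> vtasks;

  // can some case of the V recursion reproduce value T at (p,q)?  Used to
  // disambiguate ties in the triplet re-addition rule: two dangle cases may
  // re-add to the same context energy, but only the true one implies an
  // inner V value the trace can continue from.
  bool v_reproducible(int p, int q, int T) {
    if (T >= E_BAR) return false;
    if (q - p <= ctx.P.m || !ctx.pt(p, q) || !ctx.C.pair_ok(p, q))
      return false;
    if (ctx.C.region_ok(p + 1, q - 1) && T == ctx.e_hairpin(p, q))
      return true;
    auto ar = arrows.find(key(p, q));
    if (ar != arrows.end())
      return T == eadd(ctx.e_intloop(p, q, ar->second.p, ar->second.q),
                       ar->second.V);
    if (il_cand(p, q).e == T) return true;
    std::vector<int> W_, WM_, WM2_;
    for (int d = 0; d < ctx.n_ml_cases(); ++d) {
      Ctx::MLClose mc = ctx.ml_close_case(p, q, d);
      if (!mc.valid || mc.b2 - mc.a2 < 2 * ctx.P.m + 3) continue;
      rec_rows(mc.a2, mc.b2, W_, WM_, WM2_);
      if (T == eadd(WM2_[mc.b2], mc.extra)) return true;
    }
    return false;
  }

  // resolve the dangle case of a candidate stem [k,l] in context ml with
  // target energy T, per the active recovery strategy, and push the inner
  // V cell
  void enter_stem(const CandEntry& e, int k, int l, bool ml, int T) {
    if (ctx.model != 1) {
      vtasks.push_back({k, l, e.V});
      return;
    }
    int d = -1;
    int innerV = 0;
    if (strategy == STRAT_TRACE) {
      auto it = edarrows.find(key(k, l));
      if (it == edarrows.end()) err("ed-arrow", k, l);
      d = ml ? it->second.dWM : it->second.dW;
      innerV = (d == 0) ? e.V : T - ctx.stem_case_terms(k, l, d, ml);
    } else if (strategy == STRAT_STANDARD) {
      int enc = 4 * (ml ? e.WMd : e.Wd) + (ml ? e.dWM : e.dW);
      int dd = ((enc % 4) + 4) % 4;
      int val = (enc - dd) / 4;
      if (val != T) err("encoded stem", k, l);
      d = dd;
      innerV = (d == 0) ? e.V : T - ctx.stem_case_terms(k, l, d, ml);
    } else {  // triplet: re-add each dangle term to the un-dangled value
      int und = ml ? e.undWM : e.undW;
      for (int dd = 0; dd < 4; ++dd) {
        int p, q;
        ctx.stem_inner(k, l, dd, p, q);
        if ((dd == 1 || dd == 3) && !ctx.C.up_ok(k)) continue;
        if ((dd == 2 || dd == 3) && !ctx.C.up_ok(l)) continue;
        if (q - p <= ctx.P.m || !ctx.pt(p, q)) continue;
        int iv = (dd == 0 ? e.V : und);
        int trial = eadd(iv, ctx.stem_case_terms(k, l, dd, ml));
        if (trial == T && v_reproducible(p, q, iv)) {
          d = dd; innerV = iv; break;
        }
      }
      if (d < 0) err("triplet stem", k, l);
    }
    int p, q;
    ctx.stem_inner(k, l, d, p, q);
    vtasks.push_back({p, q, innerV});
  }

  // walk W(i, .) from column b leftwards using recomputed rows
  void walk_W(int i, int b) {
    std::vector<int> W_, WM_, WM2_;
    rec_rows(i, b, W_, WM_, WM2_);
    auto Wv = [&](int j) { return j < i ? 0 : W_[j]; };
    while (b > i) {
      int target = W_[b];
      if (target >= E_BAR) err("W", i, b);
      if (ctx.C.up_ok(b) && target == Wv(b - 1)) { --b; continue; }
      bool found = false;
      const auto& L = cand[b];
      for (auto it = L.rbegin(); it != L.rend(); ++it) {  // k ascending
        if (it->i < i) continue;
        if (target == eadd(Wv(it->i - 1), entry_Wd(*it))) {
          enter_stem(*it, it->i, b, false, entry_Wd(*it));
          b = it->i - 1;
          found = true;
          break;
        }
      }
      if (!found) err("W split", i, b);
    }
  }

  // walk a multiloop decomposition: kind 0 = WM2, 1 = WM
  void walk_ML(int a, int b, int kind) {
    std::vector<int> W_, WM_, WM2_;
    rec_rows(a, b, W_, WM_, WM2_);
    auto WMv = [&](int j) { return j < a ? E_INF : WM_[j]; };
    const int c = ctx.P.ml_base;
    while (true) {
      if (kind == 0) {  // WM2(a,b)
        int target = WM2_[b];
        if (target >= E_BAR || b <= a) err("WM2", a, b);
        if (ctx.C.up_ok(b) && target == eadd(WM2_[b - 1], c)) { --b; continue; }
        bool found = false;
        const auto& L = cand[b];
        for (auto it = L.rbegin(); it != L.rend(); ++it) {
          if (it->i < a) continue;
          if (target == eadd(WMv(it->i - 1), entry_WMd(*it))) {
            enter_stem(*it, it->i, b, true, entry_WMd(*it));
            b = it->i - 1;
            kind = 1;  // continue with WM(a, k-1)
            found = true;
            break;
          }
        }
        if (!found) err("WM2 split", a, b);
      } else {  // WM(a,b)
        int target = WM_[b];
        if (target >= E_BAR || b < a) err("WM", a, b);
        if (ctx.C.up_ok(b) && target == eadd(WMv(b - 1), c)) { --b; continue; }
        bool found = false;
        const auto& L = cand[b];
        for (auto it = L.rbegin(); it != L.rend(); ++it) {
          if (it->i < a) continue;
          if (!ctx.C.region_ok(a, it->i - 1)) continue;
          if (target == eadd(c * (it->i - a), entry_WMd(*it))) {
            enter_stem(*it, it->i, b, true, entry_WMd(*it));
            return;  // prefix a..k-1 is all unpaired
          }
        }
        if (found) continue;
        if (target == WM2_[b]) { kind = 0; continue; }
        err("WM case", a, b);
      }
    }
  }

  void trace() {
    ptab.assign(n + 1, 0);
    if (mfe >= E_BAR) err("start", 1, n);
    vtasks.clear();
    walk_W(1, n);
    while (!vtasks.empty()) {
      auto t = vtasks.back();
      vtasks.pop_back();
      int i = t[0], j = t[1], T = t[2];
      ptab[i] = j; ptab[j] = i;
      if (ctx.C.region_ok(i + 1, j - 1) && T == ctx.e_hairpin(i, j)) continue;
      auto ar = arrows.find(key(i, j));
      if (ar != arrows.end()) {
        const Arrow& a = ar->second;
        if (T != eadd(ctx.e_intloop(i, j, a.p, a.q), a.V))
          err("arrow", i, j);
        vtasks.push_back({a.p, a.q, a.V});
        continue;
      }
      ILRes rc = il_cand(i, j);
      if (rc.e == T) {
        const CandEntry* e = find_cand(rc.p, rc.q);
        if (!e) err("interior candidate", i, j);
        vtasks.push_back({rc.p, rc.q, e->V});
        continue;
      }
      bool done = false;
      std::vector<int> W1, WM1, WM21, W2, WM2a, WM22;
      bool have1 = false, have2 = false;
      for (int d = 0; d < ctx.n_ml_cases() && !done; ++d) {
        Ctx::MLClose mc = ctx.ml_close_case(i, j, d);
        if (!mc.valid || mc.b2 - mc.a2 < 2 * ctx.P.m + 3) continue;
        if (mc.a2 == i + 1 && !have1) {
          rec_rows(i + 1, j - 1, W1, WM1, WM21);
          have1 = true;
        }
        if (mc.a2 == i + 2 && !have2) {
          rec_rows(i + 2, j - 1, W2, WM2a, WM22);
          have2 = true;
        }
        const std::vector<int>& wm2row = (mc.a2 == i + 1) ? WM21 : WM22;
        if (T == eadd(wm2row[mc.b2], mc.extra)) {
          walk_ML(mc.a2, mc.b2, 0);
          done = true;
        }
      }
      if (!done) err("V", i, j);
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_fold_sparse(IntegerVector seq, std::string chars, int model,
                     int strategy, List par, IntegerVector cons,
                     bool d53_sum, bool debug, bool do_trace) {
  Sparse S;
  ctx_init(S.ctx, seq, chars, model, par, cons, d53_sum);
  S.strategy = strategy;
  S.debug = debug;
  S.fill();
  size_t arrows_live = S.arrows.size();
  if (do_trace && S.mfe < E_BAR) S.trace();

  int n = S.n;
  // candidate table
  IntegerMatrix cm(S.Z, 7);
  {
    int r = 0;
    for (int j = 1; j <= n; ++j)
      for (auto it = S.cand[j].rbegin(); it != S.cand[j].rend(); ++it) {
        cm(r, 0) = it->i; cm(r, 1) = j; cm(r, 2) = it->V;
        cm(r, 3) = S.entry_Wd(*it); cm(r, 4) = S.entry_WMd(*it);
        cm(r, 5) = it->dW; cm(r, 6) = it->dWM;
        ++r;
      }
    colnames(cm) = CharacterVector::create("i", "j", "V", "Wd", "WMd", "dW",
                                           "dWM");
  }
  // per-candidate payload bytes by strategy: the standard strategy widens
  // its two bit-encoded context fields so the full energy range remains
  // representable after the 2-bit shift; the triplet keeps plain 32-bit
  // fields plus one byte of per-context dangle codes; d0/d2 candidates are
  // (start, V) pairs
  int payload = 8;
  if (S.ctx.model == 1)
    payload = (strategy == STRAT_STANDARD) ? 24
              : (strategy == STRAT_TRIPLET) ? 17 : 16;
  size_t peak_cells = (size_t)S.band_rows() * (n + 2) + 5 * (size_t)(n + 2);

  List stats = List::create(
      _["n"] = n,
      _["Z"] = (double)S.Z,
      _["z_ratio"] = n > 1 ? (double)S.Z / ((double)n * (n - 1) / 2) : 0.0,
      _["candidates_per_column"] = IntegerVector(S.cand_per_col.begin() + 1,
                                                 S.cand_per_col.end()),
      _["trace_arrows_peak"] = (double)S.t_peak,
      _["trace_arrows_live"] = (double)arrows_live,
      _["trace_arrows_removed"] = (double)S.arrows_removed,
      _["ed_trace_arrows"] = (double)S.edarrows.size(),
      _["candidate_payload_bytes"] = payload,
      _["peak_dense_cells"] = (double)peak_cells);

  List out = List::create(
      _["mfe"] = S.mfe, _["n"] = n, _["stats"] = stats,
      _["candidates"] = cm);
  if (do_trace && S.mfe < E_BAR)
    out["pt"] = IntegerVector(S.ptab.begin() + 1, S.ptab.end());
  if (debug) {
    auto mat = [&](const std::vector<int>& M_) {
      IntegerMatrix R(n, n);
      for (int i = 1; i <= n; ++i)
        for (int j = 1; j <= n; ++j)
          R(i - 1, j - 1) = (j >= i) ? M_[(size_t)i * (n + 2) + j]
                                     : NA_INTEGER;
      return R;
    };
    out["matrices"] = List::create(
        _["W"] = mat(S.dbgW), _["Wp"] = mat(S.dbgWp), _["V"] = mat(S.dbgV),
        _["WM"] = mat(S.dbgWM), _["WMp"] = mat(S.dbgWMp),
        _["WM2"] = mat(S.dbgWM2));
  }
  return out;
}
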