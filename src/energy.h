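#ifndef SPARSEFOLD_ENERGY_H
#define SPARSEFOLD_ENERGY_H

#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <string>
#include <vector>
#include <cmath>

// Energies are integers in dekacal/mol (0.01 kcal/mol).  E_INF marks
// forbidden states; it is chosen so that E_INF + E_INF is far below the
// int32 overflow bound, and any value above E_BAR is treated as infinite.
constexpr int E_INF = 10000000;
constexpr int E_BAR = E_INF / 2;

inline int eadd(int a, int b) {
  return (a >= E_BAR || b >= E_BAR) ? E_INF : a + b;
}

// base codes 0=N 1=A 2=C 3=G 4=U; pair types CG=1 GC=2 GU=3 UG=4 AU=5 UA=6
inline int pair_code(int b5, int b3) {
  static const int tab[5][5] = {
    {0, 0, 0, 0, 0},
    {0, 0, 0, 0, 5},   // A.
    {0, 0, 0, 1, 0},   // C.
    {0, 0, 2, 0, 3},   // G.
    {0, 6, 0, 4, 0}};  // U.
  return tab[b5][b3];
}

struct Params {
  int stack[8][8];
  int mmh[8][5][5], mmi[8][5][5], mm1n[8][5][5], mm23[8][5][5];
  int mmm[8][5][5], mme[8][5][5];
  int d5[8][5], d3[8][5];
  int int11[8][8][5][5];
  int int21[8][8][5][5][5];
  int int22[7][7][5][5][5][5];
  int hp[31], bulge[31], internal[31];
  int ml_base, ml_closing, ml_intern;  // c, a, b
  int ninio, max_ninio, terminal_AU;
  double lxc;
  int m, M;
  bool d53_sum;  // exclusive-dangle 53' as dangle5+dangle3 instead of mismatch
  std::map<std::string, int> tetra, tri, hexa;

  void load(const Rcpp::List& p);
};

struct Cons {
  int n;
  std::vector<int> partner;  // 0 free, -1 forced unpaired, >0 partner index
  std::vector<int> pfx;      // prefix count of forced-paired positions

  void init(int n_, const Rcpp::IntegerVector& part) {
    n = n_;
    partner.assign(n + 2, 0);
    pfx.assign(n + 2, 0);
    for (int i = 1; i <= n; ++i) {
      if (part.size()) partner[i] = part[i - 1];
      pfx[i] = pfx[i - 1] + (partner[i] > 0 ? 1 : 0);
    }
    pfx[n + 1] = pfx[n];
  }
  bool up_ok(int i) const { return partner[i] <= 0; }
  // true when no position in [i,j] is forced to pair
  bool region_ok(int i, int j) const {
    if (i > j) return true;
    return pfx[j] - pfx[i - 1] == 0;
  }
  bool pair_ok(int i, int j) const {
    if (partner[i] == -1 || partner[j] == -1) return false;
    if (partner[i] > 0 && partner[i] != j) return false;
    if (partner[j] > 0 && partner[j] != i) return false;
    return true;
  }
};

// Branch-free guard of the interior-loop scan: adds 0 to e when both region
// flags are set and (effectively) infinity otherwise, via two's-complement
// masking instead of conditionals.
inline int il_guard(int left_ok, int right_ok, int e) {
  return e + (((left_ok - 1) | (right_ok - 1)) & E_INF);
}

// folding context shared by both engines
struct Ctx {
  int n;
  std::vector<int> S;   // 1-based base codes
  std::string chars;    // 1-based characters (index 0 unused)
  Params P;
  Cons C;
  int model;  // 0,1,2

  int pt(int i, int j) const { return pair_code(S[i], S[j]); }
  int tau(int type) const { return type > 2 ? P.terminal_AU : 0; }

  int loop_extrap(const int* tab, int size) const {
    if (size <= 30) return tab[size];
    return tab[30] + (int)(P.lxc * std::log(size / 30.0));
  }

  int e_hairpin(int i, int j) const {
    int size = j - i - 1;
    if (size < P.m) return E_INF;
    int type = pt(i, j);
    if (!type) return E_INF;
    int e = loop_extrap(P.hp, size);
    if (size == 4) {
      auto it = P.tetra.find(chars.substr(i, 6));
      if (it != P.tetra.end()) return it->second;
    } else if (size == 6) {
      auto it = P.hexa.find(chars.substr(i, 8));
      if (it != P.hexa.end()) return it->second;
    } else if (size == 3) {
      auto it = P.tri.find(chars.substr(i, 5));
      if (it != P.tri.end()) return it->second;
      return e + tau(type);
    }
    e += P.mmh[type][S[i + 1]][S[j - 1]];
    return e;
  }

  // interior loop / bulge / stack closed by i.j with inner pair p.q
  int e_intloop(int i, int j, int p, int q) const {
    int type = pt(i, j), type2 = pt(q, p);
    if (!type || !type2) return E_INF;
    int n1 = p - i - 1, n2 = j - q - 1;
    if (n1 + n2 > P.M) return E_INF;
    int nl = n1 > n2 ? n1 : n2, ns = n1 > n2 ? n2 : n1;
    if (nl == 0) return P.stack[type][type2];
    if (ns == 0) {
      int e = loop_extrap(P.bulge, nl);
      if (nl == 1) {
        e += P.stack[type][type2];
      } else {
        if (type > 2) e += P.terminal_AU;
        if (type2 > 2) e += P.terminal_AU;
      }
      return e;
    }
    int si1 = S[i + 1], sj1 = S[j - 1], sp1 = S[p - 1], sq1 = S[q + 1];
    if (ns == 1) {
      if (nl == 1) return P.int11[type][type2][si1][sj1];
      if (nl == 2) {
        if (n1 == 1) return P.int21[type][type2][si1][sq1][sj1];
        return P.int21[type2][type][sq1][si1][sp1];
      }
      int e = loop_extrap(P.internal, nl + 1);
      int nin = (nl - ns) * P.ninio;
      e += nin < P.max_ninio ? nin : P.max_ninio;
      e += P.mm1n[type][si1][sj1] + P.mm1n[type2][sq1][sp1];
      return e;
    }
    if (ns == 2) {
      if (nl == 2) return P.int22[type][type2][si1][sp1][sq1][sj1];
      if (nl == 3) {
        return P.internal[5] + P.ninio +
               P.mm23[type][si1][sj1] + P.mm23[type2][sq1][sp1];
      }
    }
    int e = loop_extrap(P.internal, nl + ns);
    int nin = (nl - ns) * P.ninio;
    e += nin < P.max_ninio ? nin : P.max_ninio;
    e += P.mmi[type][si1][sj1] + P.mmi[type2][sq1][sp1];
    return e;
  }

  // dangle / mismatch contribution of a stem of pair type `type` whose
  // 5'-adjacent base is b5 and 3'-adjacent base is b3 (-1 = absent);
  // ml: use the multiloop mismatch table; sum53: decompose the both-sides
  // term into dangle5 + dangle3 (exclusive-dangle table mapping option)
  int stem_dangle(int type, int b5, int b3, bool ml, bool sum53) const {
    if (b5 >= 0 && b3 >= 0) {
      if (sum53) return P.d5[type][b5] + P.d3[type][b3];
      return ml ? P.mmm[type][b5][b3] : P.mme[type][b5][b3];
    }
    if (b5 >= 0) return P.d5[type][b5];
    if (b3 >= 0) return P.d3[type][b3];
    return 0;
  }

  // energy (and chosen dangle case, for the exclusive model) of a stem
  // occupying [i,j] of an external loop or a multiloop.  Dangle cases:
  // 0 = none, 1 = 5', 2 = 3', 3 = both sides.  Vij etc. are the V values of
  // the unshifted and shifted pairs (E_INF where invalid).
  struct StemE { int e; int d; };

  StemE ctx_stem(int i, int j, int Vij, int Vi1j, int Vij1, int Vi1j1,
                 bool ml) const {
    const int b = ml ? P.ml_intern : 0;
    const int c = ml ? P.ml_base : 0;
    if (model == 0) {
      int t = pt(i, j);
      return {eadd(Vij, t ? tau(t) + b : 0), 0};
    }
    if (model == 2) {
      int t = pt(i, j);
      if (!t || Vij >= E_BAR) return {E_INF, 0};
      int b5 = ml ? S[i - 1] : (i > 1 ? S[i - 1] : -1);
      int b3 = ml ? S[j + 1] : (j < n ? S[j + 1] : -1);
      return {eadd(Vij, tau(t) + b + stem_dangle(t, b5, b3, ml, false)), 3};
    }
    // exclusive dangle: four cases in printed order
    int best = E_INF, bd = 0;
    {
      int t = pt(i, j);
      if (t && Vij < E_BAR) { best = Vij + tau(t) + b; bd = 0; }
    }
    if (C.up_ok(i)) {
      int t = pt(i + 1, j);
      if (t && Vi1j < E_BAR) {
        int e = Vi1j + tau(t) + b + c + P.d5[t][S[i]];
        if (e < best) { best = e; bd = 1; }
      }
    }
    if (C.up_ok(j)) {
      int t = pt(i, j - 1);
      if (t && Vij1 < E_BAR) {
        int e = Vij1 + tau(t) + b + c + P.d3[t][S[j]];
        if (e < best) { best = e; bd = 2; }
      }
    }
    if (C.up_ok(i) && C.up_ok(j)) {
      int t = pt(i + 1, j - 1);
      if (t && Vi1j1 < E_BAR) {
        int e = Vi1j1 + tau(t) + b + 2 * c +
                stem_dangle(t, S[i], S[j], ml, P.d53_sum);
        if (e < best) { best = e; bd = 3; }
      }
    }
    return {best, bd};
  }

  // terms added to V(p,q) by dangle case d of a stem spanning [i,j]
  // (inverse of ctx_stem for a known case)
  int stem_case_terms(int i, int j, int d, bool ml) const {
    const int b = ml ? P.ml_intern : 0;
    const int c = ml ? P.ml_base : 0;
    if (model == 2) {
      int t = pt(i, j);
      int b5 = ml ? S[i - 1] : (i > 1 ? S[i - 1] : -1);
      int b3 = ml ? S[j + 1] : (j < n ? S[j + 1] : -1);
      return tau(t) + b + stem_dangle(t, b5, b3, ml, false);
    }
    if (model == 0 || d == 0) return tau(pt(i, j)) + b;
    if (d == 1) { int t = pt(i + 1, j); return tau(t) + b + c + P.d5[t][S[i]]; }
    if (d == 2) { int t = pt(i, j - 1); return tau(t) + b + c + P.d3[t][S[j]]; }
    int t = pt(i + 1, j - 1);
    return tau(t) + b + 2 * c + stem_dangle(t, S[i], S[j], ml, P.d53_sum);
  }

  // inner pair of a stem spanning [i,j] under dangle case d
  void stem_inner(int i, int j, int d, int& p, int& q) const {
    p = i + (model == 1 && (d == 1 || d == 3) ? 1 : 0);
    q = j - (model == 1 && (d == 2 || d == 3) ? 1 : 0);
  }

  // multiloop-closing cases for pair i.j: returns energies (excluding the
  // WM2 part) and the WM2 span per case; cases follow the printed order of
  // the exclusive model; d0/d2 have a single case 0.
  struct MLClose { int extra; int a2, b2; bool valid; };

  MLClose ml_close_case(int i, int j, int d) const {
    int rt = pt(j, i);  // closing pair seen from inside the loop
    const int base = P.ml_closing + P.ml_intern + tau(rt);
    const int c = P.ml_base;
    if (model == 0) return {base, i + 1, j - 1, d == 0};
    if (model == 2)
      return {base + P.mmm[rt][S[j - 1]][S[i + 1]], i + 1, j - 1, d == 0};
    switch (d) {
      case 0: return {base, i + 1, j - 1, true};
      case 1:  // inner base i+1 dangles 3' of the closing pair
        return {base + c + P.d3[rt][S[i + 1]], i + 2, j - 1, C.up_ok(i + 1)};
      case 2:  // inner base j-1 dangles 5' of the closing pair
        return {base + c + P.d5[rt][S[j - 1]], i + 1, j - 2, C.up_ok(j - 1)};
      default:
        return {base + 2 * c +
                    stem_dangle(rt, S[j - 1], S[i + 1], true, P.d53_sum),
                i + 2, j - 2, C.up_ok(i + 1) && C.up_ok(j - 1)};
    }
  }
  int n_ml_cases() const { return model == 1 ? 4 : 1; }
};

void ctx_init(Ctx& ctx, const Rcpp::IntegerVector& seq,
              const std::string& chars, int model, const Rcpp::List& par,
              const Rcpp::IntegerVector& cons, bool d53_sum);

#endif
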