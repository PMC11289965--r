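#include "energy.h"

using namespace Rcpp;

void Params::load(const List& p) {
  IntegerVector v;

  v = p["stack"];
  for (int a = 1; a <= 7; ++a)
    for (int b = 1; b <= 7; ++b) stack[a][b] = v[(a - 1) * 7 + (b - 1)];

  auto mm = [&](const char* name, int tab[8][5][5]) {
    IntegerVector w = p[name];
    for (int t = 1; t <= 7; ++t)
      for (int a = 0; a < 5; ++a)
        for (int b = 0; b < 5; ++b)
          tab[t][a][b] = w[((t - 1) * 5 + a) * 5 + b];
  };
  mm("mismatch_hairpin", mmh);
  mm("mismatch_interior", mmi);
  mm("mismatch_interior_1n", mm1n);
  mm("mismatch_interior_23", mm23);
  mm("mismatch_multi", mmm);
  mm("mismatch_exterior", mme);

  auto dang = [&](const char* name, int tab[8][5]) {
    IntegerVector w = p[name];
    for (int t = 1; t <= 7; ++t)
      for (int a = 0; a < 5; ++a) tab[t][a] = w[(t - 1) * 5 + a];
  };
  dang("dangle5", d5);
  dang("dangle3", d3);

  v = p["int11"];
  for (int t = 1; t <= 7; ++t)
    for (int u = 1; u <= 7; ++u)
      for (int a = 0; a < 5; ++a)
        for (int b = 0; b < 5; ++b)
          int11[t][u][a][b] = v[(((t - 1) * 7 + (u - 1)) * 5 + a) * 5 + b];

  v = p["int21"];
  for (int t = 1; t <= 7; ++t)
    for (int u = 1; u <= 7; ++u)
      for (int a = 0; a < 5; ++a)
        for (int b = 0; b < 5; ++b)
          for (int c = 0; c < 5; ++c)
            int21[t][u][a][b][c] =
                v[((((t - 1) * 7 + (u - 1)) * 5 + a) * 5 + b) * 5 + c];

  v = p["int22"];
  for (int t = 0; t < 7; ++t)
    for (int u = 0; u < 7; ++u)
      for (int a = 0; a < 5; ++a)
        for (int b = 0; b < 5; ++b)
          for (int c = 0; c < 5; ++c)
            for (int d = 0; d < 5; ++d) int22[t][u][a][b][c][d] = E_INF;
  for (int t = 1; t <= 6; ++t)
    for (int u = 1; u <= 6; ++u)
      for (int a = 1; a <= 4; ++a)
        for (int b = 1; b <= 4; ++b)
          for (int c = 1; c <= 4; ++c)
            for (int d = 1; d <= 4; ++d)
              int22[t][u][a][b][c][d] =
                  v[((((((t - 1) * 6 + (u - 1)) * 4 + (a - 1)) * 4 +
                       (b - 1)) * 4 + (c - 1)) * 4 + (d - 1))];

  auto len31 = [&](const char* name, int* tab) {
    IntegerVector w = p[name];
    for (int k = 0; k < 31; ++k) tab[k] = w[k];
  };
  len31("hairpin_init", hp);
  len31("bulge_init", bulge);
  len31("interior_init", internal);

  auto loops = [&](const char* name, std::map<std::string, int>& tab) {
    IntegerVector w = p[name];
    if (w.size() == 0) return;
    CharacterVector nm = w.names();
    for (int k = 0; k < w.size(); ++k) tab[as<std::string>(nm[k])] = w[k];
  };
  loops("tetraloops", tetra);
  loops("triloops", tri);
  loops("hexaloops", hexa);

  ml_base = as<int>(p["ml_base"]);
  ml_closing = as<int>(p["ml_closing"]);
  ml_intern = as<int>(p["ml_intern"]);
  ninio = as<int>(p["ninio"]);
  max_ninio = as<int>(p["max_ninio"]);
  terminal_AU = as<int>(p["terminal_AU"]);
  lxc = as<double>(p["lxc"]);
  m = as<int>(p["m"]);
  M = as<int>(p["M"]);
}

void ctx_init(Ctx& ctx, const IntegerVector& seq, const std::string& chars,
              int model, const List& par, const IntegerVector& cons,
              bool d53_sum) {
  ctx.n = seq.size();
  ctx.S.assign(ctx.n + 2, 0);
  for (int i = 1; i <= ctx.n; ++i) ctx.S[i] = seq[i - 1];
  ctx.chars = std::string(" ") + chars + " ";
  ctx.model = model;
  ctx.P.load(par);
  ctx.P.d53_sum = d53_sum;
  ctx.C.init(ctx.n, cons);
}
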