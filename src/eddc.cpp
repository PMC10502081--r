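#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Edit distance with unit duplication and contraction.
//
// Single-character operations (match / mismatch / insertion / deletion) are
// combined with whole-unit copy-number operations: duplicating an existing
// copy of a unit u (u -> uu) and contracting two adjacent copies (uu -> u).
// Copy blocks routed through a unit are tracked by per-unit chain states:
//   P  - paired blocks (one block of s matched to one block of t via u)
//   Us - surplus s blocks removed by contraction after at least one pair
//   Ut - surplus t blocks created by duplication after at least one pair
//   D  - a run of s copies with no t counterpart (one full deletion seeds it,
//        the rest contract into the seed)
//   I  - a run of t copies with no s counterpart (one full insertion seeds
//        it, the rest are duplications)
// Every transition corresponds to a realisable edit script, so the value is
// always achievable; optimality is exercised against an exhaustive script
// search on small instances in the test suite.

static double block_lev(const std::string &a, const std::string &u,
                        double mis, double ins, double del) {
  const int n = (int)a.size(), m = (int)u.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int k = 0; k <= m; ++k) prev[k] = k * ins;  // build u chars = insertions
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * del;
    for (int k = 1; k <= m; ++k) {
      double d = prev[k - 1] + (a[i - 1] == u[k - 1] ? 0.0 : mis);
      d = std::min(d, prev[k] + del);
      d = std::min(d, cur[k - 1] + ins);
      cur[k] = d;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
double cpp_eddc(std::string s, std::string t, std::vector<std::string> units,
                double mismatch, double insertion, double deletion,
                NumericVector dup_cost, NumericVector con_cost) {
  const int ns = (int)s.size(), nt = (int)t.size();
  const int nu = (int)units.size();
  const double INF = 1e300;

  std::vector<int> mlen(nu), lmin(nu), lmax(nu);
  int R = 2;
  for (int ui = 0; ui < nu; ++ui) {
    mlen[ui] = (int)units[ui].size();
    lmin[ui] = std::max(1, mlen[ui] - 2);
    lmax[ui] = mlen[ui] + 2;
    R = std::max(R, lmax[ui] + 1);
  }

  // block conversion costs: bs[ui][i * W + (L - lmin)] = lev(s[i-L..i), u)
  std::vector<std::vector<double> > bs(nu), bt(nu);
  for (int ui = 0; ui < nu; ++ui) {
    int W = lmax[ui] - lmin[ui] + 1;
    bs[ui].assign((size_t)(ns + 1) * W, INF);
    bt[ui].assign((size_t)(nt + 1) * W, INF);
    for (int i = 0; i <= ns; ++i)
      for (int L = lmin[ui]; L <= std::min(lmax[ui], i); ++L)
        bs[ui][(size_t)i * W + (L - lmin[ui])] =
          block_lev(s.substr(i - L, L), units[ui], mismatch, insertion, deletion);
    for (int j = 0; j <= nt; ++j)
      for (int L = lmin[ui]; L <= std::min(lmax[ui], j); ++L)
        bt[ui][(size_t)j * W + (L - lmin[ui])] =
          block_lev(t.substr(j - L, L), units[ui], mismatch, insertion, deletion);
  }

  const size_t rowlen = nt + 1;
  auto makeRing = [&](std::vector<std::vector<double> > &ring) {
    ring.assign(R, std::vector<double>(rowlen, INF));
  };
  std::vector<std::vector<double> > E;
  std::vector<std::vector<std::vector<double> > > P(nu), Us(nu), Ut(nu), D(nu), I(nu);
  makeRing(E);
  for (int ui = 0; ui < nu; ++ui) {
    makeRing(P[ui]); makeRing(Us[ui]); makeRing(Ut[ui]);
    makeRing(D[ui]); makeRing(I[ui]);
  }

  for (int i = 0; i <= ns; ++i) {
    int ri = i % R;
    for (int ui = 0; ui < nu; ++ui) {
      std::fill(P[ui][ri].begin(), P[ui][ri].end(), INF);
      std::fill(Us[ui][ri].begin(), Us[ui][ri].end(), INF);
      std::fill(Ut[ui][ri].begin(), Ut[ui][ri].end(), INF);
      std::fill(D[ui][ri].begin(), D[ui][ri].end(), INF);
      std::fill(I[ui][ri].begin(), I[ui][ri].end(), INF);
    }
    std::fill(E[ri].begin(), E[ri].end(), INF);

    for (int j = 0; j <= nt; ++j) {
      for (int ui = 0; ui < nu; ++ui) {
        const int W = lmax[ui] - lmin[ui] + 1;
        const int m = mlen[ui];
        double p = INF, us = INF, ut = INF, dd = INF, ii = INF;
        for (int Ls = lmin[ui]; Ls <= std::min(lmax[ui], i); ++Ls) {
          int rs = (i - Ls) % R;
          double cs = bs[ui][(size_t)i * W + (Ls - lmin[ui])];
          // paired block needs a t block too
          for (int Lt = lmin[ui]; Lt <= std::min(lmax[ui], j); ++Lt) {
            double ct = bt[ui][(size_t)j * W + (Lt - lmin[ui])];
            double base = std::min(E[rs][j - Lt], P[ui][rs][j - Lt]);
            if (base < INF) p = std::min(p, base + cs + ct);
          }
          double baseU = std::min(P[ui][rs][j], Us[ui][rs][j]);
          if (baseU < INF) us = std::min(us, baseU + cs + con_cost[ui]);
          if (E[rs][j] < INF)
            dd = std::min(dd, E[rs][j] + cs + m * deletion);
          if (D[ui][rs][j] < INF)
            dd = std::min(dd, D[ui][rs][j] + cs + con_cost[ui]);
        }
        for (int Lt = lmin[ui]; Lt <= std::min(lmax[ui], j); ++Lt) {
          double ct = bt[ui][(size_t)j * W + (Lt - lmin[ui])];
          double baseU = std::min(P[ui][ri][j - Lt], Ut[ui][ri][j - Lt]);
          if (baseU < INF) ut = std::min(ut, baseU + ct + dup_cost[ui]);
          if (E[ri][j - Lt] < INF)
            ii = std::min(ii, E[ri][j - Lt] + ct + m * insertion);
          if (I[ui][ri][j - Lt] < INF)
            ii = std::min(ii, I[ui][ri][j - Lt] + ct + dup_cost[ui]);
        }
        P[ui][ri][j] = p; Us[ui][ri][j] = us; Ut[ui][ri][j] = ut;
        D[ui][ri][j] = dd; I[ui][ri][j] = ii;
      }
      double e = INF;
      if (i == 0 && j == 0) e = 0.0;
      if (i > 0 && j > 0) {
        double sub = (s[i - 1] == t[j - 1]) ? 0.0 : mismatch;
        e = std::min(e, E[(i - 1) % R][j - 1] + sub);
      }
      if (i > 0) e = std::min(e, E[(i - 1) % R][j] + deletion);
      if (j > 0) e = std::min(e, E[ri][j - 1] + insertion);
      for (int ui = 0; ui < nu; ++ui) {
        e = std::min(e, P[ui][ri][j]);
        e = std::min(e, Us[ui][ri][j]);
        e = std::min(e, Ut[ui][ri][j]);
        e = std::min(e, D[ui][ri][j]);
        e = std::min(e, I[ui][ri][j]);
      }
      E[ri][j] = e;
    }
  }
  return E[ns % R][nt];
}
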