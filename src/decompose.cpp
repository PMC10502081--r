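#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

// Parse S into unit copies (with edits) and uncovered literal runs.
//
// Objective, minimised jointly over all segmentations:
//   sum(per-segment edit cost) + copy_cost * (#unit copies)
//                              + unc_cost  * (#uncovered bases)
// ties broken toward lower total edit cost, then toward uncovered/earlier
// unit in the order given.  The copy and uncovered terms are the occ(u) and
// uncovered-base terms of the unit-selection penalty, so the same parse
// serves both the reported Levenshtein distance and the penalty.
//
// Encoding: value = combined * K + dist, K larger than any achievable dist,
// so ordering is lexicographic (combined, dist).

struct Cell {
  int64_t v;     // encoded (combined, dist)
  int start;     // 0-based offset where the current copy began
  int edits;     // edit cost accumulated inside the current copy
};

// exact = 1 restricts copies to exact unit matches (no edits): the parse
// then minimises occ + uncovered, the variable part of the unit-selection
// penalty, whose occ(u) counts exact occurrences in S.
// exact = 2 additionally requires copies to come in tandem runs of at
// least min_run adjacent exact copies: scattered or paired chance matches
// of a short unit (e.g. inside error-broken stretches) then cannot absorb
// uncovered bases, while true generating units - which slippage lays down
// in long runs - can.

// run-restricted exact parse: O(n * |units|)
static List exact_run_parse(const std::string &S,
                            const std::vector<std::string> &units,
                            int copy_cost, int unc_cost,
                            const std::vector<int> &min_run) {
  const int n = (int)S.size();
  const int nu = (int)units.size();
  const long long INF = (long long)1 << 60;
  std::vector<long long> B(n + 1, INF);
  std::vector<int> chU(n + 1, -1), chR(n + 1, 0);
  // L[ui][j]: consecutive exact copies of unit ui ending at offset j
  std::vector<std::vector<int> > L(nu, std::vector<int>(n + 1, 0));
  std::vector<std::vector<long long> > A(nu,
      std::vector<long long>(n + 1, INF));
  std::vector<std::vector<int> > AR(nu, std::vector<int>(n + 1, 0));
  B[0] = 0;
  for (int j = 1; j <= n; ++j) {
    long long best = (B[j - 1] < INF) ? B[j - 1] + unc_cost : INF;
    int bu = -1, br = 0;
    for (int ui = 0; ui < nu; ++ui) {
      const std::string &u = units[ui];
      int m = (int)u.size();
      if (j >= m && S.compare(j - m, m, u) == 0)
        L[ui][j] = (j >= 2 * m ? L[ui][j - m] : 0) + 1;
      int mr = min_run[ui] < 2 ? 2 : min_run[ui];
      if (L[ui][j] >= mr) {
        long long a = INF; int r = 0;
        if (B[j - mr * m] < INF) {
          a = B[j - mr * m] + (long long)mr * copy_cost;
          r = mr;
        }
        if (L[ui][j] >= mr + 1 && A[ui][j - m] < INF &&
            A[ui][j - m] + copy_cost < a) {
          a = A[ui][j - m] + copy_cost; r = AR[ui][j - m] + 1;
        }
        A[ui][j] = a; AR[ui][j] = r;
        if (a < best) { best = a; bu = ui; br = r; }
      }
    }
    B[j] = best; chU[j] = bu; chR[j] = br;
  }
  std::vector<int> oS, oE, oU, oEd;
  int j = n;
  while (j > 0) {
    if (chU[j] < 0) {
      int e = j;
      while (j > 0 && chU[j] < 0) --j;
      oS.push_back(j); oE.push_back(e); oU.push_back(-1); oEd.push_back(0);
    } else {
      int m = (int)units[chU[j]].size();
      for (int r = 0; r < chR[j]; ++r) {
        oS.push_back(j - (r + 1) * m); oE.push_back(j - r * m);
        oU.push_back(chU[j]); oEd.push_back(0);
      }
      j -= chR[j] * m;
    }
  }
  std::reverse(oS.begin(), oS.end());
  std::reverse(oE.begin(), oE.end());
  std::reverse(oU.begin(), oU.end());
  std::reverse(oEd.begin(), oEd.end());
  IntegerVector unit1(oU.size());
  for (size_t i = 0; i < oU.size(); ++i)
    unit1[i] = (oU[i] < 0) ? NA_INTEGER : oU[i] + 1;
  return List::create(
    _["start"] = wrap(oS), _["end"] = wrap(oE),
    _["unit"] = unit1, _["edits"] = wrap(oEd),
    _["distance"] = 0.0, _["combined"] = (double)B[n]);
}

// [[Rcpp::export]]
List cpp_decompose(std::string S, std::vector<std::string> units,
                   int mismatch, int indel, int copy_cost, int unc_cost,
                   int exact = 0,
                   IntegerVector min_run = IntegerVector::create()) {
  if (exact == 2) {
    std::vector<int> mr(units.size(), 2);
    for (size_t i = 0; i < units.size(); ++i)
      if (min_run.size() > 0)
        mr[i] = min_run[i % min_run.size()];
    return exact_run_parse(S, units, copy_cost, unc_cost, mr);
  }
  const int n = (int)S.size();
  const int nu = (int)units.size();
  int cmax = std::max(std::max(mismatch, indel), std::max(copy_cost, unc_cost));
  if (cmax < 1) cmax = 1;
  const int64_t K = (int64_t)8 * (n + 2) * cmax + 16;
  const int64_t INF = (int64_t)1 << 62;

  std::vector<int64_t> B(n + 1, INF);
  std::vector<int> choice(n + 1, -2), segStart(n + 1, 0), segEdits(n + 1, 0);
  B[0] = 0;

  std::vector<std::vector<Cell> > prev(nu), cur(nu);
  for (int ui = 0; ui < nu; ++ui) {
    int m = (int)units[ui].size();
    prev[ui].assign(m + 1, Cell{INF, 0, 0});
    cur[ui].assign(m + 1, Cell{INF, 0, 0});
  }

  // seed column 0: a copy may start at the very beginning
  for (int ui = 0; ui < nu; ++ui) {
    int m = (int)units[ui].size();
    prev[ui][0] = Cell{(int64_t)copy_cost * K, 0, 0};
    if (!exact) {
      for (int k = 1; k <= m; ++k) {
        Cell c = prev[ui][k - 1];
        c.v += (int64_t)indel * K + indel;
        c.edits += indel;
        prev[ui][k] = c;
      }
    }
  }

  for (int j = 1; j <= n; ++j) {
    char sc = S[j - 1];
    // pass A: extend copies through S[j-1]
    for (int ui = 0; ui < nu; ++ui) {
      const std::string &u = units[ui];
      int m = (int)u.size();
      cur[ui][0] = Cell{INF, 0, 0};
      for (int k = 1; k <= m; ++k) {
        int sub = (sc == u[k - 1]) ? 0 : mismatch;
        Cell best{INF, 0, 0};
        // diagonal: consume S char against unit char
        if (prev[ui][k - 1].v < INF && !(exact && sub != 0)) {
          Cell c = prev[ui][k - 1];
          c.v += (int64_t)sub * K + sub;
          c.edits += sub;
          best = c;
        }
        if (!exact) {
          // up: S char is an insertion relative to the unit
          if (prev[ui][k].v < INF) {
            Cell c = prev[ui][k];
            c.v += (int64_t)indel * K + indel;
            c.edits += indel;
            if (c.v < best.v) best = c;
          }
          // left: unit char deleted
          if (cur[ui][k - 1].v < INF) {
            Cell c = cur[ui][k - 1];
            c.v += (int64_t)indel * K + indel;
            c.edits += indel;
            if (c.v < best.v) best = c;
          }
        }
        cur[ui][k] = best;
      }
    }
    // settle B[j]: uncovered base, or a completed copy
    int64_t bb = (B[j - 1] < INF) ? B[j - 1] + (int64_t)unc_cost * K : INF;
    int ch = -1, st = 0, ed = 0;
    for (int ui = 0; ui < nu; ++ui) {
      int m = (int)units[ui].size();
      if (cur[ui][m].v < bb) {
        bb = cur[ui][m].v;
        ch = ui; st = cur[ui][m].start; ed = cur[ui][m].edits;
      }
    }
    B[j] = bb;
    choice[j] = ch; segStart[j] = st; segEdits[j] = ed;
    // pass B: a fresh copy may start at boundary j (leading deletions allowed)
    for (int ui = 0; ui < nu; ++ui) {
      int m = (int)units[ui].size();
      cur[ui][0] = Cell{B[j] + (int64_t)copy_cost * K, j, 0};
      if (!exact) {
        for (int k = 1; k <= m; ++k) {
          Cell c = cur[ui][k - 1];
          if (c.v < INF) {
            c.v += (int64_t)indel * K + indel;
            c.edits += indel;
            if (c.v < cur[ui][k].v) cur[ui][k] = c;
          }
        }
      }
      std::swap(prev[ui], cur[ui]);
    }
  }

  // traceback
  std::vector<int> outStart, outEnd, outUnit, outEdits;
  int j = n;
  while (j > 0) {
    if (choice[j] == -1) {  // uncovered base; merge runs
      int e = j;
      while (j > 0 && choice[j] == -1) --j;
      outStart.push_back(j); outEnd.push_back(e);
      outUnit.push_back(-1); outEdits.push_back(0);
    } else {
      outStart.push_back(segStart[j]); outEnd.push_back(j);
      outUnit.push_back(choice[j]); outEdits.push_back(segEdits[j]);
      j = segStart[j];
    }
  }
  std::reverse(outStart.begin(), outStart.end());
  std::reverse(outEnd.begin(), outEnd.end());
  std::reverse(outUnit.begin(), outUnit.end());
  std::reverse(outEdits.begin(), outEdits.end());

  int64_t enc = B[n];
  int64_t dist = enc % K;
  int64_t combined = enc / K;
  IntegerVector unit1(outUnit.size());
  for (size_t i = 0; i < outUnit.size(); ++i)
    unit1[i] = (outUnit[i] < 0) ? NA_INTEGER : outUnit[i] + 1;
  return List::create(
    _["start"] = wrap(outStart), _["end"] = wrap(outEnd),
    _["unit"] = unit1, _["edits"] = wrap(outEdits),
    _["distance"] = (double)dist, _["combined"] = (double)combined);
}
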