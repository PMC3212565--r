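#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with linear gap cost.
// Scoring: match +1, mismatch -1, gap -2. Traceback recovers the number of
// matching columns, total alignment columns and the aligned spans on both
// sequences, which downstream code converts to identity and coverage of the
// shorter sequence.

struct SWResult {
  int score, matches, columns;
  int a_start, a_end, b_start, b_end; // 1-based inclusive; 0 if no alignment
};

static SWResult sw_core(const char *a, int na, const char *b, int nb) {
  const int MATCH = 1, MISMATCH = -1, GAP = -2;
  SWResult res = {0, 0, 0, 0, 0, 0, 0};
  if (na == 0 || nb == 0) return res;
  static std::vector<short> H; // score matrix, reused across calls
  H.assign((size_t)(na + 1) * (nb + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= na; ++i) {
    const short *hp = &H[(size_t)(i - 1) * (nb + 1)];
    short *hr = &H[(size_t)i * (nb + 1)];
    const char ai = a[i - 1];
    int rowbest = 0, rowj = 0;
    for (int j = 1; j <= nb; ++j) {
      int s = hp[j - 1] + (ai == b[j - 1] ? MATCH : MISMATCH);
      int sup = hp[j] + GAP;
      int sleft = hr[j - 1] + GAP;
      s = sup > s ? sup : s;
      s = sleft > s ? sleft : s;
      s = s > 0 ? s : 0;
      hr[j] = (short)s;
      int better = s > rowbest;
      rowbest = better ? s : rowbest;
      rowj = better ? j : rowj;
    }
    if (rowbest > best) { best = rowbest; bi = i; bj = rowj; }
  }
  if (best <= 0) return res;
  res.score = best;
  res.a_end = bi; res.b_end = bj;
  // traceback by recomputing transitions (preference: diag, up, left —
  // matching the forward maximisation order)
  int i = bi, j = bj;
  while (i > 0 && j > 0 && H[(size_t)i * (nb + 1) + j] > 0) {
    int h = H[(size_t)i * (nb + 1) + j];
    int sub = (a[i - 1] == b[j - 1] ? MATCH : MISMATCH);
    if (h == H[(size_t)(i - 1) * (nb + 1) + j - 1] + sub) {
      res.columns++;
      if (a[i - 1] == b[j - 1]) res.matches++;
      --i; --j;
    } else if (h == H[(size_t)(i - 1) * (nb + 1) + j] + GAP) {
      res.columns++;
      --i;
    } else {
      res.columns++;
      --j;
    }
  }
  res.a_start = i + 1; res.b_start = j + 1;
  return res;
}

// [[Rcpp::export(name = ".cpp_sw_batch")]]
IntegerMatrix cpp_sw_batch(CharacterVector a, CharacterVector b) {
  if (a.size() != b.size()) stop("length mismatch");
  int n = a.size();
  IntegerMatrix out(n, 7);
  colnames(out) = CharacterVector::create("score", "matches", "columns",
                                          "a_start", "a_end", "b_start", "b_end");
  for (int k = 0; k < n; ++k) {
    const char *sa = CHAR(STRING_ELT(a, k));
    const char *sb = CHAR(STRING_ELT(b, k));
    SWResult r = sw_core(sa, std::strlen(sa), sb, std::strlen(sb));
    out(k, 0) = r.score; out(k, 1) = r.matches; out(k, 2) = r.columns;
    out(k, 3) = r.a_start; out(k, 4) = r.a_end; out(k, 5) = r.b_start; out(k, 6) = r.b_end;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_sw_pair")]]
IntegerVector cpp_sw_pair(std::string a, std::string b) {
  SWResult r = sw_core(a.c_str(), a.size(), b.c_str(), b.size());
  IntegerVector out = IntegerVector::create(
    _["score"] = r.score, _["matches"] = r.matches, _["columns"] = r.columns,
    _["a_start"] = r.a_start, _["a_end"] = r.a_end,
    _["b_start"] = r.b_start, _["b_end"] = r.b_end);
  return out;
}

// Minimum unit-cost edit distance of `pat` against any substring of `sub`
// (semi-global / infix alignment): free leading and trailing gaps on the
// subject only. Full dynamic programme over all subject positions — this is
// the exhaustive reference used both as the brute-force scan and to verify
// the seeded assignment path.

// [[Rcpp::export(name = ".cpp_edit_infix")]]
IntegerVector cpp_edit_infix(CharacterVector pat, CharacterVector sub) {
  if (pat.size() != sub.size()) stop("length mismatch");
  int n = pat.size();
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    const char *p = CHAR(STRING_ELT(pat, k));
    const char *s = CHAR(STRING_ELT(sub, k));
    int np = std::strlen(p), ns = std::strlen(s);
    std::vector<int> prev(ns + 1, 0), cur(ns + 1, 0); // row 0: all zeros (free start)
    for (int i = 1; i <= np; ++i) {
      cur[0] = i;
      for (int j = 1; j <= ns; ++j) {
        int d = prev[j - 1] + (p[i - 1] == s[j - 1] ? 0 : 1);
        int u = prev[j] + 1, l = cur[j - 1] + 1;
        if (u < d) d = u;
        if (l < d) d = l;
        cur[j] = d;
      }
      std::swap(prev, cur);
    }
    int best = prev[0];
    for (int j = 1; j <= ns; ++j) if (prev[j] < best) best = prev[j];
    out[k] = best;
  }
  return out;
}

// Banded variant used by the seeded tag-assignment path: the pattern is
// expected to start near subject position `diag` (1-based), and only
// alignments within +/- band diagonals are scored. Positions outside the
// band are treated as unreachable.

// [[Rcpp::export(name = ".cpp_edit_infix_banded")]]
IntegerVector cpp_edit_infix_banded(CharacterVector pat, CharacterVector sub,
                                    IntegerVector diag, int band) {
  if (pat.size() != sub.size() || pat.size() != diag.size()) stop("length mismatch");
  int n = pat.size();
  const int INF = 1 << 28;
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    const char *p = CHAR(STRING_ELT(pat, k));
    const char *s = CHAR(STRING_ELT(sub, k));
    int np = std::strlen(p), ns = std::strlen(s);
    int d0 = diag[k]; // expected subject start position of pattern, 1-based
    int lo = d0 - 1 - band, hi = d0 - 1 + np + band; // subject window, 0-based half-open-ish
    if (lo < 0) lo = 0;
    if (hi > ns) hi = ns;
    if (lo >= hi) { out[k] = INF; continue; }
    int w = hi - lo;
    std::vector<int> prev(w + 1, 0), cur(w + 1, 0);
    for (int i = 1; i <= np; ++i) {
      cur[0] = i;
      for (int j = 1; j <= w; ++j) {
        int sj = lo + j; // subject prefix length consumed (window bounds the band)
        int d = prev[j - 1] + (p[i - 1] == s[sj - 1] ? 0 : 1);
        int u = prev[j] + 1, l = cur[j - 1] + 1;
        if (u < d) d = u;
        if (l < d) d = l;
        cur[j] = d;
      }
      std::swap(prev, cur);
    }
    int best = prev[0];
    for (int j = 1; j <= w; ++j) if (prev[j] < best) best = prev[j];
    out[k] = best;
  }
  return out;
}

// Per-base alignment depth helper for the annotation profiler: add +1 over
// [starts[i], ends[i]] (1-based inclusive) into a depth vector of length n.

// [[Rcpp::export(name = ".cpp_interval_depth")]]
NumericVector cpp_interval_depth(IntegerVector starts, IntegerVector ends, int n) {
  NumericVector depth(n);
  for (int k = 0; k < starts.size(); ++k) {
    int a = starts[k], b = ends[k];
    if (a < 1) a = 1;
    if (b > n) b = n;
    for (int i = a; i <= b; ++i) depth[i - 1] += 1.0;
  }
  return depth;
}
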