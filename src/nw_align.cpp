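#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Gotoh three-state global alignment with affine gaps.
// States: M = residue/residue column, X = gap in b (consumes a), Y = gap in a
// (consumes b).  A gap of length L costs gap_open + L * gap_extend; end gaps
// are penalized (true global alignment).  Tie-break on traceback: M > X > Y,
// applied both when choosing the final state and when choosing a predecessor,
// so the traceback is deterministic across platforms.
//
// a, b: 0-based integer codes into the rows/cols of `sub`.
// Returns the optimal score and the two gapped rows as index vectors where
// -1 marks a gap.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline int best3(double m, double x, double y) {
  // preference order M(0) > X(1) > Y(2) on ties
  if (m >= x && m >= y) return 0;
  if (x >= y) return 1;
  return 2;
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double go = gap_open + gap_extend;  // cost of first gap column
  const double ge = gap_extend;

  // DP matrices, (n+1) x (m+1), column-major index i + j*(n+1)
  const size_t sz = (size_t)(n + 1) * (m + 1);
  std::vector<double> M(sz, NEG_INF), X(sz, NEG_INF), Y(sz, NEG_INF);
  // predecessor state for each state/cell (0=M,1=X,2=Y), -1 unset
  std::vector<signed char> pM(sz, -1), pX(sz, -1), pY(sz, -1);

  auto idx = [n](int i, int j) { return (size_t)i + (size_t)j * (n + 1); };

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[idx(i, 0)] = -(go + (i - 1) * ge);
    pX[idx(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[idx(0, j)] = -(go + (j - 1) * ge);
    pY[idx(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int j = 1; j <= m; ++j) {
    for (int i = 1; i <= n; ++i) {
      const size_t c = idx(i, j);
      const size_t d = idx(i - 1, j - 1);
      const size_t u = idx(i - 1, j);
      const size_t l = idx(i, j - 1);

      const double s = sub(a[i - 1], b[j - 1]);
      int st = best3(M[d], X[d], Y[d]);
      double v = (st == 0 ? M[d] : (st == 1 ? X[d] : Y[d]));
      if (v > NEG_INF) { M[c] = v + s; pM[c] = (signed char)st; }

      double xm = M[u] - go, xx = X[u] - ge, xy = Y[u] - go;
      st = best3(xm, xx, xy);
      v = (st == 0 ? xm : (st == 1 ? xx : xy));
      if (v > NEG_INF) { X[c] = v; pX[c] = (signed char)st; }

      double ym = M[l] - go, yx = X[l] - go, yy = Y[l] - ge;
      st = best3(ym, yx, yy);
      v = (st == 0 ? ym : (st == 1 ? yx : yy));
      if (v > NEG_INF) { Y[c] = v; pY[c] = (signed char)st; }
    }
  }

  const size_t e = idx(n, m);
  int st = best3(M[e], X[e], Y[e]);
  const double score = (st == 0 ? M[e] : (st == 1 ? X[e] : Y[e]));

  // traceback
  std::vector<int> ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t c = idx(i, j);
    int prev;
    if (st == 0) {            // M: consumed a[i-1], b[j-1]
      prev = pM[c];
      ra.push_back(i - 1); rb.push_back(j - 1);
      --i; --j;
    } else if (st == 1) {     // X: consumed a[i-1], gap in b
      prev = pX[c];
      ra.push_back(i - 1); rb.push_back(-1);
      --i;
    } else {                  // Y: gap in a, consumed b[j-1]
      prev = pY[c];
      ra.push_back(-1); rb.push_back(j - 1);
      --j;
    }
    st = prev;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["score"] = score,
                      _["ia"] = IntegerVector(ra.begin(), ra.end()),
                      _["ib"] = IntegerVector(rb.begin(), rb.end()));
}

// Score-only variant sharing the same recurrences; used for the all-vs-all
// reciprocal-best-hit scan where the traceback of non-best pairs is wasted.
// [[Rcpp::export(name = ".nw_score_cpp")]]
double nw_score_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                    double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double go = gap_open + gap_extend;
  const double ge = gap_extend;

  std::vector<double> Mp(n + 1), Xp(n + 1), Yp(n + 1);
  std::vector<double> Mc(n + 1), Xc(n + 1), Yc(n + 1);

  Mp[0] = 0.0; Xp[0] = NEG_INF; Yp[0] = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    Mp[i] = NEG_INF; Yp[i] = NEG_INF;
    Xp[i] = -(go + (i - 1) * ge);
  }

  for (int j = 1; j <= m; ++j) {
    Mc[0] = NEG_INF; Xc[0] = NEG_INF;
    Yc[0] = -(go + (j - 1) * ge);
    for (int i = 1; i <= n; ++i) {
      const double s = sub(a[i - 1], b[j - 1]);
      double d = std::max(Mp[i - 1], std::max(Xp[i - 1], Yp[i - 1]));
      Mc[i] = (d > NEG_INF) ? d + s : NEG_INF;
      Xc[i] = std::max(Mc[i - 1] - go, std::max(Xc[i - 1] - ge, Yc[i - 1] - go));
      Yc[i] = std::max(Mp[i] - go, std::max(Xp[i] - go, Yp[i] - ge));
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  return std::max(Mp[n], std::max(Xp[n], Yp[n]));
}

// Batch score-only scan over candidate pairs (used by the RBH stage).
// seqs_a / seqs_b: lists of 0-based integer-coded sequences; pairs: 1-based
// (i, j) index pairs into them.
// [[Rcpp::export(name = ".nw_score_batch_cpp")]]
NumericVector nw_score_batch_cpp(List seqs_a, List seqs_b, IntegerMatrix pairs,
                                 NumericMatrix sub, double gap_open,
                                 double gap_extend) {
  const int n_pairs = pairs.nrow();
  NumericVector out(n_pairs);
  for (int r = 0; r < n_pairs; ++r) {
    IntegerVector a = seqs_a[pairs(r, 0) - 1];
    IntegerVector b = seqs_b[pairs(r, 1) - 1];
    out[r] = nw_score_cpp(a, b, sub, gap_open, gap_extend);
  }
  return out;
}
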