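#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh).
//
// Recurrences, 1-based over query i and hit j:
//   H(i,j) = max(0, H(i-1,j-1) + s(qi,hj), E(i,j), F(i,j))
//   E(i,j) = max(H(i,j-1) - gap_open, E(i,j-1) - gap_extend)   gap in query
//   F(i,j) = max(H(i-1,j) - gap_open, F(i-1,j) - gap_extend)   gap in hit
// so a gap of length L costs gap_open + (L-1) * gap_extend (EMBOSS water
// convention). Traceback starts at the maximal H cell (smallest (i,j) in
// row-major order among ties) and stops at the first cell of value 0.
// State preference at ties: diagonal, then gap-in-hit (F), then
// gap-in-query (E); within a gap run, closing the gap is preferred to
// extending it. All comparisons are exact: scores are sums of matrix
// integers and the two penalties, reproduced bit-identically on both the
// fill and traceback passes.
//
// qc / hc are 0-based row indices of each residue into S, or -1 when the
// matrix has no row for that letter (ambiguity codes): such pairs score 0.

// [[Rcpp::export]]
List sw_align_cpp(std::string q, std::string h,
                  IntegerVector qc, IntegerVector hc,
                  NumericMatrix S, double gap_open, double gap_extend) {
  const int n = q.size(), m = h.size();
  if (n == 0 || m == 0) stop("empty sequence");

  auto sc = [&](int i, int j) -> double {
    int a = qc[i - 1], b = hc[j - 1];
    if (a < 0 || b < 0) return 0.0;
    return S(a, b);
  };

  const double NEG = -1e100;
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), NEG);
  std::vector<double> F((n + 1) * (m + 1), NEG);
  auto at = [&](std::vector<double> &M, int i, int j) -> double & {
    return M[(size_t)i * (m + 1) + j];
  };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double e = std::max(at(H, i, j - 1) - gap_open,
                          at(E, i, j - 1) - gap_extend);
      double f = std::max(at(H, i - 1, j) - gap_open,
                          at(F, i - 1, j) - gap_extend);
      double d = at(H, i - 1, j - 1) + sc(i, j);
      double v = 0.0;
      if (d > v) v = d;
      if (e > v) v = e;
      if (f > v) v = f;
      at(E, i, j) = e;
      at(F, i, j) = f;
      at(H, i, j) = v;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0,
                        _["aligned_query"] = "", _["aligned_hit"] = "",
                        _["query_start"] = 0, _["query_end"] = 0,
                        _["hit_start"] = 0, _["hit_end"] = 0);
  }

  std::string aq, ah;  // built in reverse
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = E (gap in query), 2 = F (gap in hit)
  while (true) {
    if (state == 0) {
      double v = at(H, i, j);
      if (v == 0.0) break;
      if (i > 0 && j > 0 && at(H, i - 1, j - 1) + sc(i, j) == v) {
        aq.push_back(q[i - 1]); ah.push_back(h[j - 1]);
        --i; --j;
      } else if (at(F, i, j) == v) {
        state = 2;
      } else {
        state = 1;
      }
    } else if (state == 2) {  // gap in hit: consume query residue
      aq.push_back(q[i - 1]); ah.push_back('-');
      double v = at(F, i, j);
      if (at(H, i - 1, j) - gap_open == v) { --i; state = 0; }
      else { --i; }
    } else {  // gap in query: consume hit residue
      aq.push_back('-'); ah.push_back(h[j - 1]);
      double v = at(E, i, j);
      if (at(H, i, j - 1) - gap_open == v) { --j; state = 0; }
      else { --j; }
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(ah.begin(), ah.end());

  return List::create(_["score"] = best,
                      _["aligned_query"] = aq, _["aligned_hit"] = ah,
                      _["query_start"] = i + 1, _["query_end"] = bi,
                      _["hit_start"] = j + 1, _["hit_end"] = bj);
}
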