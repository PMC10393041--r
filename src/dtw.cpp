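#include <Rcpp.h>
using namespace Rcpp;

// Classic DTW dynamic program with absolute-difference local cost and step
// moves {(1,0),(0,1),(1,1)}; boundary path (0,0) -> (L1-1, L2-1).
// Optional Sakoe-Chiba band (band < 0 disables it). Rolling two-row DP keeps
// memory at O(min side) for the long raw records used in graph construction.
// [[Rcpp::export(name = ".dtw_dp")]]
double dtw_dp(NumericVector a, NumericVector b, int band = -1) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("dtw_distance: empty series");
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> prev(m, inf), cur(m, inf);
  for (int i = 0; i < n; ++i) {
    int jlo = 0, jhi = m - 1;
    if (band >= 0) {
      jlo = std::max(0, i - band);
      jhi = std::min(m - 1, i + band);
    }
    std::fill(cur.begin(), cur.end(), inf);
    for (int j = jlo; j <= jhi; ++j) {
      double cost = std::abs(a[i] - b[j]);
      double best;
      if (i == 0 && j == 0) best = 0.0;
      else {
        best = inf;
        if (i > 0) best = std::min(best, prev[j]);        // (1,0)
        if (j > 0) best = std::min(best, cur[j - 1]);     // (0,1)
        if (i > 0 && j > 0) best = std::min(best, prev[j - 1]); // (1,1)
      }
      cur[j] = cost + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
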