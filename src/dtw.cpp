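#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Banded (Sakoe-Chiba) dynamic time warping between equal-length series.
// Local cost |a_i - b_j|; steps (1,0), (0,1), (1,1); path constrained to
// |i - j| <= w; returns the optimal cumulative cost from (1,1) to (n,n)
// without path-length normalization.
//
// Two rolling rows are kept over the band only, so memory is O(w) and the
// inner loop touches at most n * (2w + 1) cells.
// [[Rcpp::export(name = ".dtw_band_cpp")]]
double dtw_band_cpp(NumericVector a, NumericVector b, int w) {
  const int n = a.size();
  if (b.size() != n)
    stop("signals must have equal length");
  if (n == 0)
    stop("empty signal");
  if (w < 0)
    stop("window must be non-negative");
  if (w > n - 1) w = n - 1;

  const double inf = std::numeric_limits<double>::infinity();
  const int bw = 2 * w + 1;

  // prev[k] holds D(i-1, j) with k = j - ((i-1) - w); cur likewise for row i
  std::vector<double> prev(bw + 1, inf), cur(bw + 1, inf);
  const double* pa = REAL(a);
  const double* pb = REAL(b);

  // Row 0: cumulative |a_0 - b_j| along the first row of the band.
  {
    const int jhi = std::min(n - 1, w);
    double acc = 0.0;
    for (int j = 0; j <= jhi; ++j) {
      acc += std::fabs(pa[0] - pb[j]);
      cur[j - (0 - w)] = acc;
    }
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), inf);
  }
  // Rows 1..n-1. With prev[k] = D(i-1, j-1) and prev[k+1] = D(i-1, j)
  // (indices shifted by one between consecutive rows), and all cells
  // outside the previous row's band holding +inf, no band-edge guards are
  // needed except for the first column of the current row (no insertion).
  for (int i = 1; i < n; ++i) {
    const int jlo = std::max(0, i - w);
    const int jhi = std::min(n - 1, i + w);
    const int base = i - w;  // column of cur[0]
    const double ai = pa[i];
    int k = jlo - base;
    cur[k] = std::min(prev[k + 1], prev[k]) + std::fabs(ai - pb[jlo]);
    for (int j = jlo + 1; j <= jhi; ++j) {
      ++k;
      double best = cur[k - 1];                            // insertion (0,1)
      if (prev[k + 1] < best) best = prev[k + 1];          // deletion (1,0)
      if (prev[k] < best) best = prev[k];                  // match (1,1)
      cur[k] = best + std::fabs(ai - pb[j]);
    }
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), inf);
  }
  // prev now holds row n-1; column n-1 sits at index (n-1) - ((n-1) - w) = w
  return prev[w];
}
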