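#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Fenwick tree over value ranks supporting k-th order statistic queries.
// Exact sliding min / median / variance for equal-width half-open windows:
// each sample enters and leaves the active set once as the two pointers
// advance, so the whole batch costs O((n + w) log n) regardless of overlap.
struct Fenwick {
  int m;
  std::vector<int> bit;
  explicit Fenwick(int m_) : m(m_), bit(m_ + 1, 0) {}
  void add(int i, int delta) {            // 1-based rank
    for (; i <= m; i += i & -i) bit[i] += delta;
  }
  int kth(int k) const {                   // k-th smallest rank present
    int pos = 0;
    int log = 1;
    while ((1 << log) <= m) ++log;
    for (int pw = 1 << (log - 1); pw > 0; pw >>= 1) {
      if (pos + pw <= m && bit[pos + pw] < k) {
        pos += pw;
        k -= bit[pos];
      }
    }
    return pos + 1;
  }
};

// [[Rcpp::export]]
NumericMatrix sliding_window_stats_cpp(NumericVector t, NumericVector x,
                                       NumericVector starts, double width) {
  const int n = t.size(), w = starts.size();
  NumericMatrix out(w, 7);  // n, mean, variance, sd, min, max, median
  std::fill(out.begin(), out.end(), NA_REAL);
  if (w == 0) return out;

  // rank-compress values
  std::vector<double> sorted(x.begin(), x.end());
  std::sort(sorted.begin(), sorted.end());
  sorted.erase(std::unique(sorted.begin(), sorted.end()), sorted.end());
  const int m = std::max<int>(1, sorted.size());
  std::vector<int> rank(n);
  for (int i = 0; i < n; ++i)
    rank[i] = 1 + (std::lower_bound(sorted.begin(), sorted.end(), x[i]) - sorted.begin());

  // center values to keep the sum-of-squares update well conditioned
  double xbar = 0;
  for (int i = 0; i < n; ++i) xbar += x[i];
  if (n > 0) xbar /= n;

  Fenwick fen(m);
  long double sum = 0.0L, sumsq = 0.0L;
  int lo = 0, hi = 0, cnt = 0;

  for (int k = 0; k < w; ++k) {
    const double a = starts[k], b = starts[k] + width;
    while (hi < n && t[hi] < b) {
      const double xc = x[hi] - xbar;
      fen.add(rank[hi], 1);
      sum += xc; sumsq += xc * xc;
      ++cnt; ++hi;
    }
    while (lo < hi && t[lo] < a) {
      const double xc = x[lo] - xbar;
      fen.add(rank[lo], -1);
      sum -= xc; sumsq -= xc * xc;
      --cnt; ++lo;
    }
    out(k, 0) = cnt;
    if (cnt == 0) continue;
    const long double mean_c = sum / cnt;
    const long double msq = sumsq / cnt;
    long double var = msq - mean_c * mean_c;          // population variance
    // cancellation dead-band: windows of identical values must report exactly 0
    if (var < 1e-9L * (msq + mean_c * mean_c)) var = 0;
    out(k, 1) = (double)(mean_c + xbar);
    out(k, 2) = (double)var;
    out(k, 3) = std::sqrt((double)var);
    out(k, 4) = sorted[fen.kth(1) - 1];
    out(k, 5) = sorted[fen.kth(cnt) - 1];
    if (cnt % 2 == 1)
      out(k, 6) = sorted[fen.kth((cnt + 1) / 2) - 1];
    else
      out(k, 6) = 0.5 * (sorted[fen.kth(cnt / 2) - 1] + sorted[fen.kth(cnt / 2 + 1) - 1]);
  }
  return out;
}
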