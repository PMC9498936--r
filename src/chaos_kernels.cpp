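#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact brute-force nearest-neighbor search with a Theiler (temporal)
// exclusion window. O(n^2); callers cap/stride n. Ties in distance are
// broken toward the smaller index for reproducibility.

// Kennel false-nearest-neighbor count for one dimension m.
// X: n x m embedded points; xnext: the (m+1)-th coordinate of each point;
// tidx: original time index of each point (striding-aware); theiler:
// minimum |t_i - t_j|; rt: distance-ratio threshold; atol: absolute floor
// on the extra-coordinate separation (suppresses ratio blow-up between
// numerically identical recurrences of noise-free periodic data); ra:
// attractor size for the loneliness criterion (a pair whose (m+1)-D
// separation exceeds amax * ra is false regardless of the ratio); pass
// ra <= 0 to disable the loneliness test.
// [[Rcpp::export]]
List fnn_count_cpp(NumericMatrix X, NumericVector xnext, IntegerVector tidx,
                   double theiler, double rt, double atol, double ra,
                   double amax) {
  const int n = X.nrow(), m = X.ncol();
  long long n_false = 0, n_valid = 0;
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int bj = -1;
    for (int j = 0; j < n; ++j) {
      if (std::abs((double)(tidx[i] - tidx[j])) <= theiler) continue;
      double d2 = 0.0;
      for (int c = 0; c < m; ++c) {
        double diff = X(i, c) - X(j, c);
        d2 += diff * diff;
        if (d2 >= best) break;
      }
      if (d2 < best || (d2 == best && (bj < 0 || j < bj))) {
        best = d2;
        bj = j;
      }
    }
    if (bj < 0) continue;
    ++n_valid;
    double dm = std::sqrt(best);
    double extra = std::abs(xnext[i] - xnext[bj]);
    bool is_false = false;
    if (extra > atol) {
      if (dm == 0.0 || extra / dm > rt) is_false = true;
    }
    if (!is_false && ra > 0.0) {
      double dnext = std::sqrt(dm * dm + extra * extra);
      if (dnext / ra > amax) is_false = true;
    }
    if (is_false) ++n_false;
  }
  return List::create(_["n_false"] = (double)n_false,
                      _["n_valid"] = (double)n_valid);
}

// Rosenstein mean log-divergence curve: for each base point find its
// nearest neighbor beyond the Theiler window, then track pair separation
// k steps forward. Points are assumed consecutive in time.
// [[Rcpp::export]]
List rosenstein_curve_cpp(NumericMatrix X, double theiler, int kmax) {
  const int n = X.nrow(), m = X.ncol();
  const int nbase = n - kmax;
  if (nbase < 2) stop("too few points for the requested divergence horizon");
  std::vector<double> sum_log(kmax + 1, 0.0);
  std::vector<long long> cnt(kmax + 1, 0);
  long long n_pairs = 0;
  for (int i = 0; i < nbase; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int bj = -1;
    for (int j = 0; j < nbase; ++j) {
      if (std::abs((double)(i - j)) <= theiler) continue;
      double d2 = 0.0;
      for (int c = 0; c < m; ++c) {
        double diff = X(i, c) - X(j, c);
        d2 += diff * diff;
        if (d2 >= best) break;
      }
      if (d2 < best || (d2 == best && (bj < 0 || j < bj))) {
        best = d2;
        bj = j;
      }
    }
    if (bj < 0) continue;
    ++n_pairs;
    for (int k = 0; k <= kmax; ++k) {
      double d2 = 0.0;
      for (int c = 0; c < m; ++c) {
        double diff = X(i + k, c) - X(bj + k, c);
        d2 += diff * diff;
      }
      if (d2 > 0.0) {
        sum_log[k] += 0.5 * std::log(d2);
        ++cnt[k];
      }
    }
  }
  NumericVector mean_log(kmax + 1), counts(kmax + 1);
  for (int k = 0; k <= kmax; ++k) {
    mean_log[k] = cnt[k] > 0 ? sum_log[k] / cnt[k] : NA_REAL;
    counts[k] = (double)cnt[k];
  }
  return List::create(_["mean_log"] = mean_log, _["count"] = counts,
                      _["n_pairs"] = (double)n_pairs);
}

// Grassberger-Procaccia pair counts: number of pairs (|i-j| > theiler)
// with distance <= r for each radius in the sorted grid r_sorted.
// [[Rcpp::export]]
List corr_count_cpp(NumericMatrix X, double theiler, NumericVector r_sorted) {
  const int n = X.nrow(), m = X.ncol(), nr = r_sorted.size();
  std::vector<double> r2(nr);
  for (int a = 0; a < nr; ++a) r2[a] = r_sorted[a] * r_sorted[a];
  const double r2max = r2[nr - 1];
  std::vector<long long> hist(nr, 0);
  long long n_pairs = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if ((double)(j - i) <= theiler) continue;
      ++n_pairs;
      double d2 = 0.0;
      for (int c = 0; c < m; ++c) {
        double diff = X(i, c) - X(j, c);
        d2 += diff * diff;
        if (d2 > r2max) break;
      }
      if (d2 > r2max) continue;
      // smallest radius index with r2 >= d2
      int lo = 0, hi = nr - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (r2[mid] >= d2) hi = mid; else lo = mid + 1;
      }
      ++hist[lo];
    }
  }
  NumericVector counts(nr);
  long long acc = 0;
  for (int a = 0; a < nr; ++a) {
    acc += hist[a];
    counts[a] = (double)acc;
  }
  return List::create(_["count"] = counts, _["n_pairs"] = (double)n_pairs);
}
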