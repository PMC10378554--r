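#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Counts swaps needed to sort y (merge sort); equals the number of
// discordant pairs when the input is ordered by x with ties in x broken by y.
static double merge_count(std::vector<double>& y, std::vector<double>& buf,
                          int lo, int hi) {
  if (hi - lo < 2) return 0.0;
  int mid = (lo + hi) / 2;
  double swaps = merge_count(y, buf, lo, mid) + merge_count(y, buf, mid, hi);
  int i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (y[j] < y[i]) {           // strict: ties are not inversions
      swaps += mid - i;
      buf[k++] = y[j++];
    } else {
      buf[k++] = y[i++];
    }
  }
  while (i < mid) buf[k++] = y[i++];
  while (j < hi) buf[k++] = y[j++];
  std::copy(buf.begin() + lo, buf.begin() + hi, y.begin() + lo);
  return swaps;
}

static double tie_term(const std::vector<double>& v) {
  double s = 0.0;
  size_t i = 0;
  while (i < v.size()) {
    size_t j = i;
    while (j < v.size() && v[j] == v[i]) ++j;
    double t = (double)(j - i);
    s += t * (t - 1.0) / 2.0;
    i = j;
  }
  return s;
}

// Kendall's tau-b via Knight's algorithm. Returns NA for a constant input.
// [[Rcpp::export(name = ".kendall_tau_cpp")]]
double kendall_tau_cpp(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n != y.size()) stop("x and y must have equal length");
  if (n < 2) stop("need at least 2 observations");
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });
  std::vector<double> xs(n), ys(n);
  for (int i = 0; i < n; ++i) { xs[i] = x[idx[i]]; ys[i] = y[idx[i]]; }

  double n0 = (double)n * (n - 1.0) / 2.0;
  double n1 = tie_term(xs);
  std::vector<double> ysorted(ys);
  std::sort(ysorted.begin(), ysorted.end());
  double n2 = tie_term(ysorted);

  // joint ties
  double n3 = 0.0;
  {
    int i = 0;
    while (i < n) {
      int j = i;
      while (j < n && xs[j] == xs[i] && ys[j] == ys[i]) ++j;
      double t = (double)(j - i);
      n3 += t * (t - 1.0) / 2.0;
      i = j;
    }
  }

  std::vector<double> buf(n);
  double swaps = merge_count(ys, buf, 0, n);
  double S = n0 - n1 - n2 + n3 - 2.0 * swaps;
  double den = std::sqrt((n0 - n1) * (n0 - n2));
  if (den <= 0.0) return NA_REAL;
  return S / den;
}
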