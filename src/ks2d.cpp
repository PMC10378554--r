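#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Fenwick (binary indexed) tree for dominance counting.
struct Fenwick {
  std::vector<int> t;
  int n;
  explicit Fenwick(int n_) : t(n_ + 1, 0), n(n_) {}
  void reset() { std::fill(t.begin(), t.end(), 0); }
  void add(int i) { for (; i <= n; i += i & (-i)) t[i]++; }
  int query(int i) const { int s = 0; for (; i > 0; i -= i & (-i)) s += t[i]; return s; }
};

// Two-sample Fasano-Franceschini statistic: max over pooled evaluation
// points, over the four closed quadrants, of the absolute difference in
// empirical fractions between the two samples. Points are given as x-order
// (ox, group-sorted by x ascending) and y-ranks (ry in 1..N).
static double ff_stat(const std::vector<int>& ox, const std::vector<int>& ry,
                      const std::vector<double>& xs, const IntegerVector& lab,
                      int n1, int n2, Fenwick& f1, Fenwick& f2) {
  int N = ox.size();
  f1.reset(); f2.reset();
  std::vector<int> cy1(N + 1), cy2(N + 1); // counts with y-rank <= r, per sample
  {
    std::vector<int> n1r(N + 1, 0), nallr(N + 1, 0);
    for (int i = 0; i < N; ++i) {
      nallr[ry[i]]++;
      if (lab[i] == 1) n1r[ry[i]]++;
    }
    int c1 = 0, call = 0;
    for (int r = 1; r <= N; ++r) {
      c1 += n1r[r]; call += nallr[r];
      cy1[r] = c1; cy2[r] = call - c1;
    }
  }
  double D = 0.0;
  int cx1 = 0, cx2 = 0; // counts with x <= current, per sample
  int i = 0;
  while (i < N) {
    int j = i;
    // insert the whole group of tied x first so that "<= x" is consistent
    while (j < N && xs[ox[j]] == xs[ox[i]]) {
      int p = ox[j];
      if (lab[p] == 1) { f1.add(ry[p]); cx1++; } else { f2.add(ry[p]); cx2++; }
      ++j;
    }
    for (int k = i; k < j; ++k) {
      int p = ox[k];
      int r = ry[p];
      double a11 = (double)f1.query(r) / n1;        // x<=, y<=
      double a21 = (double)f2.query(r) / n2;
      double b11 = (double)cx1 / n1 - a11;          // x<=, y>
      double b21 = (double)cx2 / n2 - a21;
      double c11 = (double)cy1[r] / n1 - a11;       // x>, y<=
      double c21 = (double)cy2[r] / n2 - a21;
      double d11 = 1.0 - (double)cx1 / n1 - c11;    // x>, y>
      double d21 = 1.0 - (double)cx2 / n2 - c21;
      double m = std::max(std::max(std::fabs(a11 - a21), std::fabs(b11 - b21)),
                          std::max(std::fabs(c11 - c21), std::fabs(d11 - d21)));
      if (m > D) D = m;
    }
    i = j;
  }
  return D;
}

// Two-sample 2-D KS test with permutation p-value. x, y: pooled coordinates
// (first n1 from sample 1); n_perm label permutations use R's RNG.
// [[Rcpp::export(name = ".ks2d_perm_cpp")]]
List ks2d_perm_cpp(NumericVector x, NumericVector y, int n1, int n_perm) {
  int N = x.size();
  if (y.size() != N) stop("x and y must have equal length");
  int n2 = N - n1;
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty");

  std::vector<double> xs(x.begin(), x.end());
  std::vector<int> ox(N), oy(N);
  for (int i = 0; i < N; ++i) { ox[i] = i; oy[i] = i; }
  std::sort(ox.begin(), ox.end(), [&](int a, int b) { return xs[a] < xs[b]; });
  std::sort(oy.begin(), oy.end(), [&](int a, int b) {
    if (y[a] != y[b]) return y[a] < y[b];
    return a < b;
  });
  // tie-aware ranks: every member of a tied group gets the group's maximum
  // rank, so "rank <= r" means "value <= y"
  std::vector<int> ry(N);
  {
    int r = 0;
    while (r < N) {
      int r2 = r;
      while (r2 + 1 < N && y[oy[r2 + 1]] == y[oy[r]]) ++r2;
      for (int k = r; k <= r2; ++k) ry[oy[k]] = r2 + 1;
      r = r2 + 1;
    }
  }

  IntegerVector lab(N);
  for (int i = 0; i < N; ++i) lab[i] = (i < n1) ? 1 : 2;

  Fenwick f1(N), f2(N);
  double D = ff_stat(ox, ry, xs, lab, n1, n2, f1, f2);

  double p = NA_REAL;
  if (n_perm > 0) {
    RNGScope scope;
    int ge = 0;
    IntegerVector plab = clone(lab);
    for (int b = 0; b < n_perm; ++b) {
      // Fisher-Yates with R's RNG so set.seed() controls reproducibility
      for (int i = N - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(plab[i], plab[j]);
      }
      double Db = ff_stat(ox, ry, xs, plab, n1, n2, f1, f2);
      if (Db >= D) ge++;
    }
    p = (1.0 + ge) / (n_perm + 1.0);
  }
  return List::create(_["statistic"] = D, _["p_value"] = p);
}
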