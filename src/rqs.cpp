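#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Rational-quadratic spline machinery for the coupling flow. Raw parameters
// theta (per sample, length P = 3K+1) decode to K bin widths and heights
// (softmax, floored) and K+1 positive knot derivatives (softplus, floored).
// The spline maps [0,1] -> [0,1] monotonically.

static const double MIN_BIN = 1e-3;
static const double MIN_DERIV = 1e-3;

static inline double softplus(double x) {
  return x > 30 ? x : std::log1p(std::exp(x));
}

// Evaluate the spline and its log-derivative for one sample.
static inline void rqs_one(const double* th, int K, double x,
                           double& y, double& logdet,
                           std::vector<double>& kx, std::vector<double>& ky,
                           std::vector<double>& dv) {
  // softmax widths and heights
  double mx = th[0], mh = th[K];
  for (int k = 1; k < K; ++k) {
    if (th[k] > mx) mx = th[k];
    if (th[K + k] > mh) mh = th[K + k];
  }
  double sw = 0, sh = 0;
  for (int k = 0; k < K; ++k) {
    kx[k] = std::exp(th[k] - mx); sw += kx[k];
    ky[k] = std::exp(th[K + k] - mh); sh += ky[k];
  }
  double scale = 1.0 - K * MIN_BIN;
  double cx = 0, cy = 0;
  for (int k = 0; k < K; ++k) {
    double w = MIN_BIN + scale * kx[k] / sw;
    double h = MIN_BIN + scale * ky[k] / sh;
    kx[k] = cx; ky[k] = cy;  // left knot of bin k
    cx += w; cy += h;
  }
  kx[K] = 1.0; ky[K] = 1.0;
  for (int k = 0; k <= K; ++k) dv[k] = MIN_DERIV + softplus(th[2 * K + k]);

  if (x < 1e-9) x = 1e-9;
  if (x > 1 - 1e-9) x = 1 - 1e-9;
  int b = 0;
  while (b < K - 1 && x > kx[b + 1]) ++b;
  double xl = kx[b], xr = (b == K - 1) ? 1.0 : kx[b + 1];
  double yl = ky[b], yr = (b == K - 1) ? 1.0 : ky[b + 1];
  double w = xr - xl, h = yr - yl;
  double s = h / w;
  double xi = (x - xl) / w;
  if (xi < 0) xi = 0;
  if (xi > 1) xi = 1;
  double q = xi * (1 - xi);
  double dk = dv[b], dk1 = dv[b + 1];
  double denom = s + (dk1 + dk - 2 * s) * q;
  y = yl + h * (s * xi * xi + dk * q) / denom;
  if (y < 0) y = 0;
  if (y > 1) y = 1;
  double deriv = s * s * (dk1 * xi * xi + 2 * s * q + dk * (1 - xi) * (1 - xi))
    / (denom * denom);
  logdet = std::log(deriv > 1e-30 ? deriv : 1e-30);
}

// [[Rcpp::export(name = ".rqs_eval_cpp")]]
List rqs_eval_cpp(NumericVector x, NumericMatrix Theta, int K) {
  int n = x.size();
  int P = 3 * K + 1;
  if (Theta.ncol() != P || Theta.nrow() != n) stop("Theta must be n x (3K+1)");
  NumericVector y(n), logdet(n);
  std::vector<double> kx(K + 1), ky(K + 1), dv(K + 1), th(P);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < P; ++j) th[j] = Theta(i, j);
    double yi, ld;
    rqs_one(th.data(), K, x[i], yi, ld, kx, ky, dv);
    y[i] = yi; logdet[i] = ld;
  }
  return List::create(_["y"] = y, _["logdet"] = logdet);
}

// Analytic gradients of the per-sample value
//   val = gy * y(x, theta) - logdet(x, theta)
// w.r.t. the raw parameters theta and w.r.t. x. Chain: spline quantities
// (xi, bin width/height, knot offsets, derivatives) -> softmax / softplus.
// Validated in tests against the central-difference route below.
// [[Rcpp::export(name = ".rqs_grad_cpp")]]
List rqs_grad_analytic_cpp(NumericVector x, NumericMatrix Theta, int K,
                           NumericVector gy) {
  int n = x.size();
  int P = 3 * K + 1;
  if (Theta.ncol() != P || Theta.nrow() != n) stop("Theta must be n x (3K+1)");
  NumericMatrix Gtheta(n, P);
  NumericVector gx(n);
  double scale = 1.0 - K * MIN_BIN;
  std::vector<double> pw(K), ph(K), kx(K + 1), ky(K + 1), dv(K + 1),
    sig(K + 1);
  for (int i = 0; i < n; ++i) {
    // decode softmax widths/heights (probabilities kept for the chain rule)
    double mx = Theta(i, 0), mh = Theta(i, K);
    for (int k = 1; k < K; ++k) {
      if (Theta(i, k) > mx) mx = Theta(i, k);
      if (Theta(i, K + k) > mh) mh = Theta(i, K + k);
    }
    double sw = 0, sh = 0;
    for (int k = 0; k < K; ++k) {
      pw[k] = std::exp(Theta(i, k) - mx); sw += pw[k];
      ph[k] = std::exp(Theta(i, K + k) - mh); sh += ph[k];
    }
    double cx = 0, cy = 0;
    for (int k = 0; k < K; ++k) {
      pw[k] /= sw; ph[k] /= sh;
      kx[k] = cx; ky[k] = cy;
      cx += MIN_BIN + scale * pw[k];
      cy += MIN_BIN + scale * ph[k];
    }
    kx[K] = 1.0; ky[K] = 1.0;
    for (int k = 0; k <= K; ++k) {
      double c = Theta(i, 2 * K + k);
      dv[k] = MIN_DERIV + softplus(c);
      sig[k] = 1.0 / (1.0 + std::exp(-c));   // d softplus / dc
    }
    double xi0 = x[i];
    if (xi0 < 1e-9) xi0 = 1e-9;
    if (xi0 > 1 - 1e-9) xi0 = 1 - 1e-9;
    int b = 0;
    while (b < K - 1 && xi0 > kx[b + 1]) ++b;
    double xl = kx[b], xr = (b == K - 1) ? 1.0 : kx[b + 1];
    double yl = ky[b], yr = (b == K - 1) ? 1.0 : ky[b + 1];
    double w = xr - xl, h = yr - yl;
    double s = h / w;
    double xi = (xi0 - xl) / w;
    if (xi < 0) xi = 0;
    if (xi > 1) xi = 1;
    double q = xi * (1 - xi);
    double dk = dv[b], dk1 = dv[b + 1];
    double dq = 1 - 2 * xi;                  // dq/dxi
    double D = s + (dk1 + dk - 2 * s) * q;
    double A = s * xi * xi + dk * q;
    double Np = dk1 * xi * xi + 2 * s * q + dk * (1 - xi) * (1 - xi);
    double D2 = D * D;
    double g = gy[i];

    // partials of val = g*y - logdet w.r.t. spline quantities
    // y = yl + h*A/D ; logdet = 2 log s + log Np - 2 log D
    double dA_dxi = 2 * s * xi + dk * dq;
    double dD_dxi = (dk1 + dk - 2 * s) * dq;
    double dN_dxi = 2 * dk1 * xi + 2 * s * dq - 2 * dk * (1 - xi);
    double dval_dxi = g * h * (dA_dxi * D - A * dD_dxi) / D2
      - (dN_dxi / Np - 2 * dD_dxi / D);
    // s-direction (h and w enter through s and directly)
    double dA_ds = xi * xi;
    double dD_ds = 1 - 2 * q;
    double dval_ds = g * h * (dA_ds * D - A * dD_ds) / D2
      - (2 / s + 2 * q / Np - 2 * dD_ds / D);
    // derivatives at the two knots
    double dval_ddk = g * h * q * (D - A) / D2
      - ((1 - xi) * (1 - xi) / Np - 2 * q / D);
    double dval_ddk1 = -g * h * A * q / D2 - (xi * xi / Np - 2 * q / D);
    // primitive partials
    double dval_dyl = g;                               // y_b
    double dval_dh = g * A / D + dval_ds / w;          // h_b (s = h/w)
    double dval_dxl = dval_dxi * (-1.0 / w);           // x_b
    double dval_dw = dval_dxi * (-xi / w) + dval_ds * (-s / w);
    gx[i] = dval_dxi / w;

    // chain to raw width parameters: w_k = MIN_BIN + scale*p_k,
    // x_b = sum_{k<b} w_k ;  dval/dw_k = [k<b]*dval_dxl + [k==b]*dval_dw
    double dotw = 0, doth = 0;
    for (int k = 0; k < K; ++k) {
      double gk = (k < b) ? dval_dxl : (k == b ? dval_dw : 0.0);
      double hk = (k < b) ? dval_dyl : (k == b ? dval_dh : 0.0);
      dotw += gk * pw[k];
      doth += hk * ph[k];
    }
    for (int k = 0; k < K; ++k) {
      double gk = (k < b) ? dval_dxl : (k == b ? dval_dw : 0.0);
      double hk = (k < b) ? dval_dyl : (k == b ? dval_dh : 0.0);
      Gtheta(i, k) = scale * pw[k] * (gk - dotw);
      Gtheta(i, K + k) = scale * ph[k] * (hk - doth);
    }
    for (int k = 0; k <= K; ++k) {
      double gd = (k == b) ? dval_ddk : (k == b + 1 ? dval_ddk1 : 0.0);
      Gtheta(i, 2 * K + k) = gd * sig[k];
    }
  }
  return List::create(_["Gtheta"] = Gtheta, _["gx"] = gx);
}

// Gradients of the per-sample value  gy * y(x, theta) - logdet(x, theta)
// w.r.t. theta (central differences, step fd) and w.r.t. x. Kept as the
// independent reference route for the analytic gradients above.
// [[Rcpp::export(name = ".rqs_grad_fd_cpp")]]
List rqs_grad_cpp(NumericVector x, NumericMatrix Theta, int K,
                  NumericVector gy, double fd) {
  int n = x.size();
  int P = 3 * K + 1;
  NumericMatrix Gtheta(n, P);
  NumericVector gx(n);
  std::vector<double> kx(K + 1), ky(K + 1), dv(K + 1), th(P);
  double y, ld;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < P; ++j) th[j] = Theta(i, j);
    for (int j = 0; j < P; ++j) {
      double orig = th[j];
      th[j] = orig + fd;
      rqs_one(th.data(), K, x[i], y, ld, kx, ky, dv);
      double vp = gy[i] * y - ld;
      th[j] = orig - fd;
      rqs_one(th.data(), K, x[i], y, ld, kx, ky, dv);
      double vm = gy[i] * y - ld;
      th[j] = orig;
      Gtheta(i, j) = (vp - vm) / (2 * fd);
    }
    double xp = x[i] + fd < 1.0 ? x[i] + fd : 1.0;
    double xm = x[i] - fd > 0.0 ? x[i] - fd : 0.0;
    rqs_one(th.data(), K, xp, y, ld, kx, ky, dv);
    double vp = gy[i] * y - ld;
    rqs_one(th.data(), K, xm, y, ld, kx, ky, dv);
    double vm = gy[i] * y - ld;
    gx[i] = (vp - vm) / (xp - xm);
  }
  return List::create(_["Gtheta"] = Gtheta, _["gx"] = gx);
}
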