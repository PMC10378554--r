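#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Multiplicative-update (W)NMF core. V: strictly positive weights (all-ones
// for the unweighted case); M: observation mask (0 = held out, treated as
// missing: it multiplies V so masked entries enter neither numerators nor
// denominators). Regularization enters denominators elementwise as
// alpha1 + alpha2 * entry. The objective
//   sum(V*M*(X-WH)^2) + alpha1*(|W|+|H|) + alpha2/2*(||W||^2+||H||^2)
// is recorded every `obj_every` iterations (1 = every iteration);
// convergence is declared when the relative change between consecutive
// recorded values falls below `tol`.
// [[Rcpp::export(name = ".nmf_core_cpp")]]
Rcpp::List nmf_core_cpp(const arma::mat& X, const arma::mat& V,
                        const arma::mat& M, arma::mat W, arma::mat H,
                        double alpha1, double alpha2, int max_iter,
                        double tol, double eps, int obj_every = 1) {
  const bool masked = (M.n_elem == X.n_elem);
  const bool penalized = (alpha1 != 0.0 || alpha2 != 0.0);
  mat Ve = masked ? mat(V % M) : V;
  mat VX = Ve % X;
  mat WH(X.n_rows, X.n_cols), VWH(X.n_rows, X.n_cols);
  mat numW(W.n_rows, W.n_cols), denW(W.n_rows, W.n_cols);
  mat numH(H.n_rows, H.n_cols), denH(H.n_rows, H.n_cols);
  if (obj_every < 1) obj_every = 1;
  std::vector<double> trace;
  trace.reserve(max_iter / obj_every + 1);
  double prev = datum::inf;
  int it;
  for (it = 0; it < max_iter; ++it) {
    // W update
    WH = W * H;
    VWH = Ve % WH;
    numW = VX * H.t();
    denW = VWH * H.t();
    if (penalized) denW += alpha1 + alpha2 * W;
    denW += eps;
    W %= numW / denW;
    // H update (with the updated W)
    WH = W * H;
    VWH = Ve % WH;
    numH = W.t() * VX;
    denH = W.t() * VWH;
    if (penalized) denH += alpha1 + alpha2 * H;
    denH += eps;
    H %= numH / denH;

    if ((it + 1) % obj_every == 0 || it == max_iter - 1) {
      WH = W * H;
      double obj = accu(Ve % square(X - WH));
      if (penalized) {
        obj += alpha1 * (accu(abs(W)) + accu(abs(H)))
          + 0.5 * alpha2 * (accu(square(W)) + accu(square(H)));
      }
      trace.push_back(obj);
      if (it + 1 >= 10 && std::isfinite(prev)) {
        double rel = std::fabs(prev - obj) / (std::fabs(prev) + 1e-300);
        if (rel < tol) { ++it; break; }
      }
      prev = obj;
    }
  }
  return Rcpp::List::create(Rcpp::_["W"] = W, Rcpp::_["H"] = H,
                            Rcpp::_["objective"] = trace,
                            Rcpp::_["iterations"] = it);
}
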