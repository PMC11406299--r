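#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Hierarchical alternating least squares (block coordinate descent) for
//   min ||X - W H||_F^2  s.t. W >= 0, H >= 0.
// Each column of W / row of H is updated in closed form; every block update
// is non-increasing in the loss, so the recorded trace is monotone.
// Stopping: relative decrease of the loss below tol (relative to the
// first recorded loss), or max_iter outer iterations.
// [[Rcpp::export]]
Rcpp::List nmf_hals_cpp(const arma::mat& X, arma::mat W, arma::mat H,
                        int max_iter, double tol) {
  const double eps = 1e-12;
  const uword K = W.n_cols;
  std::vector<double> trace;
  trace.reserve(max_iter);
  double loss0 = -1.0, prev = datum::inf;

  for (int it = 0; it < max_iter; ++it) {
    // --- update W, column by column ---
    mat HHt = H * H.t();           // K x K
    mat XHt = X * H.t();           // v x K
    for (uword k = 0; k < K; ++k) {
      double denom = HHt(k, k);
      if (denom < eps) continue;   // degenerate component: leave untouched
      vec wk = W.col(k) + (XHt.col(k) - W * HHt.col(k)) / denom;
      wk.transform([](double x) { return x > 0.0 ? x : 0.0; });
      W.col(k) = wk;
    }
    // --- update H, row by row ---
    mat WtW = W.t() * W;           // K x K
    mat WtX = W.t() * X;           // K x n
    for (uword k = 0; k < K; ++k) {
      double denom = WtW(k, k);
      if (denom < eps) continue;
      rowvec hk = H.row(k) + (WtX.row(k) - WtW.row(k) * H) / denom;
      hk.transform([](double x) { return x > 0.0 ? x : 0.0; });
      H.row(k) = hk;
    }

    double loss = accu(square(X - W * H));
    trace.push_back(loss);
    if (loss0 < 0.0) loss0 = std::max(loss, eps);
    if (std::isfinite(prev) && (prev - loss) < tol * loss0) break;
    prev = loss;
  }

  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("H") = H,
                            Rcpp::Named("trace") = trace);
}
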