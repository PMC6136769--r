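#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Accumulates the sufficient statistics of the profiled REML log-likelihood
// of a random regression model whose marginal covariance is block-diagonal
// by genotype: V_g = Phi_a K_g Phi_a' + [plot-block] Phi_p K_p Phi_p' + R_g.
//
// Genotypes are grouped by observation "pattern" (identical basis rows,
// plot layout and harvest indices), so the Cholesky factor of the shared
// V block is computed once per pattern and reused for every genotype in
// the group.
//
// resid_type: 0 homogeneous, 1 diagonal per harvest, 2 unstructured
//             across harvests within a plot.
// rvar:  homogeneous -> length-1 variance; diagonal -> per-harvest variances.
// SigE:  unstructured residual covariance (nh x nh); ignored otherwise.
//
// Each element of `patterns` is a list with:
//   phi_a   n x Ma matrix (0 columns when the genetic term is dropped)
//   phi_p   n x Mp matrix (0 columns when the perm term is dropped)
//   plot    integer n-vector, plot label per record (within genotype)
//   harvest integer n-vector, 1-based measured-harvest index
//   X       (G*n) x p stacked fixed-effect rows, genotype-major
//   y       n x G response matrix
// [[Rcpp::export]]
Rcpp::List reml_core(const arma::mat& Kg, const arma::mat& Kp,
                     int resid_type, const arma::vec& rvar,
                     const arma::mat& SigE, const Rcpp::List& patterns) {
  double logdetV = 0.0, ytViy = 0.0;
  mat XtViX;
  vec XtViy;
  bool ok = true;
  const int npat = patterns.size();

  for (int k = 0; k < npat; ++k) {
    Rcpp::List pat = patterns[k];
    mat PhiA = Rcpp::as<mat>(pat["phi_a"]);
    mat PhiP = Rcpp::as<mat>(pat["phi_p"]);
    ivec plot = Rcpp::as<ivec>(pat["plot"]);
    ivec harv = Rcpp::as<ivec>(pat["harvest"]);
    mat Xs = Rcpp::as<mat>(pat["X"]);
    mat Y = Rcpp::as<mat>(pat["y"]);
    const int n = Y.n_rows, G = Y.n_cols, p = Xs.n_cols;
    if (XtViX.n_rows == 0) { XtViX.zeros(p, p); XtViy.zeros(p); }

    mat V(n, n, fill::zeros);
    if (PhiA.n_cols > 0) V = PhiA * Kg * PhiA.t();
    if (PhiP.n_cols > 0) {
      mat PKp = PhiP * Kp;   // n x Mp
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
          if (plot[i] == plot[j]) V(i, j) += dot(PKp.row(i), PhiP.row(j));
    }
    if (resid_type == 0) {
      V.diag() += rvar[0];
    } else if (resid_type == 1) {
      for (int i = 0; i < n; ++i) V(i, i) += rvar[harv[i] - 1];
    } else {
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
          if (plot[i] == plot[j]) V(i, j) += SigE(harv[i] - 1, harv[j] - 1);
    }

    mat L;
    if (!chol(L, V, "lower")) { ok = false; break; }
    logdetV += 2.0 * G * accu(log(L.diag()));

    for (int g = 0; g < G; ++g) {
      mat U = solve(trimatl(L), Xs.rows(g * n, g * n + n - 1));
      vec u = solve(trimatl(L), Y.col(g));
      XtViX += U.t() * U;
      XtViy += U.t() * u;
      ytViy += dot(u, u);
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("ok") = ok,
    Rcpp::Named("logdetV") = logdetV,
    Rcpp::Named("XtViX") = XtViX,
    Rcpp::Named("XtViy") = XtViy,
    Rcpp::Named("ytViy") = ytViy);
}
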