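// Gibbs sampler for the bivariate regression of (log annual cost, SPID) on a
// shared design matrix.
//
// Model: y_i ~ N2(B' x_i, Sigma), B is p x 2.
// Priors: vec(B) ~ N(0, prior_var * I_{2p}) (independent diffuse normal per
// coefficient); Omega = Sigma^{-1} ~ Wishart(df0, scale R0) in the BUGS
// dwish(R, k) convention, so the full conditional is
//   Omega | B, Y ~ Wishart(df0 + n, (R0 + E'E)^{-1})
// with E = Y - X B.  The coefficient full conditional is
//   vec(B) | Omega, Y ~ N(m, P^{-1}),
//   P = Omega (x) X'X + prior_var^{-1} I,  m = P^{-1} vec(X'Y Omega).
//
// All random numbers come from R's RNG so set.seed() gives bit-identical
// chains.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Wishart draw via Bartlett decomposition, using R's RNG.
// scale = S (so E[W] = df * S); returns one draw.
static arma::mat rwishart_bartlett(double df, const arma::mat& S) {
  const arma::uword p = S.n_rows;
  arma::mat L = arma::chol(S, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (arma::uword i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - static_cast<double>(i)));
    for (arma::uword j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

// [[Rcpp::export(name = ".gibbs_bivariate_cpp")]]
List gibbs_bivariate_cpp(const arma::mat& X, const arma::mat& Y,
                         double prior_var, double wishart_df,
                         const arma::mat& wishart_scale,
                         int burn_in, int kept, int thin) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  if (Y.n_rows != n || Y.n_cols != 2)
    stop("Y must be n x 2");
  arma::mat XtX = X.t() * X;
  arma::mat XtY = X.t() * Y;

  // collinearity check up front so the error names the offending columns
  arma::vec sv = arma::svd(XtX);
  if (sv.min() < 1e-10 * sv.max())
    stop("singular design matrix (collinear covariates)");

  // initialize at least squares
  arma::mat B = arma::solve(XtX, XtY);
  arma::mat E = Y - X * B;
  arma::mat Omega = arma::inv_sympd(
      (E.t() * E) / std::max(1.0, static_cast<double>(n) - p) +
      1e-8 * arma::eye(2, 2));

  const int n_out = kept / thin;
  arma::mat beta1_out(n_out, p), beta2_out(n_out, p), sigma_out(n_out, 3);

  const arma::uword q = 2 * p;
  arma::mat Iq = arma::eye(q, q);
  int stored = 0;
  for (int it = 0; it < burn_in + kept; ++it) {
    // coefficients | Omega
    arma::mat P = arma::kron(Omega, XtX) + (1.0 / prior_var) * Iq;
    arma::vec rhs = arma::vectorise(XtY * Omega);
    arma::mat U = arma::chol(P);              // P = U'U
    arma::vec m = arma::solve(P, rhs);
    arma::vec z(q);
    for (arma::uword k = 0; k < q; ++k) z(k) = R::norm_rand();
    arma::vec b = m + arma::solve(arma::trimatu(U), z);
    B = arma::reshape(b, p, 2);

    // Omega | coefficients
    E = Y - X * B;
    arma::mat scale_post =
        arma::inv_sympd(wishart_scale + E.t() * E);
    Omega = rwishart_bartlett(wishart_df + static_cast<double>(n),
                              scale_post);

    if (it >= burn_in && ((it - burn_in) % thin == 0) && stored < n_out) {
      arma::mat Sigma = arma::inv_sympd(Omega);
      beta1_out.row(stored) = B.col(0).t();
      beta2_out.row(stored) = B.col(1).t();
      sigma_out(stored, 0) = Sigma(0, 0);
      sigma_out(stored, 1) = Sigma(1, 1);
      sigma_out(stored, 2) = Sigma(0, 1);
      ++stored;
    }
  }
  return List::create(_["beta1"] = beta1_out,
                      _["beta2"] = beta2_out,
                      _["sigma"] = sigma_out);
}
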