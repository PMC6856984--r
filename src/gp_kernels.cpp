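// Dense kernel and Gaussian-process likelihood kernels used by the local
// (K-nearest-neighbour) and low-rank emulators.  Matrices are small
// (typically K = 100 neighbours), so everything is dense Armadillo.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// ARD squared-exponential covariance between row sets X1 (n1 x d), X2 (n2 x d).
// sf2 is the output scale squared (function variance).
// [[Rcpp::export]]
arma::mat cpp_cov_ard_se(const arma::mat& X1, const arma::mat& X2,
                         const arma::vec& ls, double sf2) {
  const uword n1 = X1.n_rows, n2 = X2.n_rows, d = X1.n_cols;
  mat Q(n1, n2, fill::zeros);
  for (uword k = 0; k < d; ++k) {
    vec a = X1.col(k) / ls(k);
    vec b = X2.col(k) / ls(k);
    Q += square(repmat(a, 1, n2) - repmat(b.t(), n1, 1));
  }
  return sf2 * exp(-0.5 * Q);
}

// Isotropic Matern 3/2 covariance (unit output scale unless sf2 given).
// [[Rcpp::export]]
arma::mat cpp_cov_matern32(const arma::mat& X1, const arma::mat& X2,
                           double len, double sf2) {
  const uword n1 = X1.n_rows, n2 = X2.n_rows, d = X1.n_cols;
  mat Q(n1, n2, fill::zeros);
  for (uword k = 0; k < d; ++k) {
    vec a = X1.col(k);
    vec b = X2.col(k);
    Q += square(repmat(a, 1, n2) - repmat(b.t(), n1, 1));
  }
  mat R = sqrt(Q) * (std::sqrt(3.0) / len);
  return sf2 * (1.0 + R) % exp(-R);
}

static bool chol_jitter(mat& L, const mat& A, double& jitter_used) {
  // Attempt Cholesky with escalating jitter relative to the mean diagonal.
  double scale = mean(A.diag());
  const double steps[] = {0.0, 1e-10, 1e-9, 1e-8, 1e-7, 1e-6, 1e-5, 1e-4,
                          1e-3, 1e-2};
  for (double s : steps) {
    mat Aj = A;
    if (s > 0) Aj.diag() += s * scale;
    if (chol(L, Aj, "lower")) { jitter_used = s * scale; return true; }
  }
  return false;
}

// Per-dimension squared differences of design rows, computed once per local
// fit and reused across every likelihood evaluation.
// [[Rcpp::export]]
arma::cube cpp_dist2_cube(const arma::mat& X) {
  const uword n = X.n_rows, d = X.n_cols;
  cube S(n, n, d);
  for (uword k = 0; k < d; ++k) {
    const vec a = X.col(k);
    mat& Sk = S.slice(k);
    for (uword j = 0; j < n; ++j)
      for (uword i = 0; i < n; ++i) {
        double dd = a(i) - a(j);
        Sk(i, j) = dd * dd;
      }
  }
  return S;
}

// Negative log marginal likelihood of a constant-mean GP with ARD-SE kernel,
// with the constant mean profiled out analytically (ordinary-kriging mean).
// par = (log ls_1..log ls_d, log sf, log sigma); if fixed_sigma >= 0 the last
// entry is absent and sigma is held at fixed_sigma. S is the precomputed
// squared-difference cube from cpp_dist2_cube.
// Returns value, gradient (same length as par) and the profiled mean.
// [[Rcpp::export]]
Rcpp::List cpp_nll_ard_se_cached(const arma::vec& par, const arma::cube& S,
                                 const arma::vec& y, double fixed_sigma) {
  const uword n = S.n_rows, d = S.n_slices;
  const bool fixn = fixed_sigma >= 0.0;
  vec ls2 = exp(2.0 * par.subvec(0, d - 1));
  double sf = std::exp(par(d));
  double sigma = fixn ? fixed_sigma : std::exp(par(d + 1));
  double sf2 = sf * sf, s2 = sigma * sigma;

  mat Q(n, n, fill::zeros);
  for (uword k = 0; k < d; ++k) Q += S.slice(k) / ls2(k);
  mat R = exp(-0.5 * Q);
  mat A = sf2 * R;
  A.diag() += s2;

  mat L;
  double jit;
  if (!chol_jitter(L, A, jit)) {
    return Rcpp::List::create(Rcpp::Named("value") = 1e10,
                              Rcpp::Named("gradient") = vec(par.n_elem, fill::zeros),
                              Rcpp::Named("mean") = mean(y),
                              Rcpp::Named("ok") = false);
  }
  mat Li = inv(trimatl(L));      // chol succeeded, so the diagonal is > 0
  mat Ainv = Li.t() * Li;
  vec Ai1 = sum(Ainv, 1);
  double c = dot(Ai1, y) / accu(Ai1);
  vec r = y - c;
  vec alpha = Ainv * r;
  double logdet = 2.0 * sum(log(L.diag()));
  double nll = 0.5 * dot(r, alpha) + 0.5 * logdet +
               0.5 * n * std::log(2.0 * M_PI);

  // grad_p = 0.5 sum_ij W_ij dA_ij, W = Ainv - alpha alpha' (envelope
  // theorem covers the profiled mean); single symmetric pass
  vec grad(par.n_elem, fill::zeros);
  double gsf = 0.0, gtr = 0.0;
  for (uword j = 0; j < n; ++j) {
    for (uword i = j; i < n; ++i) {
      const double mult = (i == j) ? 1.0 : 2.0;
      const double w = Ainv(i, j) - alpha(i) * alpha(j);
      const double wr = mult * w * sf2 * R(i, j);
      gsf += wr;
      if (i == j) gtr += w;
      for (uword k = 0; k < d; ++k)
        grad(k) += 0.5 * wr * S(i, j, k) / ls2(k);
    }
  }
  grad(d) = gsf;  // 0.5 * sum(W o 2 sf2 R)
  if (!fixn) grad(d + 1) = gtr * s2;
  return Rcpp::List::create(Rcpp::Named("value") = nll,
                            Rcpp::Named("gradient") = grad,
                            Rcpp::Named("mean") = c,
                            Rcpp::Named("ok") = true);
}

// convenience wrapper computing the distance cube on the fly
// [[Rcpp::export]]
Rcpp::List cpp_nll_ard_se(const arma::vec& par, const arma::mat& X,
                          const arma::vec& y, double fixed_sigma) {
  return cpp_nll_ard_se_cached(par, cpp_dist2_cube(X), y, fixed_sigma);
}

// Factorise a GP on (X, y) at given hyperparameters: returns the Cholesky
// factor of sf^2 R + sigma^2 I (with any jitter used), the profiled constant
// mean and the weight vector alpha = A^-1 (y - c).
// [[Rcpp::export]]
Rcpp::List cpp_gp_factor(const arma::mat& X, const arma::vec& y,
                         const arma::vec& ls, double sf, double sigma) {
  mat A = cpp_cov_ard_se(X, X, ls, sf * sf);
  A.diag() += sigma * sigma;
  mat L;
  double jit;
  if (!chol_jitter(L, A, jit))
    Rcpp::stop("covariance factorization failed even after jitter escalation to 1e-2");
  vec one(X.n_rows, fill::ones);
  vec u = solve(trimatl(L), y);
  vec v = solve(trimatl(L), one);
  vec Ainv_y = solve(trimatu(L.t()), u);
  vec Ainv_1 = solve(trimatu(L.t()), v);
  double c = dot(Ainv_1, y) / dot(Ainv_1, one);
  vec alpha = Ainv_y - c * Ainv_1;
  return Rcpp::List::create(Rcpp::Named("L") = L,
                            Rcpp::Named("alpha") = alpha,
                            Rcpp::Named("mean") = c,
                            Rcpp::Named("jitter") = jit);
}

// Predictive mean (and optionally latent variance) at rows of Xstar.
// [[Rcpp::export]]
Rcpp::List cpp_gp_predict(const arma::mat& Xstar, const arma::mat& X,
                          const arma::vec& ls, double sf,
                          const arma::mat& L, const arma::vec& alpha,
                          double mean_const, bool want_var) {
  mat Ks = cpp_cov_ard_se(X, Xstar, ls, sf * sf);  // n x m
  vec mu = mean_const + Ks.t() * alpha;
  if (!want_var)
    return Rcpp::List::create(Rcpp::Named("mean") = mu);
  mat V = solve(trimatl(L), Ks);
  vec var = sf * sf - sum(square(V), 0).t();
  var.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  return Rcpp::List::create(Rcpp::Named("mean") = mu,
                            Rcpp::Named("var") = var);
}
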