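#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Single-site Gibbs sampler for Bayesian ridge regression
//   y = mu + X beta + eps,  beta_j ~ N(0, sigma_beta^2),
//   sigma_beta^2 ~ scaled-inv-chi^2(df_beta, S_beta),
//   eps_i ~ N(0, sigma_eps^2), sigma_eps^2 ~ scaled-inv-chi^2(df_eps, S_eps).
// The scaled-inv-chi^2(df, S) draw is (SS + df*S)/chisq(df + k).
// X is expected column-centred by the caller so the intercept and marker
// effects are conditionally independent. With fix_var = true the two variance
// components are held at their initial values (ridge-equivalence mode).
// [[Rcpp::export]]
List cpp_brr_gibbs(const NumericVector y, const NumericMatrix X,
                   const int iter, const int burnin, const int thin,
                   const double df_beta, const double S_beta,
                   const double df_eps, const double S_eps,
                   const bool fix_var,
                   const double sigma_beta_sq0, const double sigma_eps_sq0) {
  const int n = X.nrow();
  const int p = X.ncol();
  const int L = (iter - burnin) / thin;

  NumericVector b(p, 0.0);
  NumericVector x2(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    x2[j] = s;
  }

  double mu = Rcpp::mean(y);
  double sb = sigma_beta_sq0, se = sigma_eps_sq0;
  NumericVector e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  NumericMatrix beta_samp(L, p);
  NumericVector sb_samp(L), se_samp(L), mu_samp(L);

  int stored = 0;
  for (int it = 1; it <= iter; ++it) {
    // intercept
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    const double mu_new = mu + ebar + norm_rand() * std::sqrt(se / n);
    const double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;

    // marker effects
    const double lambda = se / sb;
    double *ep = REAL(e);
    for (int j = 0; j < p; ++j) {
      const double bj = b[j];
      if (x2[j] <= 0.0) {           // monomorphic marker: conditional = prior
        b[j] = norm_rand() * std::sqrt(sb);
        continue;
      }
      const double *xj = &X(0, j);
      double rhs = x2[j] * bj;
      for (int i = 0; i < n; ++i) rhs += xj[i] * ep[i];
      const double cj = x2[j] + lambda;
      const double bnew = rhs / cj + norm_rand() * std::sqrt(se / cj);
      const double db = bnew - bj;
      if (db != 0.0) for (int i = 0; i < n; ++i) ep[i] -= xj[i] * db;
      b[j] = bnew;
    }

    if (!fix_var) {
      double bb = 0.0;
      for (int j = 0; j < p; ++j) bb += b[j] * b[j];
      sb = (bb + df_beta * S_beta) / R::rchisq(p + df_beta);
      double ee = 0.0;
      for (int i = 0; i < n; ++i) ee += e[i] * e[i];
      se = (ee + df_eps * S_eps) / R::rchisq(n + df_eps);
    }

    if (it > burnin && (it - burnin) % thin == 0 && stored < L) {
      for (int j = 0; j < p; ++j) beta_samp(stored, j) = b[j];
      sb_samp[stored] = sb;
      se_samp[stored] = se;
      mu_samp[stored] = mu;
      ++stored;
    }
  }

  return List::create(_["beta"] = beta_samp,
                      _["sigma_beta_sq"] = sb_samp,
                      _["sigma_eps_sq"] = se_samp,
                      _["mu"] = mu_samp);
}
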