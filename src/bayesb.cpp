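// Single-site Gibbs sampler for a spike-and-slab marker-effect model:
//   y = mu + X beta + e,  beta_j = 0 with prob 1 - pi,
//   beta_j | in ~ N(0, sigma2_j),  sigma2_j ~ scaled-inv-chi2(df0, S0)
//   e ~ N(0, I sigma2_e),  sigma2_e ~ scaled-inv-chi2(dfe, Se),
//   pi ~ Beta(1, 1) (prior mean 0.5) unless fixed.
// Uses R's RNG (set.seed() in R governs the chain).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_bayesb_gibbs(NumericMatrix X, NumericVector y, int n_iter,
                      int burn_in, double df0, double S0, double dfe,
                      double Se, double pi_fixed, double sigma2_beta_fixed,
                      double sigma2_e_fixed) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> xx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xx[j] = s;
  }

  double ybar = mean(y);
  double mu = ybar;
  double vy = var(y);
  if (vy <= 0) vy = 1e-8;
  double sigma2_e = sigma2_e_fixed > 0 ? sigma2_e_fixed : 0.5 * vy;
  double pi = pi_fixed > 0 ? pi_fixed : 0.5;
  std::vector<double> beta(p, 0.0), s2(p);
  for (int j = 0; j < p; ++j)
    s2[j] = sigma2_beta_fixed > 0 ? sigma2_beta_fixed
                                  : S0 * df0 / (df0 + 2.0); // prior mode
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i] - mu;

  std::vector<double> beta_sum(p, 0.0), incl_sum(p, 0.0);
  double mu_sum = 0, pi_sum = 0, s2e_sum = 0;
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double rs = 0;
    for (int i = 0; i < n; ++i) rs += r[i] + mu;
    double mu_new = rs / n + norm_rand() * std::sqrt(sigma2_e / n);
    for (int i = 0; i < n; ++i) r[i] += mu - mu_new;
    mu = mu_new;

    int n_incl = 0;
    for (int j = 0; j < p; ++j) {
      if (xx[j] <= 0) { beta[j] = 0; continue; }
      // residual with marker j excluded
      double rhs = 0;
      if (beta[j] != 0) {
        for (int i = 0; i < n; ++i) r[i] += X(i, j) * beta[j];
      }
      for (int i = 0; i < n; ++i) rhs += X(i, j) * r[i];

      double s2j = s2[j];
      double v = sigma2_e / (xx[j] + sigma2_e / s2j);
      double m = v * rhs / sigma2_e;
      // log Bayes factor inclusion vs exclusion
      double logBF = 0.5 * std::log(v / s2j) + 0.5 * m * m / v;
      bool include;
      if (pi >= 1.0) {
        include = true;
      } else {
        double lo = logBF + std::log(pi / (1.0 - pi));
        double prob = 1.0 / (1.0 + std::exp(-lo));
        include = unif_rand() < prob;
      }
      if (include) {
        beta[j] = m + norm_rand() * std::sqrt(v);
        for (int i = 0; i < n; ++i) r[i] -= X(i, j) * beta[j];
        ++n_incl;
      } else {
        beta[j] = 0;
      }

      if (sigma2_beta_fixed <= 0) {
        // scaled-inv-chi2 update (prior draw when excluded keeps chain proper)
        double df_post = include ? df0 + 1.0 : df0;
        double ss = include ? S0 * df0 + beta[j] * beta[j] : S0 * df0;
        s2[j] = ss / R::rchisq(df_post);
      }
      if (it >= burn_in) incl_sum[j] += include ? 1.0 : 0.0;
    }

    if (sigma2_e_fixed <= 0) {
      double ss = 0;
      for (int i = 0; i < n; ++i) ss += r[i] * r[i];
      sigma2_e = (ss + Se * dfe) / R::rchisq(n + dfe);
    }
    if (pi_fixed <= 0) {
      pi = R::rbeta(1.0 + n_incl, 1.0 + p - n_incl);
      if (pi < 1e-6) pi = 1e-6;
      if (pi > 1 - 1e-6) pi = 1 - 1e-6;
    }

    if (it >= burn_in) {
      for (int j = 0; j < p; ++j) beta_sum[j] += beta[j];
      mu_sum += mu; pi_sum += pi; s2e_sum += sigma2_e;
      ++kept;
    }
    if (it % 500 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector bhat(p), pip(p);
  for (int j = 0; j < p; ++j) {
    bhat[j] = beta_sum[j] / kept;
    pip[j] = incl_sum[j] / kept;
  }
  return List::create(_["beta"] = bhat, _["inclusion_prob"] = pip,
                      _["mu"] = mu_sum / kept, _["pi"] = pi_sum / kept,
                      _["sigma2_e"] = s2e_sum / kept);
}
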