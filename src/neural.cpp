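#include <Rcpp.h>
#include <functional>
#include "wfpt.h"
using namespace Rcpp;

// Hierarchical trial-by-trial regression of a standardized covariate onto a
// decision parameter. Per subject: intercept par0, slope beta, plus log a,
// logit z and log t0 nuisance parameters; all Normal around group means.
// target = 0 regresses onto the drift rate (v_i = par0 + beta * x_i),
// target = 1 onto boundary separation (a_i = exp(loga0 + beta * x_i)).

static double slice_scalar2(double x0, double w, int m,
                            const std::function<double(double)> &logf) {
  double f0 = logf(x0);
  if (!R_finite(f0)) return x0;
  double y = f0 + std::log(unif_rand());
  double u = unif_rand();
  double L = x0 - w * u;
  double R = L + w;
  int j = (int)std::floor(m * unif_rand());
  int k = m - 1 - j;
  while (j > 0 && logf(L) > y) { L -= w; --j; }
  while (k > 0 && logf(R) > y) { R += w; --k; }
  for (int it = 0; it < 100; ++it) {
    double x1 = L + unif_rand() * (R - L);
    if (logf(x1) > y) return x1;
    if (x1 < x0) L = x1; else R = x1;
  }
  return x0;
}

// [[Rcpp::export]]
List neural_reg_sampler_cpp(NumericVector rt, IntegerVector upper,
                            IntegerVector subj, NumericVector x,
                            int target, NumericVector prior_mean,
                            NumericVector prior_sd, NumericVector sigma_scale,
                            NumericVector slice_w, double q,
                            double log_contam, double eps,
                            int n_iter, int burn) {
  const int n = rt.size();
  int S = 0;
  for (int i = 0; i < n; ++i) S = std::max(S, subj[i] + 1);
  const int P = 5; // par0, beta, loga, logitz, logt0

  std::vector<std::vector<int>> trials(S);
  for (int i = 0; i < n; ++i) trials[subj[i]].push_back(i);

  std::vector<std::vector<double>> theta(S, std::vector<double>(P));
  std::vector<double> mu(P), sigma(P, 0.1);
  for (int p = 0; p < P; ++p) mu[p] = prior_mean[p];
  for (int s = 0; s < S; ++s)
    for (int p = 0; p < P; ++p) theta[s][p] = mu[p] + 0.01 * norm_rand();

  auto subj_loglik = [&](int s, const std::vector<double> &th) -> double {
    double ll = 0.0;
    double z = 1.0 / (1.0 + std::exp(-th[3]));
    double t0 = std::exp(th[4]);
    for (size_t j = 0; j < trials[s].size(); ++j) {
      int i = trials[s][j];
      double v, a;
      if (target == 0) {
        v = th[0] + th[1] * x[i];
        a = std::exp(th[2]);
      } else {
        v = th[0];
        a = std::exp(th[2] + th[1] * x[i]);
      }
      ll += wfpt_mix_log(rt[i], upper[i], v, a, z, t0, q, log_contam, eps);
      if (ll == R_NegInf) return R_NegInf;
    }
    return ll;
  };

  NumericMatrix mu_draws(n_iter, P), sigma_draws(n_iter, P);
  NumericMatrix theta_draws(n_iter, S * P);
  NumericVector deviance(n_iter);

  for (int it = 0; it < n_iter; ++it) {
    for (int s = 0; s < S; ++s) {
      for (int p = 0; p < P; ++p) {
        std::vector<double> th = theta[s];
        auto logpost = [&](double val) {
          th[p] = val;
          double d = (val - mu[p]) / sigma[p];
          return -0.5 * d * d + subj_loglik(s, th);
        };
        theta[s][p] = slice_scalar2(theta[s][p], slice_w[p], 10, logpost);
      }
    }
    for (int p = 0; p < P; ++p) {
      double sum = 0.0;
      for (int s = 0; s < S; ++s) sum += theta[s][p];
      double prec = S / (sigma[p] * sigma[p]) + 1.0 / (prior_sd[p] * prior_sd[p]);
      double mean = (sum / (sigma[p] * sigma[p]) +
                     prior_mean[p] / (prior_sd[p] * prior_sd[p])) / prec;
      mu[p] = mean + norm_rand() / std::sqrt(prec);
      auto logpost = [&](double lsig) {
        double sig = std::exp(lsig);
        double ss = 0.0;
        for (int s = 0; s < S; ++s) {
          double d = theta[s][p] - mu[p];
          ss += d * d;
        }
        return -S * lsig - ss / (2.0 * sig * sig) -
               sig * sig / (2.0 * sigma_scale[p] * sigma_scale[p]) + lsig;
      };
      sigma[p] = std::exp(slice_scalar2(std::log(sigma[p]), 0.5, 10, logpost));
    }
    for (int p = 0; p < P; ++p) {
      mu_draws(it, p) = mu[p];
      sigma_draws(it, p) = sigma[p];
    }
    for (int s = 0; s < S; ++s)
      for (int p = 0; p < P; ++p) theta_draws(it, s * P + p) = theta[s][p];
    double ll = 0.0;
    for (int s = 0; s < S; ++s) ll += subj_loglik(s, theta[s]);
    deviance[it] = -2.0 * ll;
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["mu"] = mu_draws, _["sigma"] = sigma_draws,
                      _["theta"] = theta_draws, _["deviance"] = deviance);
}
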