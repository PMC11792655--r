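#include <Rcpp.h>
#include <functional>
#include "wfpt.h"
using namespace Rcpp;

// Hierarchical drift-diffusion sampler.
//
// Parameter types are indexed 0..3 = v, a, z, t0 and sampled on unconstrained
// scales (v identity, log a, logit z, log t0). Subject-level parameters
// theta[type][subject][cell] are Normal around their group's mean
// mu[type][group][cell] with a cell-wise sd sigma[type][cell] shared across
// groups. Group means get Normal priors (conjugate update); sds get
// Half-Normal priors (slice update on log sigma); subject parameters are
// updated by stepping-out slice sampling against the Wiener first-passage
// likelihood with an outlier mixture.

static inline double to_natural(int type, double x) {
  switch (type) {
    case 0: return x;                        // v
    case 1: return std::exp(x);              // a
    case 2: return 1.0 / (1.0 + std::exp(-x)); // z
    default: return std::exp(x);             // t0
  }
}

// Generic scalar slice sampler (Neal 2003, stepping out + shrinkage).
static double slice_scalar(double x0, double w, int m,
                           const std::function<double(double)> &logf) {
  double f0 = logf(x0);
  if (!R_finite(f0)) return x0; // infeasible start: leave untouched
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
List hddm_sampler_cpp(NumericVector rt, IntegerVector upper,
                      IntegerVector subj, IntegerVector group,
                      List cells, IntegerVector K, IntegerVector use_group,
                      List init_mu,
                      NumericVector prior_mean, NumericVector prior_sd,
                      NumericVector sigma_scale, NumericVector slice_w,
                      double q, double log_contam, double eps,
                      int n_iter, int burn, int fix_hyper) {
  const int n = rt.size();
  const int S = group.size();
  int G = 0;
  for (int s = 0; s < S; ++s) G = std::max(G, group[s] + 1);
  // number of group-mean levels per parameter type (1 when the spec drops
  // the group factor for that parameter) and the subject -> mean-level map
  int Gp[4];
  for (int p = 0; p < 4; ++p) Gp[p] = use_group[p] ? G : 1;
  auto glev = [&](int p, int s) { return use_group[p] ? group[s] : 0; };

  IntegerVector cell[4];
  for (int p = 0; p < 4; ++p) cell[p] = as<IntegerVector>(cells[p]);

  // trial index lists per (type, subject, cell)
  std::vector<std::vector<std::vector<std::vector<int>>>> idx(4);
  for (int p = 0; p < 4; ++p) {
    idx[p].assign(S, std::vector<std::vector<int>>(K[p]));
    for (int i = 0; i < n; ++i) idx[p][subj[i]][cell[p][i]].push_back(i);
  }

  // state
  std::vector<std::vector<std::vector<double>>> theta(4); // [p][s][k]
  std::vector<std::vector<std::vector<double>>> mu(4);    // [p][g][k]
  std::vector<std::vector<double>> sigma(4);              // [p][k]
  // cached natural-scale subject parameters
  std::vector<std::vector<std::vector<double>>> nat(4);
  for (int p = 0; p < 4; ++p) {
    NumericMatrix m0 = as<NumericMatrix>(init_mu[p]); // Gp x K_p
    mu[p].assign(Gp[p], std::vector<double>(K[p]));
    for (int g = 0; g < Gp[p]; ++g)
      for (int k = 0; k < K[p]; ++k) mu[p][g][k] = m0(g, k);
    sigma[p].assign(K[p], fix_hyper ? prior_sd[p] : 0.1);
    theta[p].assign(S, std::vector<double>(K[p]));
    nat[p].assign(S, std::vector<double>(K[p]));
    for (int s = 0; s < S; ++s)
      for (int k = 0; k < K[p]; ++k) {
        theta[p][s][k] = m0(glev(p, s), k) + 0.01 * norm_rand();
        nat[p][s][k] = to_natural(p, theta[p][s][k]);
      }
  }

  // log-likelihood of the trials in (p, s, k) with this type's natural value
  // replaced by cand (other types from cache)
  auto cell_loglik = [&](int p, int s, int k, double cand) -> double {
    double ll = 0.0;
    const std::vector<int> &ids = idx[p][s][k];
    for (size_t j = 0; j < ids.size(); ++j) {
      int i = ids[j];
      double v  = (p == 0) ? cand : nat[0][s][cell[0][i]];
      double a  = (p == 1) ? cand : nat[1][s][cell[1][i]];
      double z  = (p == 2) ? cand : nat[2][s][cell[2][i]];
      double t0 = (p == 3) ? cand : nat[3][s][cell[3][i]];
      ll += wfpt_mix_log(rt[i], upper[i], v, a, z, t0, q, log_contam, eps);
      if (ll == R_NegInf) return R_NegInf;
    }
    return ll;
  };

  auto full_deviance = [&]() -> double {
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      int s = subj[i];
      ll += wfpt_mix_log(rt[i], upper[i], nat[0][s][cell[0][i]],
                         nat[1][s][cell[1][i]], nat[2][s][cell[2][i]],
                         nat[3][s][cell[3][i]], q, log_contam, eps);
    }
    return -2.0 * ll;
  };

  // draw storage (transformed scale)
  List mu_draws(4), sigma_draws(4), theta_draws(4);
  for (int p = 0; p < 4; ++p) {
    mu_draws[p] = NumericMatrix(n_iter, Gp[p] * K[p]);
    sigma_draws[p] = NumericMatrix(n_iter, K[p]);
    theta_draws[p] = NumericMatrix(n_iter, S * K[p]);
  }
  NumericVector deviance(n_iter);
  // running mean of theta after burn-in, for D(theta_bar)
  std::vector<std::vector<std::vector<double>>> theta_sum(4);
  for (int p = 0; p < 4; ++p)
    theta_sum[p].assign(S, std::vector<double>(K[p], 0.0));
  int n_kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // subject-level updates
    for (int p = 0; p < 4; ++p) {
      for (int s = 0; s < S; ++s) {
        int g = glev(p, s);
        for (int k = 0; k < K[p]; ++k) {
          if (idx[p][s][k].empty()) { // cell unobserved: draw from hierarchy
            theta[p][s][k] = mu[p][g][k] + sigma[p][k] * norm_rand();
            nat[p][s][k] = to_natural(p, theta[p][s][k]);
            continue;
          }
          double mu_c = mu[p][g][k], sd_c = sigma[p][k];
          auto logpost = [&](double x) {
            double d = (x - mu_c) / sd_c;
            double lp = -0.5 * d * d;
            return lp + cell_loglik(p, s, k, to_natural(p, x));
          };
          theta[p][s][k] = slice_scalar(theta[p][s][k], slice_w[p], 10, logpost);
          nat[p][s][k] = to_natural(p, theta[p][s][k]);
        }
      }
    }
    // group means: conjugate Normal update (fixed for pooled fits)
    for (int p = 0; p < 4 && !fix_hyper; ++p) {
      for (int g = 0; g < Gp[p]; ++g) {
        for (int k = 0; k < K[p]; ++k) {
          double sum = 0.0; int ng = 0;
          for (int s = 0; s < S; ++s)
            if (glev(p, s) == g) { sum += theta[p][s][k]; ++ng; }
          double prec = ng / (sigma[p][k] * sigma[p][k]) +
                        1.0 / (prior_sd[p] * prior_sd[p]);
          double mean = (sum / (sigma[p][k] * sigma[p][k]) +
                         prior_mean[p] / (prior_sd[p] * prior_sd[p])) / prec;
          mu[p][g][k] = mean + norm_rand() / std::sqrt(prec);
        }
      }
    }
    // group sds: slice on log sigma, Half-Normal prior
    for (int p = 0; p < 4 && !fix_hyper; ++p) {
      for (int k = 0; k < K[p]; ++k) {
        auto logpost = [&](double lsig) {
          double sig = std::exp(lsig);
          double ss = 0.0;
          for (int s = 0; s < S; ++s) {
            double d = theta[p][s][k] - mu[p][glev(p, s)][k];
            ss += d * d;
          }
          return -S * lsig - ss / (2.0 * sig * sig) -
                 sig * sig / (2.0 * sigma_scale[p] * sigma_scale[p]) + lsig;
        };
        sigma[p][k] = std::exp(slice_scalar(std::log(sigma[p][k]), 0.5, 10, logpost));
      }
    }

    // record
    for (int p = 0; p < 4; ++p) {
      NumericMatrix md = as<NumericMatrix>(mu_draws[p]);
      NumericMatrix sd = as<NumericMatrix>(sigma_draws[p]);
      NumericMatrix td = as<NumericMatrix>(theta_draws[p]);
      for (int g = 0; g < Gp[p]; ++g)
        for (int k = 0; k < K[p]; ++k) md(it, g * K[p] + k) = mu[p][g][k];
      for (int k = 0; k < K[p]; ++k) sd(it, k) = sigma[p][k];
      for (int s = 0; s < S; ++s)
        for (int k = 0; k < K[p]; ++k) td(it, s * K[p] + k) = theta[p][s][k];
    }
    deviance[it] = full_deviance();
    if (it >= burn) {
      ++n_kept;
      for (int p = 0; p < 4; ++p)
        for (int s = 0; s < S; ++s)
          for (int k = 0; k < K[p]; ++k) theta_sum[p][s][k] += theta[p][s][k];
    }
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }

  // deviance at the posterior mean of subject parameters
  for (int p = 0; p < 4; ++p)
    for (int s = 0; s < S; ++s)
      for (int k = 0; k < K[p]; ++k)
        nat[p][s][k] = to_natural(p, theta_sum[p][s][k] / std::max(1, n_kept));
  double dev_at_mean = full_deviance();

  return List::create(_["mu"] = mu_draws, _["sigma"] = sigma_draws,
                      _["theta"] = theta_draws, _["deviance"] = deviance,
                      _["dev_at_mean"] = dev_at_mean, _["n_groups"] = G);
}
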