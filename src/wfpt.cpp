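#include <Rcpp.h>
#include "wfpt.h"
using namespace Rcpp;

// First-passage-time density of a Wiener diffusion at the lower boundary,
// after Navarro & Fuss (2009): rescale to tau = t / a^2 and evaluate the
// standardized density f(tau | 0, 1, w) with either the small-time or the
// large-time series, whichever needs fewer terms at tolerance eps.
static double fpt_std(double tau, double w, double eps) {
  // number of terms for the small-time expansion
  double ks;
  if (2.0 * std::sqrt(2.0 * M_PI * tau) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tau * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * tau)));
    ks = std::max(ks, std::sqrt(tau) + 1.0);
  } else {
    ks = 2.0;
  }
  // number of terms for the large-time expansion
  double kl;
  if (M_PI * tau * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tau * eps) / (M_PI * M_PI * tau));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tau)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tau));
  }

  double p = 0.0;
  if (ks < kl) {
    int K = (int)std::ceil(ks);
    for (int k = -((K - 1) / 2); k <= ((K - 1) / 2) + 1; ++k) {
      double wk = w + 2.0 * k;
      p += wk * std::exp(-wk * wk / (2.0 * tau));
    }
    p /= std::sqrt(2.0 * M_PI * tau * tau * tau);
  } else {
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      p += k * std::exp(-k * k * M_PI * M_PI * tau / 2.0) * std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  return p;
}

double wfpt_log_lower(double t, double v, double a, double w, double eps) {
  if (!(t > 0.0) || !(a > 0.0) || !(w > 0.0) || !(w < 1.0) ||
      !R_finite(v) || !R_finite(a)) {
    return R_NegInf;
  }
  double tau = t / (a * a);
  double p = fpt_std(tau, w, eps);
  if (!(p > 0.0)) return R_NegInf;
  return std::log(p) - v * a * w - v * v * t / 2.0 - 2.0 * std::log(a);
}

double wfpt_log_response(double rt, int upper, double v, double a, double w,
                         double t0, double eps) {
  double t = rt - t0;
  if (!(t > 0.0)) return R_NegInf;
  if (upper) {
    // upper-boundary density via the (v, w) -> (-v, 1 - w) reflection
    return wfpt_log_lower(t, -v, a, 1.0 - w, eps);
  }
  return wfpt_log_lower(t, v, a, w, eps);
}

double wfpt_mix_log(double rt, int upper, double v, double a, double w,
                    double t0, double q, double log_contam, double eps) {
  double lw = wfpt_log_response(rt, upper, v, a, w, t0, eps);
  if (q <= 0.0) return lw;
  double l1 = std::log1p(-q) + lw;      // (1-q) * wfpt
  double l2 = std::log(q) + log_contam; // q * contaminant
  double m = std::max(l1, l2);
  if (m == R_NegInf) return R_NegInf;
  return m + std::log(std::exp(l1 - m) + std::exp(l2 - m));
}

// [[Rcpp::export]]
NumericVector wfpt_logpdf_cpp(NumericVector rt, IntegerVector upper,
                              NumericVector v, NumericVector a,
                              NumericVector z, NumericVector t0,
                              double eps) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = wfpt_log_response(rt[i], upper[i % upper.size()],
                               v[i % v.size()], a[i % a.size()],
                               z[i % z.size()], t0[i % t0.size()], eps);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector wfpt_mix_logpdf_cpp(NumericVector rt, IntegerVector upper,
                                  NumericVector v, NumericVector a,
                                  NumericVector z, NumericVector t0,
                                  double q, double log_contam, double eps) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = wfpt_mix_log(rt[i], upper[i % upper.size()],
                          v[i % v.size()], a[i % a.size()],
                          z[i % z.size()], t0[i % t0.size()],
                          q, log_contam, eps);
  }
  return out;
}
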