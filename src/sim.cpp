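#include <Rcpp.h>
using namespace Rcpp;

// Forward Euler-Maruyama simulation of the diffusion process with unit
// diffusion coefficient. Per-trial parameters are recycled. Trials that do
// not absorb before t_max are returned with NA rt/boundary (censored).
// The discrete walk only observes the process at the grid, so a naive
// barrier test is biased by O(sqrt(dt)); the Broadie-Glasserman-Kou
// continuity correction (barriers shifted inward by 0.5826 sqrt(dt))
// removes the leading-order bias.
// [[Rcpp::export]]
List simulate_ddm_cpp(int n, NumericVector v, NumericVector a,
                      NumericVector z, NumericVector t0,
                      double dt, double t_max) {
  NumericVector rt(n);
  IntegerVector upper(n);
  double sdt = std::sqrt(dt);
  double shift = 0.5826 * sdt; // zeta(1/2)/sqrt(2*pi)
  int max_steps = (int)std::ceil(t_max / dt);
  for (int i = 0; i < n; ++i) {
    double ai = a[i % a.size()];
    double x = z[i % z.size()] * ai;
    double vi = v[i % v.size()];
    double hi = ai - shift, lo = shift;
    int step = 0;
    int hit = NA_INTEGER;
    while (step < max_steps) {
      ++step;
      x += vi * dt + sdt * norm_rand();
      if (x >= hi) { hit = 1; break; }
      if (x <= lo) { hit = 0; break; }
    }
    if (hit == NA_INTEGER) {
      rt[i] = NA_REAL;
      upper[i] = NA_INTEGER;
    } else {
      rt[i] = t0[i % t0.size()] + step * dt;
      upper[i] = hit;
    }
  }
  return List::create(_["rt"] = rt, _["upper"] = upper);
}
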