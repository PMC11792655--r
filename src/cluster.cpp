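#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Cluster-based permutation engine for paired (one-sample on differences)
// designs over channel x time maps. Points with |t| above tcrit are grouped
// into signed clusters under channel-adjacency x consecutive-time
// connectivity; the null is the permutation distribution of the maximum
// absolute cluster mass under random per-subject sign flips (two-sided,
// positive and negative clusters pooled).

struct ClusterOut {
  std::vector<double> mass;
  std::vector<int> sign;
  std::vector<int> npts;
  std::vector<int> labels; // C*T, 0 = none, else cluster id (1-based)
};

// one-sample t over subjects at each (channel, time) point; zero-variance
// points yield NaN and never enter a cluster
static void tmap(const double *d, const double *flip, int S, int C, int T,
                 std::vector<double> &t) {
  int P = C * T;
  for (int p = 0; p < P; ++p) {
    double m = 0.0, m2 = 0.0;
    for (int s = 0; s < S; ++s) {
      double v = flip[s] * d[s + (size_t)S * p];
      m += v;
      m2 += v * v;
    }
    m /= S;
    double var = (m2 - S * m * m) / (S - 1);
    t[p] = (var > 0.0) ? m / std::sqrt(var / S) : R_NaN;
  }
}

static void find_clusters(const std::vector<double> &t, double tcrit,
                          const std::vector<std::vector<int>> &adj,
                          int C, int T, ClusterOut &out, bool keep_labels) {
  int P = C * T;
  std::vector<int> lab(P, 0);
  out.mass.clear(); out.sign.clear(); out.npts.clear();
  int next = 0;
  std::vector<int> stack;
  for (int p0 = 0; p0 < P; ++p0) {
    if (lab[p0] != 0) continue;
    double tv = t[p0];
    if (!R_finite(tv) || std::fabs(tv) <= tcrit) continue;
    int sgn = tv > 0 ? 1 : -1;
    ++next;
    double mass = 0.0;
    int npts = 0;
    stack.clear();
    stack.push_back(p0);
    lab[p0] = next;
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      mass += t[p];
      ++npts;
      int c = p % C, ti = p / C;
      // neighbors: adjacent channels at same time, same channel +/- 1 sample
      for (size_t j = 0; j < adj[c].size(); ++j) {
        int pn = adj[c][j] + ti * C;
        double tn = t[pn];
        if (lab[pn] == 0 && R_finite(tn) && std::fabs(tn) > tcrit &&
            ((tn > 0) == (sgn > 0))) {
          lab[pn] = next;
          stack.push_back(pn);
        }
      }
      for (int dt = -1; dt <= 1; dt += 2) {
        int tj = ti + dt;
        if (tj < 0 || tj >= T) continue;
        int pn = c + tj * C;
        double tn = t[pn];
        if (lab[pn] == 0 && R_finite(tn) && std::fabs(tn) > tcrit &&
            ((tn > 0) == (sgn > 0))) {
          lab[pn] = next;
          stack.push_back(pn);
        }
      }
    }
    out.mass.push_back(mass);
    out.sign.push_back(sgn);
    out.npts.push_back(npts);
  }
  if (keep_labels) out.labels = lab;
}

// [[Rcpp::export]]
List cluster_perm_cpp(NumericVector diff, IntegerVector dims,
                      List adjacency, double tcrit, int n_perm) {
  int S = dims[0], C = dims[1], T = dims[2];
  std::vector<std::vector<int>> adj(C);
  for (int c = 0; c < C; ++c) {
    IntegerVector a = adjacency[c]; // 0-based neighbor channels
    adj[c].assign(a.begin(), a.end());
  }
  std::vector<double> t(C * T);
  std::vector<double> flip(S, 1.0);

  tmap(REAL(diff), flip.data(), S, C, T, t);
  ClusterOut obs;
  find_clusters(t, tcrit, adj, C, T, obs, true);

  NumericVector null_max(n_perm);
  ClusterOut perm;
  for (int b = 0; b < n_perm; ++b) {
    for (int s = 0; s < S; ++s) flip[s] = unif_rand() < 0.5 ? -1.0 : 1.0;
    std::vector<double> tp(C * T);
    tmap(REAL(diff), flip.data(), S, C, T, tp);
    find_clusters(tp, tcrit, adj, C, T, perm, false);
    double mx = 0.0;
    for (size_t i = 0; i < perm.mass.size(); ++i)
      mx = std::max(mx, std::fabs(perm.mass[i]));
    null_max[b] = mx;
    if (b % 100 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix tmat(C, T);
  for (int p = 0; p < C * T; ++p) tmat[p] = t[p];
  IntegerMatrix labmat(C, T);
  for (int p = 0; p < C * T; ++p) labmat[p] = obs.labels[p];
  return List::create(_["t"] = tmat, _["labels"] = labmat,
                      _["mass"] = NumericVector(obs.mass.begin(), obs.mass.end()),
                      _["sign"] = IntegerVector(obs.sign.begin(), obs.sign.end()),
                      _["n_points"] = IntegerVector(obs.npts.begin(), obs.npts.end()),
                      _["null_max"] = null_max);
}
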