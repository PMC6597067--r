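#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Energy-gated stochastic spiking network.  Per node i and step t:
//   cost_i = r1 * outdeg_i / <Nout> + r2 * k_i / <Nin>,
//     k_i = number of currently active in-neighbours of i;
//   if E_i > cost_i (strict), node fires with probability
//     corrected:  1 - (1 - p sigma(E_i))^(1 + k_i)
//     as_printed: (1 - p sigma(E_i))^(1 + k_i)
//   E_i <- (1-eps) E_i + eps Ebar - a_i cost_i  (costs from pre-update
//   activities; synchronous update).
// One uniform deviate is drawn per node per step, in node order, from R's
// RNG, so a seeded run matches the pure-R reference step exactly.

namespace {

inline double sigma_e(double E, double w, double e_low) {
  double a = w * E - e_low;
  if (a > 40.0) a = 40.0;
  if (a < -40.0) a = -40.0;
  return 0.5 * (std::tanh(a) + 1.0);
}

} // namespace

// adj_targets / adj_ptr: CSR over out-edges (0-based targets; node i's
// targets are adj_targets[adj_ptr[i] .. adj_ptr[i+1]-1]).  Ignored when
// fully_connected is true.
// [[Rcpp::export]]
List cpp_simulate_agents(int n, int steps, double p, double e_low,
                         double e_bar, double w, double eps, double r1,
                         double r2, bool corrected, NumericVector e0,
                         bool fully_connected, IntegerVector adj_targets,
                         IntegerVector adj_ptr, NumericVector out_deg,
                         double mean_in, double mean_out, bool full_history) {
  std::vector<int> q(n, 0), a(n, 0), k(n, 0);
  std::vector<double> E(e0.begin(), e0.end());
  IntegerVector activity(steps + 1);
  activity[0] = 0;
  double e_min = R_PosInf, e_max = R_NegInf;
  for (int i = 0; i < n; ++i) {
    if (E[i] < e_min) e_min = E[i];
    if (E[i] > e_max) e_max = E[i];
  }
  IntegerMatrix q_hist;
  NumericMatrix e_hist;
  if (full_history) {
    q_hist = IntegerMatrix(steps + 1, n);
    e_hist = NumericMatrix(steps + 1, n);
    for (int i = 0; i < n; ++i) {
      q_hist(0, i) = 0;
      e_hist(0, i) = E[i];
    }
  }

  int S = 0; // current total activity
  for (int t = 1; t <= steps; ++t) {
    // active in-neighbour counts from time-(t-1) activities
    if (fully_connected) {
      for (int i = 0; i < n; ++i) k[i] = S - q[i];
    } else {
      std::fill(k.begin(), k.end(), 0);
      if (S > 0) {
        for (int j = 0; j < n; ++j) {
          if (!q[j]) continue;
          for (int e = adj_ptr[j]; e < adj_ptr[j + 1]; ++e) k[adj_targets[e]]++;
        }
      }
    }
    int Snew = 0;
    for (int i = 0; i < n; ++i) {
      double cost = r1 * out_deg[i] / mean_out + r2 * k[i] / mean_in;
      double u = unif_rand();
      int ai = 0;
      if (E[i] > cost) {
        double s = p * sigma_e(E[i], w, e_low);
        double pf = corrected ? -expm1((1.0 + k[i]) * log1p(-s))
                              : std::pow(1.0 - s, 1.0 + k[i]);
        if (u < pf) ai = 1;
      }
      a[i] = ai;
      E[i] = (1.0 - eps) * E[i] + eps * e_bar - (ai ? cost : 0.0);
      if (E[i] < e_min) e_min = E[i];
      if (E[i] > e_max) e_max = E[i];
      Snew += ai;
    }
    for (int i = 0; i < n; ++i) q[i] = a[i];
    S = Snew;
    activity[t] = S;
    if (full_history) {
      for (int i = 0; i < n; ++i) {
        q_hist(t, i) = q[i];
        e_hist(t, i) = E[i];
      }
    }
  }

  List out = List::create(_["activity"] = activity, _["e_min"] = e_min,
                          _["e_max"] = e_max);
  if (full_history) {
    out["q_history"] = q_hist;
    out["e_history"] = e_hist;
  }
  return out;
}
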