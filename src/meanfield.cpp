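#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Activity-energy mean-field map:
//   q_{t+1} = 1 - (1 - p sigma(E_t))^(z q_t)
//   E_{t+1} = (1-eps) E_t + eps Ebar - r q_t [E_t >= r q_t]
// sigma(E) = (tanh(w E - e_low) + 1)/2; the Heaviside gate pays the cost at
// equality (H(0) = 1).  tanh argument clamped to +-40 (sigma saturates long
// before double rounding).

namespace {

inline double sigma_e(double E, double w, double e_low) {
  double a = w * E - e_low;
  if (a > 40.0) a = 40.0;
  if (a < -40.0) a = -40.0;
  return 0.5 * (std::tanh(a) + 1.0);
}

inline void mf_step(double& q, double& E, double p, double z, double w,
                    double e_low, double e_bar, double eps, double r) {
  double s = sigma_e(E, w, e_low);
  // 1 - (1 - p s)^(z q) computed as -expm1(z q log1p(-p s)) for accuracy
  double qn = -expm1(z * q * log1p(-p * s));
  double En = (1.0 - eps) * E + eps * e_bar - (E >= r * q ? r * q : 0.0);
  q = qn;
  E = En;
}

} // namespace

// [[Rcpp::export]]
List cpp_simulate_meanfield(double q0, double e0, int steps, double p,
                            double z, double w, double e_low, double e_bar,
                            double eps, double r) {
  NumericVector q(steps + 1), E(steps + 1);
  double qc = q0, Ec = e0;
  q[0] = qc;
  E[0] = Ec;
  for (int t = 0; t < steps; ++t) {
    mf_step(qc, Ec, p, z, w, e_low, e_bar, eps, r);
    q[t + 1] = qc;
    E[t + 1] = Ec;
  }
  return List::create(_["q"] = q, _["E"] = E);
}

// Time-varying p and Ebar (one value per step taken); used by the
// hypoxia/reoxygenation protocol.
// [[Rcpp::export]]
List cpp_simulate_meanfield_schedule(double q0, double e0, NumericVector p_t,
                                     NumericVector ebar_t, double z, double w,
                                     double e_low, double eps, double r) {
  int steps = p_t.size();
  NumericVector q(steps + 1), E(steps + 1);
  double qc = q0, Ec = e0;
  q[0] = qc;
  E[0] = Ec;
  for (int t = 0; t < steps; ++t) {
    mf_step(qc, Ec, p_t[t], z, w, e_low, ebar_t[t], eps, r);
    q[t + 1] = qc;
    E[t + 1] = Ec;
  }
  return List::create(_["q"] = q, _["E"] = E);
}
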