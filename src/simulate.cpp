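#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step integration of the coupled phase-oscillator family
//
//   dtheta_i/dt = omega_i + c * sum_j w_ij * sin(theta_j(t - tau) - theta_i(t))
//
// All four model variants share this single code path so that the reduction
// identities (tau = 0, w_ij = 1, adaptive threshold below min r) hold
// bitwise: the standard model is literally the delayed model with
// delay_steps = 0 and an all-ones weight matrix.
//
// Adaptive variant (behavioral plasticity): when the order parameter r(t)
// drops below r_threshold, natural frequencies decay as
// domega_i/dt = -omega_i / r(t)^2. The discrete multiplier (1 - dt/r^2) is
// floored at 0 so one Euler step can never push omega through zero.
//
// Delay history: theta_j(t) = theta_j(0) for t < 0 (constant pre-history).

static double order_param(const NumericMatrix& theta, int row, int n) {
  double sc = 0.0, ss = 0.0;
  for (int i = 0; i < n; ++i) {
    sc += std::cos(theta(row, i));
    ss += std::sin(theta(row, i));
  }
  return std::sqrt(sc * sc + ss * ss) / n;
}

// [[Rcpp::export(name = ".sim_phase_euler")]]
List sim_phase_euler(NumericVector theta0, NumericVector omega0,
                     double coupling_c, NumericMatrix weights,
                     int delay_steps, bool adaptive, double r_threshold,
                     int n_steps, double dt, bool store_omega) {
  const int n = theta0.size();
  NumericMatrix theta(n_steps, n);
  NumericMatrix omega_out(store_omega ? n_steps : 1, n);
  std::vector<double> omega(omega0.begin(), omega0.end());

  for (int i = 0; i < n; ++i) theta(0, i) = theta0[i];
  if (store_omega)
    for (int i = 0; i < n; ++i) omega_out(0, i) = omega[i];

  for (int t = 0; t < n_steps - 1; ++t) {
    int td = t - delay_steps;
    if (td < 0) td = 0;
    for (int i = 0; i < n; ++i) {
      double coupling = 0.0;
      const double th_i = theta(t, i);
      for (int j = 0; j < n; ++j)
        coupling += weights(i, j) * std::sin(theta(td, j) - th_i);
      double next = th_i + dt * (omega[i] + coupling_c * coupling);
      if (!std::isfinite(next))
        stop("non-finite phase for agent %d at step %d", i + 1, t + 1);
      theta(t + 1, i) = next;
    }
    if (adaptive) {
      double r = order_param(theta, t, n);
      if (r < r_threshold) {
        double mult = 1.0 - dt / (r * r);
        if (mult < 0.0) mult = 0.0;
        for (int i = 0; i < n; ++i) omega[i] *= mult;
      }
    }
    if (store_omega)
      for (int i = 0; i < n; ++i) omega_out(t + 1, i) = omega[i];
  }

  if (store_omega)
    return List::create(_["theta"] = theta, _["omega"] = omega_out);
  return List::create(_["theta"] = theta, _["omega"] = R_NilValue);
}

// Classical RK4 for the undelayed, non-adaptive members of the family
// (standard and weighted coupling); used for integrator convergence checks.
// [[Rcpp::export(name = ".sim_phase_rk4")]]
NumericMatrix sim_phase_rk4(NumericVector theta0, NumericVector omega0,
                            double coupling_c, NumericMatrix weights,
                            int n_steps, double dt) {
  const int n = theta0.size();
  NumericMatrix theta(n_steps, n);
  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n);

  auto deriv = [&](const std::vector<double>& x, std::vector<double>& out) {
    for (int i = 0; i < n; ++i) {
      double coupling = 0.0;
      for (int j = 0; j < n; ++j)
        coupling += weights(i, j) * std::sin(x[j] - x[i]);
      out[i] = omega0[i] + coupling_c * coupling;
    }
  };

  for (int i = 0; i < n; ++i) theta(0, i) = th[i];
  for (int t = 0; t < n_steps - 1; ++t) {
    deriv(th, k1);
    for (int i = 0; i < n; ++i) tmp[i] = th[i] + 0.5 * dt * k1[i];
    deriv(tmp, k2);
    for (int i = 0; i < n; ++i) tmp[i] = th[i] + 0.5 * dt * k2[i];
    deriv(tmp, k3);
    for (int i = 0; i < n; ++i) tmp[i] = th[i] + dt * k3[i];
    deriv(tmp, k4);
    for (int i = 0; i < n; ++i) {
      th[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (!std::isfinite(th[i]))
        stop("non-finite phase for agent %d at step %d", i + 1, t + 1);
      theta(t + 1, i) = th[i];
    }
  }
  return theta;
}
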