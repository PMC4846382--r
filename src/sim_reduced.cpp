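#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Activity-based reduced model: per neuron a fast voltage V and the slow
// persistent-sodium inactivation h_NaP.  Coupling enters through the
// piecewise-linear output f(V) of the other neurons.

struct RedPars {
  double C, g_nap, g_l, g_syn, e_na, e_syn;
  double v_m, k_m, v_h, k_h, v_tau, k_tau, tau_max;
  double v_min, v_max;
};

static inline double f_out(double v, const RedPars &p) {
  if (v < p.v_min) return 0.0;
  if (v >= p.v_max) return 1.0;
  return (v - p.v_min) / (p.v_max - p.v_min);
}

static inline double m_inf(double v, const RedPars &p) {
  return 1.0 / (1.0 + std::exp((v - p.v_m) / p.k_m));
}
static inline double h_inf(double v, const RedPars &p) {
  return 1.0 / (1.0 + std::exp((v - p.v_h) / p.k_h));
}
static inline double tau_h(double v, const RedPars &p) {
  return p.tau_max / std::cosh((v - p.v_tau) / p.k_tau);
}

static void derivs(const std::vector<double> &v, const std::vector<double> &h,
                   const std::vector<double> &e_l, double w, const RedPars &p,
                   std::vector<double> &dv, std::vector<double> &dh) {
  const int n = (int) v.size();
  std::vector<double> f(n);
  for (int i = 0; i < n; ++i) f[i] = f_out(v[i], p);
  double fsum = 0.0;
  for (int i = 0; i < n; ++i) fsum += f[i];
  for (int i = 0; i < n; ++i) {
    const double drive = w * (fsum - f[i]);           // all-to-all, no self
    const double i_nap = p.g_nap * m_inf(v[i], p) * h[i] * (v[i] - p.e_na);
    const double i_l   = p.g_l * (v[i] - e_l[i]);
    const double i_syn = drive * p.g_syn * (v[i] - p.e_syn);
    dv[i] = -(i_nap + i_l + i_syn) / p.C;
    dh[i] = (h_inf(v[i], p) - h[i]) / tau_h(v[i], p);
  }
}

//' @name cpp_simulate_reduced
//' @title Fixed-step RK4 integrator for the reduced activity-based network
//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_simulate_reduced(NumericVector e_l0, List pars, double w,
                                   NumericVector v0, NumericVector h0,
                                   double dt, double duration, double discard,
                                   int record_every,
                                   double perturb_on, double perturb_off,
                                   double e_l_scale, double w_scale) {
  RedPars p;
  p.C = as<double>(pars["C"]);         p.g_nap = as<double>(pars["g_nap"]);
  p.g_l = as<double>(pars["g_l"]);     p.g_syn = as<double>(pars["g_syn"]);
  p.e_na = as<double>(pars["e_na"]);   p.e_syn = as<double>(pars["e_syn"]);
  p.v_m = as<double>(pars["v_m"]);     p.k_m = as<double>(pars["k_m"]);
  p.v_h = as<double>(pars["v_h"]);     p.k_h = as<double>(pars["k_h"]);
  p.v_tau = as<double>(pars["v_tau"]); p.k_tau = as<double>(pars["k_tau"]);
  p.tau_max = as<double>(pars["tau_max"]);
  p.v_min = as<double>(pars["v_min"]); p.v_max = as<double>(pars["v_max"]);

  const int n = e_l0.size();
  std::vector<double> base_el(e_l0.begin(), e_l0.end());
  std::vector<double> v(v0.begin(), v0.end()), h(h0.begin(), h0.end());

  const long nsteps = (long) std::lround(duration / dt);
  long nrow = 0;
  for (long s = 0; s <= nsteps; ++s)
    if (s % record_every == 0 && s * dt >= discard) nrow++;
  NumericMatrix out(nrow, 1 + 2 * n);

  std::vector<double> k1v(n), k1h(n), k2v(n), k2h(n), k3v(n), k3h(n),
      k4v(n), k4h(n), tv(n), th(n), e_l(n);

  long row = 0;
  const bool perturbed_window = perturb_off > perturb_on;
  for (long s = 0; s <= nsteps; ++s) {
    const double t = s * dt;
    if (s % record_every == 0 && t >= discard) {
      out(row, 0) = t;
      for (int i = 0; i < n; ++i) { out(row, 1 + i) = v[i]; out(row, 1 + n + i) = h[i]; }
      row++;
    }
    if (s == nsteps) break;

    const bool in_win = perturbed_window && t >= perturb_on && t < perturb_off;
    const double w_eff = in_win ? w * w_scale : w;
    for (int i = 0; i < n; ++i) e_l[i] = in_win ? base_el[i] * e_l_scale : base_el[i];

    derivs(v, h, e_l, w_eff, p, k1v, k1h);
    for (int i = 0; i < n; ++i) { tv[i] = v[i] + 0.5 * dt * k1v[i]; th[i] = h[i] + 0.5 * dt * k1h[i]; }
    derivs(tv, th, e_l, w_eff, p, k2v, k2h);
    for (int i = 0; i < n; ++i) { tv[i] = v[i] + 0.5 * dt * k2v[i]; th[i] = h[i] + 0.5 * dt * k2h[i]; }
    derivs(tv, th, e_l, w_eff, p, k3v, k3h);
    for (int i = 0; i < n; ++i) { tv[i] = v[i] + dt * k3v[i]; th[i] = h[i] + dt * k3h[i]; }
    derivs(tv, th, e_l, w_eff, p, k4v, k4h);
    for (int i = 0; i < n; ++i) {
      v[i] += dt / 6.0 * (k1v[i] + 2.0 * k2v[i] + 2.0 * k3v[i] + k4v[i]);
      h[i] += dt / 6.0 * (k1h[i] + 2.0 * k2h[i] + 2.0 * k3h[i] + k4h[i]);
      if (!R_finite(v[i]))
        stop("numerical instability: non-finite voltage (neuron %d, t = %g ms)", i + 1, t);
    }
    if (s % 200000 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
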