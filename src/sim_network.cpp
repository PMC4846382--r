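#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sigmoid steady state: 1 / (1 + exp(-(V - vh)/k)).  k < 0 gives an
// inactivation (decreasing) curve.
static inline double sigm(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vh) / k));
}

// Delayed-rectifier K+ rate functions; alpha has a removable singularity
// at V = -45 mV (limit 0.01 * 5 = 0.05).
static inline double alpha_k(double v) {
  double x = v + 45.0;
  if (std::fabs(x) < 1e-7) return 0.05;
  return 0.01 * x / (1.0 - std::exp(-x / 5.0));
}
static inline double beta_k(double v) {
  return 0.17 * std::exp(-(v + 49.0) / 40.0);
}

// Exponential-Euler update of one gating variable.
static inline double gate_step(double x, double xinf, double tau, double dt) {
  return xinf + (x - xinf) * std::exp(-dt / tau);
}

//' @name cpp_simulate_network
//' @title Compiled exponential-Euler integrator for the conductance-based network
//' @noRd
// [[Rcpp::export]]
List cpp_simulate_network(NumericVector e_l, NumericVector g_nap,
                          List fixed,
                          IntegerVector edge_from, IntegerVector edge_to,
                          NumericVector edge_w,
                          NumericMatrix init,
                          double dt, double duration, double discard,
                          IntegerVector record_ids, int record_every) {
  const int n = e_l.size();
  const double C        = as<double>(fixed["C"]);
  const double gbar_na  = as<double>(fixed["g_na"]);
  const double gbar_k   = as<double>(fixed["g_k"]);
  const double g_l      = as<double>(fixed["g_l"]);
  const double e_na     = as<double>(fixed["e_na"]);
  const double e_k      = as<double>(fixed["e_k"]);
  const double e_syn    = as<double>(fixed["e_syn"]);
  const double g_syn_bar= as<double>(fixed["g_syn_bar"]);
  const double tau_syn  = as<double>(fixed["tau_syn"]);
  const double v_thresh = as<double>(fixed["spike_threshold"]);

  // CSR adjacency by presynaptic neuron (0-based internally)
  std::vector<int> deg(n, 0);
  const int m = edge_from.size();
  for (int e = 0; e < m; ++e) deg[edge_from[e] - 1]++;
  std::vector<int> ptr(n + 1, 0);
  for (int j = 0; j < n; ++j) ptr[j + 1] = ptr[j] + deg[j];
  std::vector<int> tgt(m);
  std::vector<double> wgt(m);
  {
    std::vector<int> pos(ptr.begin(), ptr.end() - 1);
    for (int e = 0; e < m; ++e) {
      int j = edge_from[e] - 1;
      tgt[pos[j]] = edge_to[e] - 1;
      wgt[pos[j]] = edge_w[e];
      pos[j]++;
    }
  }

  // state vectors
  std::vector<double> V(n), mna(n), hna(n), mnap(n), hnap(n), mk(n), gsyn(n);
  for (int i = 0; i < n; ++i) {
    V[i]    = init(i, 0);
    mna[i]  = init(i, 1);
    hna[i]  = init(i, 2);
    mnap[i] = init(i, 3);
    hnap[i] = init(i, 4);
    mk[i]   = init(i, 5);
    gsyn[i] = init(i, 6);
  }

  const long nsteps = (long) std::lround(duration / dt);
  const double syn_decay = std::exp(-dt / tau_syn);

  std::vector< std::vector<double> > spikes(n);
  std::vector<char> spiked(n, 0), spiked_prev(n, 0);

  // trace recording
  const int nrec = record_ids.size();
  long ntr = 0;
  if (nrec > 0 && record_every > 0) {
    for (long s = 1; s <= nsteps; ++s)
      if (s % record_every == 0 && s * dt > discard) ntr++;
  }
  NumericMatrix traces(ntr, nrec > 0 ? 1 + 2 * nrec : 1);
  long trow = 0;

  for (long s = 1; s <= nsteps; ++s) {
    const double t_end = s * dt;

    // consume spikes detected in the previous step
    for (int j = 0; j < n; ++j) {
      if (spiked_prev[j]) {
        for (int e = ptr[j]; e < ptr[j + 1]; ++e)
          gsyn[tgt[e]] += g_syn_bar * wgt[e];
      }
    }

    for (int i = 0; i < n; ++i) {
      const double v = V[i];
      // gate kinetics at step start
      const double mna_inf  = sigm(v, -43.8, 6.0);
      const double tau_mna  = 0.25 / std::cosh(-(v + 43.8) / 14.0);
      const double hna_inf  = sigm(v, -67.5, -10.8);
      const double tau_hna  = 8.46 / std::cosh((v + 67.5) / 12.8);
      const double mnap_inf = sigm(v, -47.1, 3.1);
      const double tau_mnap = 1.0 / std::cosh(-(v + 47.1) / 6.2);
      const double hnap_inf = sigm(v, -60.0, -9.0);
      const double tau_hnap = 6000.0 / std::cosh((v + 60.0) / 9.0);
      const double ak = alpha_k(v), bk = beta_k(v);
      const double mk_inf = ak / (ak + bk);
      const double tau_mk = 1.0 / (ak + bk);

      // gates advance first (their kinetics evaluated at the step-start V);
      // the membrane step then uses the updated gate values in its frozen
      // conductance/reversal decomposition -- the sequencing that keeps the
      // scheme accurate at the 0.1 ms production step
      mna[i]  = gate_step(mna[i],  mna_inf,  tau_mna,  dt);
      hna[i]  = gate_step(hna[i],  hna_inf,  tau_hna,  dt);
      mnap[i] = gate_step(mnap[i], mnap_inf, tau_mnap, dt);
      hnap[i] = gate_step(hnap[i], hnap_inf, tau_hnap, dt);
      mk[i]   = gate_step(mk[i],   mk_inf,   tau_mk,   dt);

      const double g_na_eff  = gbar_na * mna[i] * mna[i] * mna[i] * hna[i];
      const double g_nap_eff = g_nap[i] * mnap[i] * hnap[i];
      const double g_k_eff   = gbar_k * mk[i] * mk[i] * mk[i] * mk[i];
      const double g_tot = g_na_eff + g_nap_eff + g_k_eff + g_l + gsyn[i];
      const double v_inf = (g_na_eff * e_na + g_nap_eff * e_na + g_k_eff * e_k +
                            g_l * e_l[i] + gsyn[i] * e_syn) / g_tot;
      const double v_new = v_inf + (v - v_inf) * std::exp(-dt * g_tot / C);
      gsyn[i] *= syn_decay;

      spiked[i] = (v < v_thresh && v_new >= v_thresh) ? 1 : 0;
      if (spiked[i] && t_end > discard) spikes[i].push_back(t_end);

      if (!R_finite(v_new))
        stop("numerical instability: non-finite membrane potential (neuron %d, t = %g ms)",
             i + 1, t_end);
      V[i] = v_new;
    }
    std::swap(spiked, spiked_prev);

    if (nrec > 0 && record_every > 0 && s % record_every == 0 && t_end > discard) {
      traces(trow, 0) = t_end;
      for (int r = 0; r < nrec; ++r) {
        int id = record_ids[r] - 1;
        traces(trow, 1 + r) = V[id];
        traces(trow, 1 + nrec + r) = hnap[id];
      }
      trow++;
    }
    if (s % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  List spk(n);
  for (int i = 0; i < n; ++i) spk[i] = NumericVector(spikes[i].begin(), spikes[i].end());

  NumericMatrix fin(n, 7);
  for (int i = 0; i < n; ++i) {
    fin(i, 0) = V[i];   fin(i, 1) = mna[i]; fin(i, 2) = hna[i];
    fin(i, 3) = mnap[i]; fin(i, 4) = hnap[i]; fin(i, 5) = mk[i];
    fin(i, 6) = gsyn[i];
  }
  return List::create(_["spikes"] = spk, _["traces"] = traces,
                      _["final_state"] = fin);
}
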