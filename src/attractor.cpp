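// One trial of the ring bump-attractor network: conductance-based
// leaky integrate-and-fire excitatory/inhibitory populations, recurrent
// excitation through NMDA-type synapses (slow kinetics, voltage-dependent
// magnesium block), external Poisson drive through fast AMPA-type synapses,
// and uniform GABA-type inhibition. E->E connectivity follows the ring
// profile passed in as a full weight matrix (mean weight 1). Forward-Euler
// integration with exact exponential decay of the synaptic gates. Uses R's
// RNG for the external Poisson streams.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List cpp_attractor_trial(const arma::mat& W_ee, Rcpp::List par,
                               const arma::uvec& stim_idx,
                               double stim_on_ms, double stim_off_ms,
                               double trial_ms) {
  const uword nE = W_ee.n_rows;
  const uword nI = Rcpp::as<uword>(par["n_inhibitory"]);
  const double dt = Rcpp::as<double>(par["dt_ms"]);
  const double ext_mean =
      Rcpp::as<double>(par["n_extern_poisson"]) *
      Rcpp::as<double>(par["poisson_rate_hz"]) * dt / 1000.0;
  const double stim_pA = Rcpp::as<double>(par["stim_strength_namp"]) * 1000.0;
  const double tau_nmda_s = Rcpp::as<double>(par["tau_nmda_ms"]);
  const double wsf = Rcpp::as<double>(par["weight_scaling"]);

  // membrane constants (pyramidal / interneuron)
  const double Cm_E = 0.5, gL_E = 25.0, Cm_I = 0.2, gL_I = 20.0;  // nF, nS
  const double E_L = -70.0, V_th = -50.0, V_reset = -60.0;        // mV
  const double tref_E = 2.0, tref_I = 1.0;                        // ms
  // synaptic constants
  const double tau_ampa = 2.0, tau_gaba = 10.0, tau_x = 2.0;      // ms
  const double alpha = 0.5;                                       // 1/ms
  const double E_gaba = -70.0;
  // maximal conductances (nS); recurrent ones carry the scaling factor
  Rcpp::List gcond = par["conductances"];
  const double G_ext2E = Rcpp::as<double>(gcond["ext2e"]);
  const double G_ext2I = Rcpp::as<double>(gcond["ext2i"]);
  const double G_e2e = Rcpp::as<double>(gcond["e2e"]) * wsf;
  const double G_e2i = Rcpp::as<double>(gcond["e2i"]) * wsf;
  const double G_i2e = Rcpp::as<double>(gcond["i2e"]) * wsf;
  const double G_i2i = Rcpp::as<double>(gcond["i2i"]) * wsf;

  const double dec_ampa = std::exp(-dt / tau_ampa);
  const double dec_gaba = std::exp(-dt / tau_gaba);
  const double dec_x = std::exp(-dt / tau_x);

  vec vE(nE, fill::value(E_L)), vI(nI, fill::value(E_L));
  vec refE(nE, fill::zeros), refI(nI, fill::zeros);
  vec sextE(nE, fill::zeros), sextI(nI, fill::zeros);
  vec xn(nE, fill::zeros), sn(nE, fill::zeros);
  double s_gaba = 0.0;

  std::vector<char> is_stim(nE, 0);
  for (uword k = 0; k < stim_idx.n_elem; ++k) is_stim[stim_idx(k)] = 1;

  const uword n_steps = (uword)std::round(trial_ms / dt);
  std::vector<double> sp_t;
  std::vector<int> sp_id;
  uword i_spikes = 0;

  for (uword step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    // decay gates, then external Poisson arrivals
    sextE *= dec_ampa; sextI *= dec_ampa;
    xn *= dec_x; s_gaba *= dec_gaba;
    for (uword i = 0; i < nE; ++i) sextE(i) += R::rpois(ext_mean);
    for (uword i = 0; i < nI; ++i) sextI(i) += R::rpois(ext_mean);
    // NMDA gating (bounded in [0,1])
    sn += dt * (-sn / tau_nmda_s + alpha * (xn % (1.0 - sn)));
    sn = clamp(sn, 0.0, 1.0);

    const vec nmda_on_E = W_ee * sn;   // ring-weighted recurrent drive
    const double nmda_tot = accu(sn);  // uniform drive onto interneurons
    const bool stim_on = (t >= stim_on_ms && t < stim_off_ms);

    // voltage update: exponential Euler with synaptic conductances (and the
    // NMDA magnesium gate) frozen over the step — unconditionally stable
    // even when the total conductance makes the effective membrane time
    // constant much shorter than dt
    // excitatory cells
    for (uword i = 0; i < nE; ++i) {
      if (refE(i) > 0) { refE(i) -= dt; vE(i) = V_reset; continue; }
      const double v = vE(i);
      const double mg = 1.0 / (1.0 + std::exp(-0.062 * v) / 3.57);
      const double g_exc = G_ext2E * sextE(i) + G_e2e * nmda_on_E(i) * mg;
      const double g_inh = G_i2e * s_gaba;
      const double g_tot = gL_E + g_exc + g_inh;
      double num = gL_E * E_L + g_inh * E_gaba;  // excitatory reversal is 0 mV
      if (stim_on && is_stim[i]) num += stim_pA;
      const double v_inf = num / g_tot;
      vE(i) = v_inf + (v - v_inf) * std::exp(-dt * g_tot / Cm_E);
      if (!std::isfinite(vE(i)))
        Rcpp::stop("numerical instability (non-finite voltage) at t = %.1f ms;"
                   " reduce the integration step", t);
      if (vE(i) >= V_th) {
        vE(i) = V_reset; refE(i) = tref_E;
        xn(i) += 1.0;
        sp_t.push_back(t); sp_id.push_back((int)i);
      }
    }
    // inhibitory cells
    for (uword i = 0; i < nI; ++i) {
      if (refI(i) > 0) { refI(i) -= dt; vI(i) = V_reset; continue; }
      const double v = vI(i);
      const double mg = 1.0 / (1.0 + std::exp(-0.062 * v) / 3.57);
      const double g_exc = G_ext2I * sextI(i) + G_e2i * nmda_tot * mg;
      const double g_inh = G_i2i * s_gaba;
      const double g_tot = gL_I + g_exc + g_inh;
      const double v_inf = (gL_I * E_L + g_inh * E_gaba) / g_tot;
      vI(i) = v_inf + (v - v_inf) * std::exp(-dt * g_tot / Cm_I);
      if (!std::isfinite(vI(i)))
        Rcpp::stop("numerical instability (non-finite voltage) at t = %.1f ms;"
                   " reduce the integration step", t);
      if (vI(i) >= V_th) {
        vI(i) = V_reset; refI(i) = tref_I;
        s_gaba += 1.0;
        ++i_spikes;
      }
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("spike_t_ms") = sp_t, Rcpp::Named("spike_unit") = sp_id,
      Rcpp::Named("n_inhib_spikes") = (double)i_spikes);
}
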