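#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One trial of the reward-driven spike/no-spike classification task.
//
// Leaky integrator with exponential postsynaptic currents, stochastic
// escape-rate spiking (spike probability per step 1 - exp(-phi*dt)) and
// instantaneous membrane reset after each output spike. Per-synapse
// eligibility traces follow
//   tau_M dE_j/dt = -E_j + (1/delta_u) [ sum_s delta(t - s) - phi(u(t)) ] sbar_j(t),
// integrated with exact exponential decay per step, the continuous drive
// held constant within a step, and post-spike delta contributions added as
// jumps of sbar_j / (delta_u * tau_M). Rates inside the eligibility drive
// (delta spikes and phi) are measured per second while time constants stay
// in ms, which keeps E of order one -- the scale at which causal and
// homeostatic terms of the reference rules are commensurable.
//
// Two consistency conditions of the escape-noise integrator: the rate
// entering spike generation and the eligibility drive is capped at the
// maximum observable rate 1000/dt Hz (the generator cannot emit more than
// one spike per step), and the drive subtracts the generator's expected
// spike rate p/dt rather than phi itself, so E is exactly centered at
// equilibrium for any rate (for phi*dt << 1 the two coincide).
//
// The per-step recurrence for synapse j,
//   E_j <- E_j*dM + gain_t*sbar_j,   sbar_j <- sbar_j*ds (+ spikes),
// is evaluated lazily: between a synapse's input events, sbar_j decays
// geometrically, so the accumulated drive is sbar_j(mark) times a scalar
// sum shared by all synapses. Each step only advances that scalar;
// per-synapse state is reconciled at the synapse's own input events, at
// postsynaptic spikes (which touch every trace) and at fixed segment
// boundaries that keep the running powers well conditioned. The result is
// identical to the step-by-step recurrence up to floating-point rounding.
//
// Input spikes are an event list (0-based step, 0-based synapse), sorted by
// step; they take effect at the end of their step (one-step delay).
// Stochasticity uses R's RNG (unif_rand), so trials are reproducible under
// set.seed().
//
// clamp_u: if finite, the membrane is clamped to this value (no reset, no
// input integration into u) -- used to validate the eligibility integrator
// against closed forms.
// [[Rcpp::export]]
List reward_trial_cpp(IntegerVector spk_step, IntegerVector spk_syn,
                      int n_steps, int n_syn, NumericVector w, double dt,
                      double tau_m, double tau_syn, double tau_M,
                      double u_rest, double u_th, double delta_u,
                      double rho_hz, double clamp_u = NA_REAL,
                      bool record_u = false) {
  const double dm = std::exp(-dt / tau_m);
  const double ds = std::exp(-dt / tau_syn);
  const double dM = std::exp(-dt / tau_M);
  const double c1 = (ds - dm) * tau_m * tau_syn / (tau_syn - tau_m);
  const double jump = 1000.0 / (delta_u * tau_M);
  const bool clamped = R_finite(clamp_u);
  const int seg_len = 256; // segment reset keeps ds^k, q well conditioned

  // Per-synapse state at its mark (the last step at which it was
  // reconciled): E after that step's update, sbar at the end of that step,
  // and the segment-local scalars at the mark.
  std::vector<double> E(n_syn, 0.0), sbar(n_syn, 0.0);
  std::vector<double> A_mark(n_syn, 0.0), dM_mark(n_syn, 1.0),
      ds_mark(n_syn, 1.0);

  // Segment-local scalars, step k since the segment start t0:
  //   A(k)   = sum_{i=1..k} gain_i * ds^(i-1) / dM^i
  //   dM_k   = dM^k,  ds_k = ds^k,  ds_prev = ds^(k-1)
  double A = 0.0, dM_k = 1.0, ds_k = 1.0, q = 0.0;

  double u = clamped ? clamp_u : u_rest;
  double I = 0.0;
  int n_spikes = 0;
  std::vector<int> post_steps;
  const int n_ev = spk_step.size();
  int ev = 0;

  NumericVector u_rec(record_u ? n_steps : 0);

  // E and sbar of synapse j advanced from its mark to the current step k
  // (E including this step's drive update, sbar still at end of step k-1).
  auto synced_E = [&](int j) {
    return (dM_k / dM_mark[j]) * E[j] +
           sbar[j] * (dM_k / ds_mark[j]) * (A - A_mark[j]);
  };
  auto sbar_prev = [&](int j, double ds_prev) {
    return sbar[j] * ds_prev / ds_mark[j];
  };
  auto set_mark = [&](int j, double e_now, double s_now) {
    E[j] = e_now;
    sbar[j] = s_now;
    A_mark[j] = A;
    dM_mark[j] = dM_k;
    ds_mark[j] = ds_k;
  };

  for (int t = 0; t < n_steps; ++t) {
    if (!clamped) u = u_rest + (u - u_rest) * dm + I * c1;
    double ex = (u - u_th) / delta_u;
    if (ex > 30.0) ex = 30.0;
    double phi_hz = rho_hz * std::exp(ex);
    if (phi_hz > 1000.0 / dt) phi_hz = 1000.0 / dt;
    const double p = 1.0 - std::exp(-phi_hz * dt / 1000.0);
    const double gain = -(1.0 - dM) * (1000.0 * p / dt) / delta_u;

    // advance the segment scalars to step k = (k_prev + 1)
    const double ds_prev = ds_k; // ds^(k-1) after the advance below
    q = (q == 0.0) ? 1.0 / dM : q * (ds / dM);
    A += gain * q;
    dM_k *= dM;
    ds_k *= ds;

    const bool spike = unif_rand() < p;
    if (spike) {
      ++n_spikes;
      post_steps.push_back(t);
      if (!clamped) u = u_rest; // instantaneous reset
    }
    if (record_u) u_rec[t] = u;

    // synaptic current: decay, then this step's input events
    I *= ds;
    const int ev0 = ev;
    while (ev < n_ev && spk_step[ev] == t) {
      I += w[spk_syn[ev]];
      ++ev;
    }

    const bool boundary = spike || (t == n_steps - 1) ||
                          ((t + 1) % seg_len == 0);
    if (boundary) {
      // reconcile every synapse at this step, then restart the segment
      for (int j = 0; j < n_syn; ++j) {
        double e_now = synced_E(j);
        double s_pre = sbar_prev(j, ds_prev);
        if (spike) e_now += jump * s_pre;
        set_mark(j, e_now, s_pre * ds);
      }
      for (int k2 = ev0; k2 < ev; ++k2) sbar[spk_syn[k2]] += 1.0;
      A = 0.0;
      dM_k = 1.0;
      ds_k = 1.0;
      q = 0.0;
      for (int j = 0; j < n_syn; ++j) {
        A_mark[j] = 0.0;
        dM_mark[j] = 1.0;
        ds_mark[j] = 1.0;
      }
    } else if (ev > ev0) {
      // reconcile only the synapses receiving spikes this step
      for (int k2 = ev0; k2 < ev; ++k2) {
        const int j = spk_syn[k2];
        double e_now = synced_E(j);
        double s_now = sbar_prev(j, ds_prev) * ds + 1.0;
        set_mark(j, e_now, s_now);
      }
    }
  }

  List out = List::create(
      _["n_spikes"] = n_spikes, _["E"] = NumericVector(E.begin(), E.end()),
      _["u_final"] = u,
      _["post_steps"] = IntegerVector(post_steps.begin(), post_steps.end()));
  if (record_u) out["u"] = u_rec;
  return out;
}
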