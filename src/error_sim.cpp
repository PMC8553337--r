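#include "rule_program.h"
#include <cmath>
using namespace Rcpp;

// Teacher-student error-driven regression trial.
//
// Identical Poisson input spikes drive a teacher neuron (fixed weights) and
// a student neuron (plastic weights); both are leaky integrators with
// exponential postsynaptic currents. Since neither membrane is reset after
// spike emission, output spiking does not influence the dynamics and the
// potentials are simulated directly. The teacher potential is sampled and
// held every `readout_every` steps and provided instantaneously to the
// plasticity rule f(v, u, sbar_j) (inputs x0, x1, x2). Raw weight-change
// rates eta*f are low-pass filtered with time constant tau_I before
// application (w_j += dt * filtered rate).
//
// Returns the accumulated squared error over the window [frac_skip*T, T]
// and decimated traces. If the rule ever returns a non-finite value the
// trial aborts with valid = FALSE.
// [[Rcpp::export]]
List error_trial_cpp(IntegerVector spk_step, IntegerVector spk_syn,
                     int n_steps, int n_syn, NumericVector w_teacher,
                     NumericVector w_student, NumericMatrix prog, double dt,
                     double tau_m, double tau_syn, double u_rest, double eta,
                     double tau_I, int readout_every, double frac_skip,
                     int record_every) {
  const double dm = std::exp(-dt / tau_m);
  const double ds = std::exp(-dt / tau_syn);
  const double dI = std::exp(-dt / tau_I);
  const double c1 = (ds - dm) * tau_m * tau_syn / (tau_syn - tau_m);
  RuleProgram rule(prog);
  std::vector<double> regs(rule.n_regs, 0.0);

  std::vector<double> sbar(n_syn, 0.0), ws(w_student.begin(), w_student.end()),
      raw(n_syn, 0.0), filt(n_syn, 0.0);
  double v = u_rest, u = u_rest, Iv = 0.0, Iu = 0.0, v_hold = u_rest;
  const int n_ev = spk_step.size();
  int ev = 0;
  bool valid = true;

  const int skip = (int)std::floor(frac_skip * n_steps);
  double sum_sq = 0.0;
  long n_sq = 0;

  const int n_rec = record_every > 0 ? n_steps / record_every : 0;
  NumericVector t_rec(n_rec), v_rec(n_rec), u_rec(n_rec);
  NumericMatrix w_rec(n_rec, record_every > 0 ? n_syn : 0);
  int rec = 0;

  for (int t = 0; t < n_steps && valid; ++t) {
    v = u_rest + (v - u_rest) * dm + Iv * c1;
    u = u_rest + (u - u_rest) * dm + Iu * c1;
    if (t % readout_every == 0) {
      v_hold = v;
      for (int j = 0; j < n_syn; ++j) {
        regs[0] = v_hold - u_rest;
        regs[1] = u - u_rest;
        regs[2] = sbar[j];
        const double f = rule.eval(regs.data());
        if (!std::isfinite(f)) {
          valid = false;
          break;
        }
        raw[j] = eta * f;
      }
    }
    if (!valid) break;
    for (int j = 0; j < n_syn; ++j) {
      filt[j] = filt[j] * dI + (1.0 - dI) * raw[j];
      ws[j] += dt * filt[j];
    }

    if (t >= skip) {
      const double d = v - u;
      sum_sq += d * d;
      ++n_sq;
    }
    if (record_every > 0 && (t + 1) % record_every == 0 && rec < n_rec) {
      t_rec[rec] = (t + 1) * dt;
      v_rec[rec] = v;
      u_rec[rec] = u;
      for (int j = 0; j < n_syn; ++j) w_rec(rec, j) = ws[j];
      ++rec;
    }

    Iv *= ds;
    Iu *= ds;
    for (int j = 0; j < n_syn; ++j) sbar[j] *= ds;
    while (ev < n_ev && spk_step[ev] == t) {
      const int j = spk_syn[ev];
      Iv += w_teacher[j];
      Iu += ws[j];
      sbar[j] += 1.0;
      ++ev;
    }
  }

  return List::create(
      _["valid"] = valid, _["rmse"] = n_sq > 0 ? std::sqrt(sum_sq / n_sq) : NA_REAL,
      _["w_final"] = NumericVector(ws.begin(), ws.end()), _["t"] = t_rec,
      _["v"] = v_rec, _["u"] = u_rec, _["w_trace"] = w_rec);
}
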