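#include "rule_program.h"
#include <cmath>
using namespace Rcpp;

// Correlation-driven task: leaky integrate-and-fire neuron with
// delta-shaped postsynaptic currents (each input spike from synapse j jumps
// u by J * w_j), deterministic threshold crossing with reset, and
// pairing-based STDP with weight-dependent homeostasis.
//
// Nearest-neighbor spike pairing: at each presynaptic spike the anticausal
// branch f_dep(w, E) is evaluated against the most recent postsynaptic
// spike (E = exp(-|dt|/tau_elig); skipped if none yet) together with the
// presynaptically triggered homeostatic term f_pre_hom(w); at each
// postsynaptic spike the causal branch f_fac(w, E) is evaluated against the
// most recent presynaptic spike of every synapse, plus the postsynaptic
// homeostatic term f_post_hom(w). A pre and post spike in the same step
// count as a causal pairing (dt = 0, E = 1). All four functions receive
// registers (x0 = w, x1 = E); homeostatic programs are decoded from
// single-input expressions of w. Weight changes are eta * f, clipped to
// [w_min, 1] after each application.
//
// spiking = false disables threshold and reset (free membrane potential);
// plastic = false freezes weights. The full membrane trace is returned when
// record_u is true.
// [[Rcpp::export]]
List corr_train_cpp(IntegerVector spk_step, IntegerVector spk_syn,
                    int n_steps, int n_syn, NumericVector w0,
                    NumericMatrix prog_dep, NumericMatrix prog_fac,
                    NumericMatrix prog_pre_hom, NumericMatrix prog_post_hom,
                    double dt, double tau_m, double u_rest, double u_th,
                    double J, double tau_elig, double eta, double w_min,
                    bool spiking = true, bool plastic = true,
                    bool record_u = false) {
  const double dm = std::exp(-dt / tau_m);
  RuleProgram dep(prog_dep), fac(prog_fac), pre_hom(prog_pre_hom),
      post_hom(prog_post_hom);
  int max_regs = std::max(std::max(dep.n_regs, fac.n_regs),
                          std::max(pre_hom.n_regs, post_hom.n_regs));
  std::vector<double> regs(std::max(max_regs, 2), 0.0);

  std::vector<double> w(w0.begin(), w0.end());
  std::vector<int> last_pre(n_syn, -1);
  int last_post = -1;
  double u = u_rest;
  bool valid = true;

  std::vector<int> post_steps;
  NumericVector u_rec(record_u ? n_steps : 0);
  const int n_ev = spk_step.size();
  int ev = 0;

  auto clip = [&](double x) {
    if (x < w_min) return w_min;
    if (x > 1.0) return 1.0;
    return x;
  };
  auto eval2 = [&](const RuleProgram &p, double wj, double E) {
    regs[0] = wj;
    regs[1] = E;
    return p.eval(regs.data());
  };

  for (int t = 0; t < n_steps && valid; ++t) {
    u = u_rest + (u - u_rest) * dm;

    while (ev < n_ev && spk_step[ev] == t) {
      const int j = spk_syn[ev];
      u += J * w[j];
      if (plastic) {
        double dw = eval2(pre_hom, w[j], 0.0); // homeostasis on every pre spike
        if (last_post >= 0) {                  // anticausal pairing, dt < 0
          const double E = std::exp(-(t - last_post) * dt / tau_elig);
          dw += eval2(dep, w[j], E);
        }
        if (!std::isfinite(dw)) {
          valid = false;
          break;
        }
        w[j] = clip(w[j] + eta * dw);
      }
      last_pre[j] = t;
      ++ev;
    }
    if (!valid) break;

    if (spiking && u >= u_th) {
      u = u_rest;
      post_steps.push_back(t);
      if (plastic) {
        for (int j = 0; j < n_syn; ++j) {
          double dw = eval2(post_hom, w[j], 0.0);
          if (last_pre[j] >= 0) { // causal pairing, dt >= 0
            const double E = std::exp(-(t - last_pre[j]) * dt / tau_elig);
            dw += eval2(fac, w[j], E);
          }
          if (!std::isfinite(dw)) {
            valid = false;
            break;
          }
          w[j] = clip(w[j] + eta * dw);
        }
      }
      last_post = t;
    }
    if (record_u) u_rec[t] = u;
  }

  List out = List::create(
      _["valid"] = valid, _["w_final"] = NumericVector(w.begin(), w.end()),
      _["post_steps"] = IntegerVector(post_steps.begin(), post_steps.end()));
  if (record_u) out["u"] = u_rec;
  return out;
}
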