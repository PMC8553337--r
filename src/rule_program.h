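#pragma once
#include <Rcpp.h>
#include <cmath>
#include <vector>

// Register bytecode for a decoded expression graph (see graph_program() on
// the R side). Registers 0..n_inputs-1 are preloaded with the rule inputs;
// each row writes one register. Opcodes: 0 const, 1 +, 2 -, 3 *, 4 /, 5 ^.
struct RuleProgram {
  std::vector<int> opcode, a1, a2, out;
  std::vector<double> cval;
  int n_inputs = 0;
  int n_regs = 0;
  std::vector<int> out_regs;

  RuleProgram() = default;

  explicit RuleProgram(Rcpp::NumericMatrix prog) {
    int n = prog.nrow();
    opcode.resize(n);
    a1.resize(n);
    a2.resize(n);
    out.resize(n);
    cval.resize(n);
    for (int i = 0; i < n; ++i) {
      opcode[i] = (int)prog(i, 0);
      a1[i] = (int)prog(i, 1);
      a2[i] = (int)prog(i, 2);
      out[i] = (int)prog(i, 3);
      cval[i] = prog(i, 4);
    }
    n_inputs = Rcpp::as<int>(prog.attr("n_inputs"));
    n_regs = Rcpp::as<int>(prog.attr("n_regs"));
    Rcpp::IntegerVector orr = prog.attr("out_regs");
    out_regs.assign(orr.begin(), orr.end());
  }

  // Evaluate with inputs already in regs[0..n_inputs-1]; returns the first
  // output. Non-finite intermediates propagate to the output, where the
  // caller must check std::isfinite.
  inline double eval(double *regs) const {
    const int n = (int)opcode.size();
    for (int i = 0; i < n; ++i) {
      double r;
      const double x = regs[a1[i]], y = regs[a2[i]];
      switch (opcode[i]) {
      case 0: r = cval[i]; break;
      case 1: r = x + y; break;
      case 2: r = x - y; break;
      case 3: r = x * y; break;
      case 4: r = x / y; break;
      case 5: r = std::pow(x, y); break;
      default: r = NA_REAL;
      }
      regs[out[i]] = r;
    }
    return regs[out_regs[0]];
  }
};
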