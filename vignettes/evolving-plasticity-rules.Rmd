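---
title: "Evolving synaptic plasticity rules: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving synaptic plasticity rules: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoplast)
```

# Overview

`evoplast` searches for symbolic synaptic plasticity rules with Cartesian
genetic programming (CGP). A rule is a mathematical expression
$f(\cdot)$ over synapse-local quantities; the weight update is
$\Delta w = \eta\, f(\cdot)$ with a fixed learning rate $\eta$. Candidate
rules are encoded as fixed-size indexed graphs (genotypes), decoded into
expressions (phenotypes), and scored by running them inside spiking-network
simulations of three task families:

* **reward-driven** -- a stochastic spiking readout classifies frozen
  spatio-temporal input patterns with a spike/no-spike code and learns from
  a trial-level reward $R \in \{-1, +1\}$ via eligibility traces and moving
  reward baselines;
* **error-driven** -- a student neuron adjusts its input weights so that its
  membrane potential tracks a teacher neuron receiving the same spikes
  through fixed weights;
* **correlation-driven** -- a leaky integrate-and-fire neuron discovers a
  repeating frozen-noise spike pattern using pairing-based STDP with
  weight-dependent homeostasis; no external feedback is available.

A $\mu{+}\lambda$ evolution strategy with tournament selection, mutation-only
variation, *neutral search* (offspring preferred at fitness ties) and
phenotype-level fitness caching drives the search. The published reference
rules of each task family ship as built-in objects
(`reward_reference_rules()`, `error_reference_rules()`,
`corr_reference_rules()`), so every result below can be recomputed without
running evolution.

# The CGP engine

A genotype is a grid of internal nodes (default one row of 12 columns, full
`levels_back`), each carrying one operator gene and `max_arity` connection
genes; output genes select source nodes. Only nodes reachable from the
outputs are *active*; the rest can mutate silently, which is what neutral
search exploits. Decoding produces a canonical fully parenthesized infix
expression; this string is the caching key. We deliberately apply **no
algebraic canonicalization**: `(x0*x2)` and `(x2*x0)` are distinct keys.
That choice is conservative -- it can only cost extra evaluations, never
return a wrong cached fitness.

The default primitive set is $\{+,-,\times,\div\}$ plus constants
$\{1.0, 0.5\}$, which spans all built-in reference rules; a binary power
operator is available as an opt-in (`default_primitives(include_pow =
TRUE)`) for weight-dependent STDP kernels of the form $(wE)^w$. Division is
**unprotected**: an expression that divides by zero is flagged invalid and
receives fitness $-\infty$, rather than being silently patched. Invalid
values never propagate into simulation state.

Every graph also compiles to a small register bytecode evaluated by the C++
simulators, so a rule costs a handful of arithmetic instructions per
application even inside tight integration loops. The test suite checks the
bytecode, the R closure, and an independent recursive tree-walk oracle
against one another on random genomes.

# Evolution strategy

Each generation draws $\lambda$ offspring from $\mu$ parents by tournament
selection (default tournament size one, i.e. uniform parent choice, the
setting used throughout) followed by independent per-gene mutation with
probability `p_mutate`. The best $\mu$ of parents and offspring survive;
at fitness ties offspring win, letting silent mutations accumulate and the
search drift across plateaus. Defaults are $\mu = 4$, $\lambda = 4$,
`p_mutate = 0.1`; the mutation rate was chosen once on the toy
symbolic-regression task (recovering $x_0 x_2$ from samples), where 0.1
recovered the target in 5/5 seeded runs within 50 generations, against 3/5
at 0.05.

Tournament subsets are drawn **without replacement**, matching the
selection algorithm's description of choosing a random subset; for a
size-2 tournament over fitnesses $\{1,2,3\}$ this gives
$P(\text{select } 3) = 2/3$ by enumeration, which the test suite verifies
by Monte Carlo.

The same task sample (derived from the run seed, not the generation index)
is evaluated in every generation, so fitness values are comparable across
generations and the fitness cache stays valid for a whole run. The cache is
transparent by contract: enabling it changes evaluation counts, never
fitness values, and the suite asserts identical trajectories either way.

# Neuron and synapse models

Times are in ms, rates in Hz, potentials in mV. Defaults
($\tau_m = 10$ ms, $u_{rest} = -70$ mV, $u_{th} = -55$ mV,
$\tau_{syn} = 5$ ms, $dt = 0.1$ ms) are conventional cortical point-neuron
values; they are package choices, not published values. The linear
subsystem (synaptic current cascade and membrane leak) is propagated
**exactly** per step, so halving `dt` changes trajectories only through
spike-time discretization. Input spikes take effect at the end of their
grid step (a one-step synaptic delay; the ordering convention is documented
in the simulator sources). Stochastic neurons spike in a step with
probability $1 - e^{-\phi(u)\,dt}$, exact for large rates, where
$\phi(u) = \rho\, e^{(u - u_{th})/\Delta u}$.

Two consistency conditions in the escape-noise integrator matter enough to
state explicitly:

1. the rate entering spike generation and the eligibility drive is capped
   at the maximum observable rate $1000/dt$ Hz (one spike per step);
2. the eligibility drive subtracts the generator's *effective* rate
   $(1 - e^{-\phi dt})/dt$ rather than $\phi$ itself.

Together these make the eligibility trace exactly centered at equilibrium
at any firing rate. Without them, saturated firing (where
$\phi dt \gg 1$ but at most one spike per step can occur) produces an
unbounded spurious negative drift in the traces, which homeostatic rule
terms then amplify into weight divergence.

# Reward-driven task

$N = 50$ inputs project to one stochastic readout. Each experiment draws
$M = 4$ frozen Poisson patterns (rate `nu_in` = 10 Hz over the
$T = 500$ ms trial; two patterns per class) and Gaussian initial weights
$w \sim \mathcal N(0, \sigma_w)$. A trial presents one uniformly chosen
pattern; the outcome is correct if the readout spikes at least once for an
"active"-class pattern or stays silent for an "inactive" one. The
eligibility trace integrates
$\tau_M \dot E_j = -E_j + \frac{1}{\Delta u}\left[\textstyle\sum_s
\delta(t - s) - \phi(u)\right]\bar s_j(t)$
and is read at trial end; baselines $\bar R^\pm$ are moving averages over
`mr` = 100 previous trials, starting at zero, resetting between
experiments.

**Units of the eligibility trace.** Integrating the trace equation with all
times in ms makes $E$ of order $10^{-4}$, while several published rules add
$E$-proportional and $O(1)$ homeostatic terms *inside one expression with a
single $\eta$* -- they are only meaningful if $E$ is of order one. We
therefore measure the rates inside the eligibility drive (the spike deltas
and $\phi$) per second while keeping time constants in ms. This is a pure
units convention: it rescales $E$ by 1000 and is absorbed into $\eta$ for
any rule homogeneous in $E$.

**Calibrated values** (chosen once, in this order, then frozen):
$\sigma_w = 1.15$ by binary search so an untrained readout spikes in about
half the trials (chance performance); $\eta = 0.1$ by grid search for high
performance of the canonical rule $(R-1)E$ -- the same procedure the rule's
original setting used -- then fixed for all rules; $\Delta u = 2$ mV,
$\rho = 20$ Hz, $\tau_M = 300$ ms as the operating point where that rule
learns most reliably; and the trial count $n = 575$ so that the
accumulated-reward fitness ($n \times$ mean reward per trial, ceiling $n$)
of $(R-1)E$ lands on its published scale of about 216.

**What reproduces and what does not.** At these settings the fixed-baseline
rule LR0 $= (R-1)E$, its adaptive-rate variant LR1 and the novelty-baseline
rule LR2 $= (R - (\bar R^+ - \bar R^-))E$ land within roughly $\pm$10% of
their published fitness values (single 20-evaluation batches scatter with a
standard error near 5%, so individual runs can sit just outside the band).
LR3 lands about 20% low, the published ordering among the rules does not
emerge, and the homeostatic rules LR4/LR5 do not learn at all here: their
reward-gated homeostatic terms shift the drive of *all* synapses per trial,
and in every desk-scale regime we probed ($\eta$ across 2.5 decades,
$\tau_M$ 100-500 ms, $\Delta u$ 1-4 mV, $\rho$ 20-100 Hz, 2 or 4 patterns)
that push lands the readout in saturated firing, where outcome probabilities
are insensitive to the weights and the policy gradient carried by $E$
vanishes. The balance between a rule's eligibility term and its homeostatic
term depends on neuron- and weight-scale constants that are not derivable
from the published material; we report the measured values rather than
tune toward the printed ones. The corresponding acceptance checks are left
failing by design.

# Error-driven task

$N = 10$ Poisson inputs with rates $r_i \sim \mathcal U[10, 50]$ Hz drive a
teacher (weights $\mathcal U[0.5, 1.5]$, shifted per trial by a global
$\mathcal U[-0.25, 0.25]$ draw) and a student (all weights starting at
1.0) for $T = 10$ s. Neither membrane is reset after spikes, so output
spiking never feeds back into the potentials and the regression dynamics
are deterministic given the inputs; the simulator therefore integrates
potentials directly. The teacher potential is sampled and held every
`delta_t` (default: every step) and the weight-change rates
$\eta f(v, u, \bar s_j)$ are low-pass filtered with $\tau_I = 100$ ms
before application. Potentials are measured relative to rest
(`u_rest = 0`), the convention under which the large-potential regime
$v, u \gg 1$ applies. $\eta = 3\times10^{-3}$ came from a one-dimensional
grid search on a single held-out task with the gradient rule
$(v - u)\bar s_j$.

Fitness is the **negative** root-mean-squared teacher-student potential
difference over the final 90% of the trial, averaged over experiments, so
that maximizing fitness is literal and the perfect-tracking optimum is 0.

`asymptotic_reduce()` fits a rule's outputs to $c_1 (v-u)\bar s + c_2$ over
sampled operating points ($v \sim \mathcal U[40, 80]$, $u - v \sim
\mathcal U[-2, 2]$, $\bar s \sim \mathcal U[0, 1]$ by default). The
gradient rule returns $c_1 = 1$, $c_2 = 0$ exactly; both published
variants reduce with $c_1 \approx 2$ and relative residual about 2%,
and the residual shrinks as the potential range grows, as the
large-potential expansion predicts.

# Correlation-driven task

$N = 500$ Poisson inputs at $\nu = 5$ Hz; a frozen pattern of
$T_{pattern} = 100$ ms alternates with $T_{inter} = 400$ ms of background.
Pattern neurons (those with at least one pattern spike) fire at the reduced
rate $\alpha\nu$ between patterns, $\alpha = 1 - \nu_{pattern}/\nu_{inter}$,
so the pattern is invisible to a rate detector. The printed $\alpha$
assumes one spike per pattern neuron; since a Poisson draw can contain
more, the input builder balances **per neuron**, reducing each pattern
neuron's background rate according to its actual replayed spike count
(clipped at zero). The residual imbalance from clipping is below 5% of the
background rate; the unbalanced construction would be off by 20%.

Learning is nearest-neighbor pairing STDP: at each presynaptic spike the
anticausal branch $f_{dep}(w, E)$ is applied against the most recent
postsynaptic spike plus the presynaptic homeostatic term; at each
postsynaptic spike the causal branch $f_{fac}(w, E)$ against each synapse's
most recent presynaptic spike plus the postsynaptic homeostatic term, with
$E = e^{-|\Delta t|/\tau}$, $\tau = 20$ ms, $\eta = 0.01$. Weights clip to
$[0, 1]$; rules that divide by $w$ use a floor of $10^{-3}$ (initial
weights $\mathcal U[0.3, 0.7]$ start well above it). A same-step pre-post
coincidence counts as a causal pairing ($\Delta t = 0$, $E = 1$).

Fitness is the **minimum** over experiments of the free-membrane-potential
signal-to-noise ratio: (mean of the per-pattern-window maxima minus the
inter-pattern mean) divided by the inter-pattern standard deviation, with
the spiking mechanism disabled and the weights frozen during measurement.
The formula uses the standard deviation (not the variance) in the
denominator. Calibrations chosen once: PSC amplitude $J = 1.5$ mV per unit
weight (an untrained neuron fires irregularly near threshold) and the
baseline rule's homeostatic constant $w_{hom} = -0.2$, beyond the mean
causal eligibility per postsynaptic spike ($\approx r\tau$) so that only
pattern-locked synapses potentiate. With 200 training presentations the
baseline rule reaches a worst-case SNR near 19 versus about 3.3 untrained,
detects every pattern presentation and stays subthreshold between them;
the two published weight-dependent rules land within a factor of two of
the baseline on the same seeds, supporting their functional-equivalence
reading.

For evolution on this task one genome carries four outputs
($f_{dep}, f_{fac}, f^{hom}_{pre}, f^{hom}_{post}$); the homeostatic
branches see only the weight (their eligibility input is masked to zero).

# Workbench, configuration and reproducibility

Run configurations are YAML (one file: task, seed, evolution, CGP and task
blocks); unknown keys anywhere are rejected rather than ignored. YAML was
chosen over other line-oriented formats because it is the one
configuration format with a reader available across the package's target
environments. Logs are JSON-lines with one record per generation; spike
rasters and traces export as CSV. A single run seed determines every
stochastic component; replaying a configuration byte-reproduces the log,
which the suite asserts.

Problem sizes in the tests and the acceptance script are the package
defaults quoted above (10 experiments per reward-fitness evaluation, 20
seeded evaluations per rule; 3 experiments per correlation fitness; 10
seeds for error-task recovery). These sizes put every stochastic check's
Monte-Carlo error well inside its assertion margin while keeping a full
run at desk scale. Full evolutionary discovery runs at the published scale
(thousands of generations on the correlation task) are out of scope here;
the package runs the same loop at smaller sizes, and the toy
symbolic-regression task exercises it end to end with a known optimum.

# What the synthetic data does and does not emulate

All inputs are generated: frozen-Poisson patterns with class labels,
teacher/student ensembles with uniform rates and weights, and
balanced-rate pattern/background sequences. These capture the statistical
structure the learning rules are sensitive to -- spatio-temporal spike
correlations, reward contingencies, teacher-student potential gaps -- but
not properties of biological recordings (rate nonstationarity, correlated
background, dale-violating weight signs are allowed in the reward task).
Passing tests therefore demonstrate that the rules and the search behave
as published *under the stated generative conditions*, not that they would
do so on physiological data.

# Known limitations

* The reward task reproduces the published absolute fitness scale for
  LR0-LR2 but not their ordering; LR3 lands low and the homeostatic rules
  LR4/LR5 do not learn in this regime (discussion above). The corresponding
  acceptance assertions fail honestly rather than being relaxed.
* The correlation task's published functional-equivalence claim holds
  behaviorally (all three STDP rules become perfect detectors) but not
  always on the free-membrane SNR scale, where the baseline rule can exceed
  the weight-dependent rules by more than the claimed factor of two.
* Nearest-neighbor pairing is one of several defensible STDP pairing
  schemes; it is isolated behind the simulator interface and documented,
  but results for strongly rate-dependent rules can depend on the scheme.
* Crossover, genotype shuffling, algebraic simplification beyond key
  normalization, multi-objective or complexity-penalized selection, and
  hierarchical credit assignment are deliberately out of scope.
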