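# evoplast

Evolutionary search for synaptic plasticity rules in spiking neuronal
networks.

How synapses should change their strength is, in computational terms, a
search problem: a plasticity rule is a function `f` over quantities locally
available at a synapse (spike timings, filtered activity traces, membrane
potentials, reward signals), and a good rule is one that lets a network
solve its task. `evoplast` runs that search with **Cartesian genetic
programming (CGP)**: candidate rules are encoded as fixed-size indexed
graphs, decoded into closed-form expressions `Δw = η·f(…)`, and scored by
simulating them inside spiking networks. Because the discovered rules are
compact symbolic expressions, they can be read, compared and analyzed — not
just executed.

The package is aimed at computational neuroscientists who want to

* reproduce and probe published plasticity rules for three task families —
  reward-driven classification, error-driven regression and
  correlation-driven pattern detection — which ship as built-in, testable
  objects, and
* run their own desk-scale evolutionary searches over rule space with a
  `μ+λ` evolution strategy (tournament selection, mutation-only variation,
  neutral search, phenotype-level fitness caching).

## The search in brief

A genotype is a grid of nodes, each holding an operator gene (over
`{+, −, ×, ÷}` plus constants, optionally `^`) and connection genes. Only
nodes reachable from the output are expressed; mutations in the rest are
*silent*, and the selection rule prefers offspring over equally fit parents
so silent variation can accumulate (neutral search). Fitness is task
specific:

| task family | network | rule inputs | fitness |
|---|---|---|---|
| reward-driven | Poisson inputs → stochastic escape-noise readout | `R, E, R̄⁺, R̄⁻` | accumulated reward over trials |
| error-driven | teacher and student leaky integrators on shared spikes | `v, u, s̄` | − RMSE of membrane potentials |
| correlation-driven | Poisson inputs → LIF with plastic synapses | `w, E^c` (4 STDP branches) | min. free-membrane SNR |

Expressions that cannot be evaluated (division by zero) receive fitness
`−∞` and are selected away; they never crash a run.

## Worked example

Recover a known expression with the full evolutionary loop (a toy
symbolic-regression fitness with optimum `x0*x2`):

```r
library(evoplast)
fit <- symbolic_regression_fitness(function(X) X[, 1] * X[, 3], n_inputs = 3, seed = 7)
res <- evolve_rules(fit, cgp_dims(n_inputs = 3, n_columns = 12),
                    default_primitives(),
                    evolution_params(mu = 2, lam = 4, n_generations = 50, seed = 3))
res
#> <evolution_result> 50 generations, best fitness -0
#>   best: (x0*x2)
#>   evaluations: 31 (cache hits 171)
```

The run reaches the optimum (mean-squared error 0, printed as fitness
`-0`), and the cache report shows why caching matters: 202 offspring
evaluations collapsed onto 31 distinct phenotypes — everything else was a
silent variant of an expression already scored.

Score a published reward-driven rule without any evolution — `LR0` is
`Δw = η(R−1)E`, which only learns from errors:

```r
cfg <- reward_task_config(n_trials = 100L, n_exp = 3L)  # a quick, small setting
eval_rule("reward", "LR0", config = cfg, seeds = 1:2, scale = "mean")
#>  seed   fitness
#>     1 0.2533333
#>     2 0.3066667
```

The fitness here is the mean reward per trial in `[−1, 1]`: after only 100
trials the readout already classifies well above chance (0), and longer
experiments push it toward its asymptote (compare
`scale = "paper"` for the accumulated-reward scale used in the acceptance
script). The STDP rules of the correlation task are inspected the same way
(`corr_reference_rules()`, `stdp_kernel()`), and `Rscript
inst/cli/evoplast.R` exposes `evolve`, `eval-rule`, `make-fixtures` and
`kernels` subcommands for shell use.

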