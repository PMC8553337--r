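#' Configuration of the reward-driven classification task
#'
#' A single stochastic escape-noise readout neuron receives `N` Poisson
#' inputs and must classify `M` frozen spatio-temporal spike patterns into
#' two classes using a spike/no-spike code: a trial is correct when the
#' output spikes at least once for an "active"-class pattern, or stays
#' silent for an "inactive"-class pattern. Reward is `+1` for a correct and
#' `-1` for an incorrect classification; weight changes are applied once per
#' trial from the reward, the per-synapse eligibility trace at trial end and
#' (depending on `baseline_mode`) the jointly or separately estimated moving
#' reward averages.
#'
#' Defaults: trial length `T = 500` ms, `nexp = 10` experiments per fitness
#' evaluation, moving-average window `mr = 100` trials. `sigma_w` is
#' calibrated so an untrained readout spikes in roughly half the trials
#' (chance performance); `eta` is tuned once for high performance of the
#' canonical rule `(R-1)*E` and then fixed for all rules; `n_trials` is
#' calibrated once so that the accumulated-reward fitness of `(R-1)*E`
#' reaches its published scale. See the methods vignette for the
#' calibration procedure.
#'
#' @param N number of input synapses.
#' @param M number of frozen patterns (assigned to two classes, half each).
#' @param T_trial trial duration (ms).
#' @param n_trials learning trials per experiment.
#' @param n_exp experiments per fitness evaluation.
#' @param eta learning rate.
#' @param tau_M eligibility-trace time constant (ms).
#' @param mr moving-average window of the reward baselines (trials).
#' @param sigma_w standard deviation of the zero-mean Gaussian initial
#'   weights.
#' @param nu_in input Poisson rate within a pattern (Hz).
#' @param baseline_mode `"split"` (rule inputs `R, E, Rbar+, Rbar-`) or
#'   `"joint"` (rule inputs `R, E, Rbar`).
#' @param neuron [neuron_params()] of the readout (instantaneous reset).
#' @param dt integration step (ms).
#' @return a `reward_task_config` list.
#' @export
reward_task_config <- function(N = 50L, M = 4L, T_trial = 500, n_trials = 575L,
                               n_exp = 10L, eta = 0.1, tau_M = 300,
                               mr = 100L, sigma_w = 1.15, nu_in = 10,
                               baseline_mode = c("split", "joint"),
                               neuron = neuron_params(
                                 tau_m = 10, u_rest = -70, u_th = -55,
                                 delta_u = 2, rho = 20,
                                 reset_mode = "instantaneous", tau_syn = 5
                               ),
                               dt = 0.1) {
  stopifnot(M >= 2L, M %% 2L == 0L, mr >= 1L, n_trials >= 1L, n_exp >= 1L)
  structure(
    list(
      N = as.integer(N), M = as.integer(M), T_trial = T_trial,
      n_trials = as.integer(n_trials), n_exp = as.integer(n_exp),
      eta = eta, tau_M = tau_M, mr = as.integer(mr), sigma_w = sigma_w,
      nu_in = nu_in, baseline_mode = match.arg(baseline_mode),
      neuron = neuron, dt = dt
    ),
    class = "reward_task_config"
  )
}

#' Update the moving-average reward baselines
#'
#' Positive and negative rewards are tracked separately:
#' `Rbar+ <- (1 - 1/mr) Rbar+ + (1/mr) max(R, 0)` and likewise `Rbar-` with
#' `min(R, 0)`; both start at zero. The expected reward is their sum
#' `Rbar = Rbar+ + Rbar-` and the expected absolute reward their difference
#' `Rbar_abs = Rbar+ - Rbar-`.
#'
#' @param b baselines list with `rplus`, `rminus` (as returned by this
#'   function or `list(rplus = 0, rminus = 0)`).
#' @param R trial reward, `-1` or `+1`.
#' @param mr moving-average window (trials), `>= 1`.
#' @return updated list with `rplus`, `rminus`, `rbar`, `rabs`.
#' @export
#' @examples
#' b <- list(rplus = 0, rminus = 0)
#' b <- update_baselines(b, +1, mr = 2)
#' b$rplus # 0.5
update_baselines <- function(b, R, mr) {
  if (mr < 1) stop("update_baselines: mr must be >= 1", call. = FALSE)
  stopifnot(R %in% c(-1, 1))
  rplus <- (1 - 1 / mr) * b$rplus + (1 / mr) * max(R, 0)
  rminus <- (1 - 1 / mr) * b$rminus + (1 / mr) * min(R, 0)
  list(rplus = rplus, rminus = rminus, rbar = rplus + rminus, rabs = rplus - rminus)
}

#' Eligibility-trace update on the simulation grid (reference integrator)
#'
#' Pure-R reference for the per-synapse eligibility dynamics
#' `tau_M dE/dt = -E + (1/delta_u) [post spikes - phi(u)] * sbar(t)`:
#' exponential decay per step, drive held constant within a step, and a jump
#' of `sbar/(delta_u * tau_M)` at each postsynaptic spike. Rates inside the
#' drive (the spike deltas and `phi`) are measured per second while time
#' constants stay in ms, keeping E of order one so that eligibility-driven
#' and homeostatic rule terms are commensurable. The compiled trial
#' simulator uses the identical scheme.
#'
#' @param E0 initial eligibility value.
#' @param post_steps integer steps (1-based) at which the postsynaptic
#'   neuron spiked.
#' @param u_trace membrane potential per step (mV).
#' @param sbar_trace filtered presynaptic trace per step.
#' @param params [neuron_params()] (uses `delta_u`, `rho`, `u_th`).
#' @param tau_M eligibility time constant (ms).
#' @param dt step (ms).
#' @return numeric vector of E at the end of each step.
#' @export
update_eligibility <- function(E0, post_steps, u_trace, sbar_trace, params,
                               tau_M, dt) {
  n <- length(u_trace)
  stopifnot(length(sbar_trace) == n)
  dM <- exp(-dt / tau_M)
  phi_hz <- pmin(escape_rate(u_trace, params), 1000 / dt)
  # Effective generator rate: expected spikes per step over dt, in Hz.
  phi_eff <- 1000 * (1 - exp(-phi_hz * dt / 1000)) / dt
  E <- numeric(n)
  e <- E0
  post <- logical(n)
  post[post_steps] <- TRUE
  for (t in seq_len(n)) {
    e <- e * dM - (1 - dM) * phi_eff[t] * sbar_trace[t] / params$delta_u
    if (post[t]) e <- e + 1000 * sbar_trace[t] / (params$delta_u * tau_M)
    E[t] <- e
  }
  E
}

# Precompute the sorted event list (0-based steps/synapses) of one frozen
# pattern for the compiled trial simulator.
pattern_events <- function(spikes, config) {
  steps <- integer(0)
  syn <- integer(0)
  for (j in seq_along(spikes)) {
    if (length(spikes[[j]]) > 0L) {
      s <- pmin(pmax(ceiling(spikes[[j]] / config$dt), 1L), config$n_steps) - 1L
      steps <- c(steps, as.integer(s))
      syn <- c(syn, rep(j - 1L, length(s)))
    }
  }
  ord <- order(steps, syn)
  list(step = steps[ord], syn = syn[ord])
}

#' Run a single classification trial
#'
#' Simulates one pattern presentation with the current weights (membrane,
#' synaptic currents and eligibility traces start from rest) and scores the
#' spike/no-spike outcome against the pattern's class.
#'
#' @param weights synaptic weight vector (length `N`).
#' @param pattern a list with `events` (from frozen pattern spikes) or raw
#'   `spikes`; see [make_reward_experiment()].
#' @param active logical: does this pattern belong to the "active" class?
#' @param config a [reward_task_config()].
#' @return list with `reward` (+1/-1), `spiked`, `n_spikes`, `E` (per-synapse
#'   eligibility at trial end).
#' @export
run_trial <- function(weights, pattern, active, config) {
  sc <- sim_config(dt = config$dt, T_total = config$T_trial)
  ev <- pattern$events %||% pattern_events(pattern$spikes, sc)
  np <- config$neuron
  res <- reward_trial_cpp(
    ev$step, ev$syn, sc$n_steps, config$N, weights,
    dt = config$dt, tau_m = np$tau_m, tau_syn = np$tau_syn,
    tau_M = config$tau_M, u_rest = np$u_rest, u_th = np$u_th,
    delta_u = np$delta_u, rho_hz = np$rho
  )
  spiked <- res$n_spikes > 0L
  correct <- (active && spiked) || (!active && !spiked)
  list(
    reward = if (correct) 1 else -1, spiked = spiked,
    n_spikes = res$n_spikes, E = res$E
  )
}

#' Draw one reward-task experiment
#'
#' An experiment is a fresh set of `M` frozen Poisson patterns with class
#' labels (exactly half "active") and fresh Gaussian initial weights. Uses
#' R's global RNG.
#'
#' @param config a [reward_task_config()].
#' @return list with `patterns` (each with precomputed event list),
#'   `active` (logical vector), `w0`.
#' @export
make_reward_experiment <- function(config) {
  sc <- sim_config(dt = config$dt, T_total = config$T_trial)
  patterns <- lapply(seq_len(config$M), function(m) {
    fp <- frozen_pattern(config$N, config$T_trial, config$nu_in)
    list(spikes = fp$spikes, events = pattern_events(fp$spikes, sc))
  })
  active <- rep(FALSE, config$M)
  active[sample.int(config$M, config$M %/% 2L)] <- TRUE
  w0 <- rnorm(config$N, 0, config$sigma_w)
  list(patterns = patterns, active = active, w0 = w0)
}

#' Apply a reward-driven plasticity rule
#'
#' Computes the per-synapse weight change `eta * f(...)` at trial end. The
#' rule arity must match the baseline mode: 4 inputs
#' `(R, E_j, Rbar+, Rbar-)` for split baselines, 3 inputs `(R, E_j, Rbar)`
#' for the joint estimate. Non-finite output raises an
#' invalid-evaluation condition.
#'
#' @param rule a [compile_rule()] object.
#' @param R trial reward.
#' @param E per-synapse eligibility vector.
#' @param baselines baselines list (see [update_baselines()]).
#' @param eta learning rate.
#' @return per-synapse weight-change vector.
#' @export
apply_rule <- function(rule, R, E, baselines, eta) {
  n_in <- length(rule$input_names)
  f <- if (n_in == 4L) {
    rule$fun(R, E, baselines$rplus, baselines$rminus)
  } else if (n_in == 3L) {
    rule$fun(R, E, baselines$rplus + baselines$rminus)
  } else {
    stop("apply_rule: rule arity must be 3 (joint) or 4 (split baselines)",
      call. = FALSE
    )
  }
  if (!all(is.finite(f))) invalid_evaluation("non-finite weight change")
  eta * f
}

#' Run one learning experiment of the reward-driven task
#'
#' Runs `n_trials` sequential trials: per trial a uniformly chosen pattern
#' is presented, the outcome rewarded, the rule applied to all synapses, and
#' the baselines updated (baselines summarize *previous* trials: the rule
#' sees them before the update). Baselines start at zero.
#'
#' @param rule a [compile_rule()] object (arity per `baseline_mode`).
#' @param config a [reward_task_config()].
#' @param experiment optionally a pre-drawn [make_reward_experiment()];
#'   drawn fresh otherwise.
#' @return list with `rewards` (per-trial vector), `mean_reward`,
#'   `w_final`, `baselines`.
#' @export
run_reward_experiment <- function(rule, config, experiment = NULL) {
  if (is.null(experiment)) experiment <- make_reward_experiment(config)
  w <- experiment$w0
  b <- list(rplus = 0, rminus = 0, rbar = 0, rabs = 0)
  rewards <- numeric(config$n_trials)
  for (i in seq_len(config$n_trials)) {
    m <- sample.int(config$M, 1L)
    tr <- run_trial(w, experiment$patterns[[m]], experiment$active[m], config)
    rewards[i] <- tr$reward
    dw <- apply_rule(rule, tr$reward, tr$E, b, config$eta)
    w <- w + dw
    b <- update_baselines(b, tr$reward, config$mr)
  }
  list(
    rewards = rewards, mean_reward = mean(rewards), w_final = w,
    baselines = b
  )
}

#' Fitness of a rule on the reward-driven task
#'
#' Runs `n_exp` independent experiments (fresh patterns, labels and initial
#' weights; baselines reset between experiments) and averages the mean
#' reward per trial. `scale = "mean"` returns the per-trial average in
#' `[-1, 1]`; `scale = "paper"` returns the accumulated-reward aggregate
#' `n_trials * mean`, whose ceiling is the number of trials. An invalid rule
#' evaluation in any trial yields `-Inf`.
#'
#' @param rule a [compile_rule()] object.
#' @param config a [reward_task_config()].
#' @param seed integer seed; experiment `k` derives its stream from
#'   `seed + k`.
#' @param scale `"mean"` or `"paper"`.
#' @return scalar fitness with attribute `per_experiment`.
#' @export
fitness_reward <- function(rule, config, seed = 1L, scale = c("mean", "paper")) {
  scale <- match.arg(scale)
  per <- numeric(config$n_exp)
  for (k in seq_len(config$n_exp)) {
    set.seed(seed + k)
    res <- tryCatch(
      run_reward_experiment(rule, config),
      evoplast_invalid_evaluation = function(e) NULL
    )
    if (is.null(res)) {
      return(structure(-Inf, per_experiment = rep(-Inf, config$n_exp)))
    }
    per[k] <- res$mean_reward
  }
  mult <- if (scale == "paper") config$n_trials else 1
  structure(mult * mean(per), per_experiment = mult * per)
}

#' Built-in reward-driven reference rules
#'
#' The canonical policy-gradient rule `R*E`, the fixed-baseline rule LR0
#' `(R-1)*E`, and the discovered variants LR1-LR5 using the jointly or
#' separately estimated reward baselines:
#' \describe{
#'   \item{pg}{`R*E`}
#'   \item{LR0}{`(R-1)*E`}
#'   \item{LR1}{`(1 + R*Rbar)*(R-1)*E` with `Rbar = Rbar+ + Rbar-`}
#'   \item{LR2}{`(R - (Rbar+ - Rbar-))*E = (R - Rbar_abs)*E`}
#'   \item{LR3}{LR2 with `eta` replaced by `eta/(1 + Rbar+)`}
#'   \item{LR4}{`(R-1)*E + (R-1)*(R + 2*Rbar+)`}
#'   \item{LR5}{`2*(R - (Rbar+ - R*Rbar-))*E - (R - (Rbar+ - R*Rbar-))*R*Rbar-`}
#' }
#' All are compiled over the split-baseline input signature
#' `(R, E, Rbar+, Rbar-)` (inputs `x0..x3`).
#'
#' @return named list of [compile_rule()] objects.
#' @export
#' @examples
#' rules <- reward_reference_rules()
#' rules$LR0$fun(1, 0.3, 0, 0) # (R-1)*E at R = 1 -> 0
reward_reference_rules <- function() {
  inputs <- c("R", "E", "Rplus", "Rminus")
  exprs <- c(
    pg = "x0*x1",
    LR0 = "(x0-1.0)*x1",
    LR1 = "(1.0+(x0*(x2+x3)))*((x0-1.0)*x1)",
    LR2 = "(x0-(x2-x3))*x1",
    LR3 = "((x0-(x2-x3))*x1)/(1.0+x2)",
    LR4 = "((x0-1.0)*x1)+((x0-1.0)*(x0+(2.0*x2)))",
    LR5 = "(2.0*((x0-(x2-(x0*x3)))*x1))-(((x0-(x2-(x0*x3)))*x0)*x3)"
  )
  lapply(exprs, compile_rule, input_names = inputs)
}
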