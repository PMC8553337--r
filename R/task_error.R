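#' Configuration of the error-driven teacher-student task
#'
#' `N` Poisson inputs with constant, uniformly drawn rates project with
#' identical connectivity to a teacher neuron (fixed, uniformly drawn
#' weights, globally shifted by a random `wshift` each trial) and a student
#' neuron (all weights starting at `w0`). Both are leaky integrators with
#' exponential postsynaptic currents; their membranes are not reset after
#' spike emission, so output spiking never influences the potentials and
#' the regression dynamics are deterministic given the inputs. The
#' student's weights evolve under `dw_j/dt = eta * f(v, u, sbar_j)`,
#' evaluated at every `delta_t` readout of the (sampled-and-held) teacher
#' potential and low-pass filtered with `tau_I` before application.
#'
#' Potentials are measured relative to rest (`u_rest = 0` by default), so
#' the rule inputs `v`, `u` are the membrane deviations in mV -- the
#' convention under which the large-potential regime `v, u >> 1` applies.
#'
#' @param N number of inputs.
#' @param rmin,rmax input-rate range (Hz).
#' @param wmin,wmax teacher weight range.
#' @param w0 initial student weight (all synapses).
#' @param wshift_max the global teacher shift is drawn uniformly from
#'   `[-wshift_max, wshift_max]` each trial.
#' @param delta_t readout interval (ms); must be a multiple of `dt`.
#' @param eta learning rate (tuned once by grid search for the rule
#'   `(v-u)*sbar`, then fixed).
#' @param tau_I low-pass time constant of the weight updates (ms).
#' @param T_trial trial duration (ms).
#' @param n_exp experiments per fitness evaluation.
#' @param neuron [neuron_params()]; `reset_mode = "none"`.
#' @param dt integration step (ms).
#' @return an `error_task_config` list.
#' @export
error_task_config <- function(N = 10L, rmin = 10, rmax = 50, wmin = 0.5,
                              wmax = 1.5, w0 = 1.0, wshift_max = 0.25,
                              delta_t = 0.1, eta = 3e-3, tau_I = 100,
                              T_trial = 10000, n_exp = 5L,
                              neuron = neuron_params(
                                tau_m = 10, u_rest = 0, u_th = 15,
                                delta_u = 2, rho = 20, reset_mode = "none",
                                tau_syn = 5
                              ),
                              dt = 0.1) {
  stopifnot(rmin <= rmax, wmin <= wmax, delta_t >= dt, n_exp >= 1L)
  structure(
    list(
      N = as.integer(N), rmin = rmin, rmax = rmax, wmin = wmin, wmax = wmax,
      w0 = w0, wshift_max = wshift_max, delta_t = delta_t, eta = eta,
      tau_I = tau_I, T_trial = T_trial, n_exp = as.integer(n_exp),
      neuron = neuron, dt = dt
    ),
    class = "error_task_config"
  )
}

#' Run one teacher-student regression trial
#'
#' Draws input rates, teacher weights and the global shift, generates the
#' Poisson input spikes, and integrates teacher, student and plastic
#' weights with the compiled simulator. Fresh randomness comes from R's
#' global RNG (seed it with [set.seed()] for reproducibility).
#'
#' @param rule a [compile_rule()] with arity 3 over `(v, u, sbar_j)`.
#' @param config an [error_task_config()].
#' @param record_every record decimated traces every this many steps
#'   (0 = no traces).
#' @return list with `valid`, `rmse` (root mean-squared potential error over
#'   the final 90% of the trial), `w_final`, `w_target` (shifted teacher
#'   weights), traces `t`, `v`, `u`, `w_trace`.
#' @export
run_error_trial <- function(rule, config, record_every = 0L) {
  stopifnot(length(rule$input_names) == 3L)
  sc <- sim_config(dt = config$dt, T_total = config$T_trial)
  rates <- runif(config$N, config$rmin, config$rmax)
  w_teach <- runif(config$N, config$wmin, config$wmax)
  wshift <- runif(1, -config$wshift_max, config$wshift_max)
  w_target <- w_teach + wshift
  spikes <- lapply(rates, poisson_train, T_ms = config$T_trial)
  ev <- pattern_events(spikes, sc)
  np <- config$neuron
  res <- error_trial_cpp(
    ev$step, ev$syn, sc$n_steps, config$N, w_target,
    rep(config$w0, config$N), rule$program,
    dt = config$dt, tau_m = np$tau_m, tau_syn = np$tau_syn,
    u_rest = np$u_rest, eta = config$eta, tau_I = config$tau_I,
    readout_every = as.integer(round(config$delta_t / config$dt)),
    frac_skip = 0.1, record_every = as.integer(record_every)
  )
  res$w_target <- w_target
  res$rates <- rates
  res
}

#' Fitness of a rule on the error-driven task
#'
#' Per experiment the error is the root mean-squared difference between
#' teacher and student membrane potential over the final 90% of the trial;
#' the fitness is the *negative* mean error across `n_exp` experiments, so
#' that higher fitness is better and the perfect-tracking optimum is 0.
#'
#' @param rule a [compile_rule()] (arity 3).
#' @param config an [error_task_config()].
#' @param seed integer seed; experiment `k` uses stream `seed + k`.
#' @return scalar fitness (`<= 0`, or `-Inf` for invalid rules) with
#'   attribute `per_experiment` (the per-experiment errors).
#' @export
fitness_error <- function(rule, config, seed = 1L) {
  errs <- numeric(config$n_exp)
  for (k in seq_len(config$n_exp)) {
    set.seed(seed + k)
    res <- run_error_trial(rule, config)
    if (!res$valid) {
      return(structure(-Inf, per_experiment = rep(Inf, config$n_exp)))
    }
    errs[k] <- res$rmse
  }
  structure(-mean(errs), per_experiment = errs)
}

#' Built-in error-driven reference rules
#'
#' The gradient-descent rule `(v-u)*sbar` plus the two discovered variants
#' that are asymptotically equivalent to it:
#' \describe{
#'   \item{grad}{`(v-u)*sbar`}
#'   \item{ER1}{`(v-u)*sbar*(2u-1)/v`}
#'   \item{ER2}{`sbar*(v+u)*(v*(v-u) - sbar)/v^2`}
#' }
#' Inputs are `(v, u, sbar)` as `x0, x1, x2`.
#'
#' @return named list of [compile_rule()] objects.
#' @export
error_reference_rules <- function() {
  inputs <- c("v", "u", "sbar")
  exprs <- c(
    grad = "(x0-x1)*x2",
    ER1 = "(((x0-x1)*x2)*((2.0*x1)-1.0))/x0",
    ER2 = "((x2*(x0+x1))*((x0*(x0-x1))-x2))/(x0*x0)"
  )
  lapply(exprs, compile_rule, input_names = inputs)
}

#' Asymptotic reduction of an error-driven rule
#'
#' In the operating regime of the task (`v` close to `u`, both large
#' compared to 1) every high-performing discovered rule reduces to
#' `c1*(v-u)*sbar + c2` with `c1` of order one and `c2` negligible. This
#' fits the rule's outputs over sampled operating points by least squares
#' and reports the constants and the relative RMS residual.
#'
#' @param rule a [compile_rule()] (arity 3 over `v, u, sbar`).
#' @param v_range range to sample `v` from (mV above rest).
#' @param du_range range of `u - v`.
#' @param sbar_range range of the filtered presynaptic trace.
#' @param n_samples number of sampled operating points.
#' @param seed RNG seed for the sampling.
#' @return list with `c1`, `c2`, `residual` (RMS misfit / RMS output).
#' @export
#' @examples
#' r <- error_reference_rules()$grad
#' asymptotic_reduce(r)$c1 # exactly 1
asymptotic_reduce <- function(rule, v_range = c(40, 80), du_range = c(-2, 2),
                              sbar_range = c(0, 1), n_samples = 2000L,
                              seed = 1L) {
  stopifnot(length(rule$input_names) == 3L)
  set.seed(seed)
  v <- runif(n_samples, v_range[1], v_range[2])
  u <- v + runif(n_samples, du_range[1], du_range[2])
  sbar <- runif(n_samples, sbar_range[1], sbar_range[2])
  y <- rule$fun(v, u, sbar)
  x <- (v - u) * sbar
  if (sd(x) == 0) {
    stop("asymptotic_reduce: degenerate sampling, (v-u)*sbar has no variance",
      call. = FALSE
    )
  }
  fit <- lm(y ~ x)
  resid_rms <- sqrt(mean(fit$residuals^2))
  out_rms <- sqrt(mean(y^2))
  list(
    c1 = unname(coef(fit)[2]), c2 = unname(coef(fit)[1]),
    residual = resid_rms / out_rms
  )
}
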