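#' Neuron parameters
#'
#' Parameters of the point-neuron models used by the task environments:
#' leaky integrators with either exponential or delta-shaped postsynaptic
#' currents, spiking stochastically through an exponential escape rate
#' `phi(u) = rho * exp((u - u_th) / delta_u)` or deterministically at a hard
#' threshold. Default potentials and time constants are conventional
#' cortical point-neuron values (times in ms, rates in Hz, potentials in
#' mV); they are package defaults, chosen once and documented in the methods
#' vignette.
#'
#' @param tau_m membrane time constant (ms), `> 0`.
#' @param u_rest resting potential (mV).
#' @param u_th threshold potential (mV).
#' @param delta_u escape-noise amplitude (mV), `> 0`.
#' @param rho firing rate at threshold (Hz), `>= 0`.
#' @param reset_mode `"instantaneous"` (reset to `u_rest` after each spike),
#'   `"none"` (membrane unaffected by own spikes) or `"lif"` (deterministic
#'   hard-threshold leaky integrate-and-fire with reset).
#' @param tau_syn synaptic time constant of the exponential PSC / filter
#'   kernel (ms).
#' @return a `neuron_params` list.
#' @export
neuron_params <- function(tau_m = 10, u_rest = -70, u_th = -55,
                          delta_u = 0.2, rho = 10,
                          reset_mode = c("instantaneous", "none", "lif"),
                          tau_syn = 5) {
  stopifnot(tau_m > 0, delta_u > 0, rho >= 0, tau_syn > 0)
  structure(
    list(
      tau_m = tau_m, u_rest = u_rest, u_th = u_th, delta_u = delta_u,
      rho = rho, reset_mode = match.arg(reset_mode), tau_syn = tau_syn
    ),
    class = "neuron_params"
  )
}

#' Simulation grid configuration
#'
#' @param dt fixed integration step (ms), `> 0`.
#' @param T_total simulation duration (ms), a multiple of `dt`.
#' @param seed integer seed for the stochastic components of a simulation.
#' @return a `sim_config` list with the derived step count `n_steps`.
#' @export
sim_config <- function(dt = 0.1, T_total, seed = 1L) {
  stopifnot(dt > 0, T_total > 0)
  n_steps <- round(T_total / dt)
  if (abs(n_steps * dt - T_total) > 1e-9 * T_total) {
    stop("sim_config: T_total must be a multiple of dt", call. = FALSE)
  }
  structure(
    list(dt = dt, T_total = T_total, n_steps = as.integer(n_steps), seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Maximum exponent allowed inside the escape rate; far above any operating
# regime, prevents numeric overflow only.
.escape_exp_clamp <- 30

#' Exponential escape rate
#'
#' Instantaneous firing rate of the stochastic neuron,
#' `phi(u) = rho * exp((u - u_th)/delta_u)` (in Hz for `rho` in Hz). In a
#' step of width `dt` a spike is emitted with probability
#' `1 - exp(-phi * dt)`, which stays exact for arbitrarily large rates. The
#' exponent is clamped at 30 to avoid overflow.
#'
#' @param u membrane potential (mV), vectorized.
#' @param params a [neuron_params()] object.
#' @return firing rate(s) in Hz.
#' @export
#' @examples
#' p <- neuron_params(rho = 10)
#' escape_rate(p$u_th, p) # == rho
escape_rate <- function(u, params) {
  params$rho * exp(pmin((u - params$u_th) / params$delta_u, .escape_exp_clamp))
}

#' Homogeneous Poisson spike train
#'
#' Draws a homogeneous Poisson process on `[0, T_ms]`: spike count
#' `~ Poisson(rate * T)`, times i.i.d. uniform, sorted. Uses R's global RNG.
#'
#' @param rate_hz rate in Hz (spikes/s), `>= 0`.
#' @param T_ms duration in ms.
#' @return sorted numeric vector of spike times (ms).
#' @export
poisson_train <- function(rate_hz, T_ms) {
  stopifnot(rate_hz >= 0, T_ms >= 0)
  n <- rpois(1L, rate_hz * T_ms / 1000)
  sort(runif(n, 0, T_ms))
}

#' Filter a spike train with a causal exponential kernel
#'
#' Produces the synaptically filtered trace `sbar(t)`: unit jump at each
#' spike, exponential decay with time constant `tau` in between, evaluated
#' on the simulation grid by exact per-step decay multiplication. Spikes are
#' assigned to the grid step containing them and take effect at the end of
#' that step (one-step synaptic delay convention).
#'
#' @param times sorted spike times (ms) in `[0, T_total]`.
#' @param tau kernel time constant (ms).
#' @param config a [sim_config()].
#' @return numeric vector of length `config$n_steps` (trace at the end of
#'   each step).
#' @export
filter_spikes <- function(times, tau, config) {
  stopifnot(tau > 0)
  counts <- spike_step_counts(times, config)
  as.numeric(stats::filter(counts, exp(-config$dt / tau), method = "recursive"))
}

# Spikes per grid step; a spike at time t lands in step ceil(t/dt) (step 1
# covers (0, dt]); t = 0 lands in step 1.
spike_step_counts <- function(times, config) {
  counts <- integer(config$n_steps)
  if (length(times) > 0L) {
    idx <- pmin(pmax(ceiling(times / config$dt), 1L), config$n_steps)
    tab <- tabulate(idx, nbins = config$n_steps)
    counts <- tab
  }
  counts
}

#' Subthreshold membrane trace of a leaky integrator (reference integrator)
#'
#' Pure-R reference implementation of the linear membrane subsystem, exact
#' per step: with `psc = "exp"` each input spike of weight `w` injects an
#' exponentially decaying current (time constant `tau_syn`) integrated by
#' the membrane; with `psc = "delta"` it causes an instantaneous jump of
#' size `w` in `u`. No spiking mechanism: this is the free membrane
#' potential. The compiled task simulators use the identical update
#' equations.
#'
#' @param spike_times list of per-input sorted spike-time vectors (ms).
#' @param weights numeric vector of synaptic weights (one per input).
#' @param params a [neuron_params()].
#' @param config a [sim_config()].
#' @param psc `"exp"` or `"delta"`.
#' @param u0 initial potential (default `u_rest`).
#' @return numeric vector of `u` at the end of each step.
#' @export
membrane_trace <- function(spike_times, weights, params, config,
                           psc = c("exp", "delta"), u0 = params$u_rest) {
  psc <- match.arg(psc)
  stopifnot(length(spike_times) == length(weights))
  dm <- exp(-config$dt / params$tau_m)
  drive <- numeric(config$n_steps)
  for (j in seq_along(spike_times)) {
    if (length(spike_times[[j]]) > 0L) {
      drive <- drive + weights[j] * spike_step_counts(spike_times[[j]], config)
    }
  }
  if (psc == "delta") {
    # u jumps by w at the spike step, then decays with tau_m.
    u_dev <- as.numeric(stats::filter(drive, dm, method = "recursive"))
    u_dev <- u_dev + (u0 - params$u_rest) * dm^seq_len(config$n_steps)
    return(params$u_rest + u_dev)
  }
  ds <- exp(-config$dt / params$tau_syn)
  # Exact propagation of the current->membrane cascade: current I is
  # piecewise exponential with jumps at step boundaries; its integral
  # against the membrane kernel over one step is c1 * I.
  c1 <- (ds - dm) * params$tau_m * params$tau_syn /
    (params$tau_syn - params$tau_m)
  u_dev <- numeric(config$n_steps)
  I <- 0
  u <- u0 - params$u_rest
  for (t in seq_len(config$n_steps)) {
    u <- u * dm + I * c1
    I <- I * ds + drive[t]
    u_dev[t] <- u
  }
  params$u_rest + u_dev
}

#' Frozen Poisson spike pattern
#'
#' Draws one frozen-noise spatio-temporal pattern: independent homogeneous
#' Poisson trains of rate `rate_hz` over `T_pattern` ms for `n_neurons`
#' inputs. The pattern is "frozen": the returned object is replayed
#' identically at every presentation. Neurons with at least one spike are
#' the *pattern neurons*.
#'
#' @param n_neurons number of input neurons.
#' @param T_pattern pattern duration (ms).
#' @param rate_hz Poisson rate (Hz), `>= 0`.
#' @return a `frozen_pattern` list: `spikes` (list of per-neuron time
#'   vectors), `pattern_neurons` (indices with >= 1 spike), `T_pattern`,
#'   `rate_hz`.
#' @export
frozen_pattern <- function(n_neurons, T_pattern, rate_hz) {
  stopifnot(rate_hz >= 0)
  spikes <- lapply(seq_len(n_neurons), function(i) poisson_train(rate_hz, T_pattern))
  structure(
    list(
      spikes = spikes,
      pattern_neurons = which(vapply(spikes, length, 1L) > 0L),
      T_pattern = T_pattern, rate_hz = rate_hz
    ),
    class = "frozen_pattern"
  )
}

#' Rate-balancing factor for pattern neurons
#'
#' In the correlation-driven task the frozen pattern (duration `T_pattern`)
#' alternates with Poisson background of duration `T_inter` at rate `nu`.
#' To prevent the output neuron from detecting the pattern through a rate
#' difference alone, pattern neurons spike at the reduced rate `alpha * nu`
#' between patterns. Background neurons average
#' `nu_inter = nu * T_inter / (T_inter + T_pattern)`; a pattern neuron
#' contributes one pattern spike per cycle, `nu_pattern = 1/(T_inter +
#' T_pattern)`, and rate balance gives `alpha = 1 - nu_pattern/nu_inter`.
#'
#' @param T_pattern pattern duration (ms).
#' @param T_inter inter-pattern duration (ms), `> 0`.
#' @param nu input rate (Hz).
#' @return a list with `alpha`, `nu_inter` (Hz), `nu_pattern` (Hz).
#' @export
#' @examples
#' balanced_rate_factor(100, 400, 5) # alpha = 0.5
balanced_rate_factor <- function(T_pattern, T_inter, nu) {
  stopifnot(T_inter > 0, nu > 0)
  nu_inter <- nu * T_inter / (T_inter + T_pattern)
  nu_pattern <- 1000 / (T_inter + T_pattern) # one spike per cycle, in Hz
  if (nu_pattern > nu_inter) {
    stop("balanced_rate_factor: pattern denser than achievable balance",
      call. = FALSE
    )
  }
  alpha <- 1 - nu_pattern / nu_inter
  stopifnot(alpha >= 0, alpha <= 1)
  list(alpha = alpha, nu_inter = nu_inter, nu_pattern = nu_pattern)
}

#' Write spike trains to CSV
#'
#' @param spikes list of per-neuron spike time vectors (ms).
#' @param path output file.
#' @return the path, invisibly. Columns: `neuron_id`, `time_ms`.
#' @export
write_spikes_csv <- function(spikes, path) {
  df <- data.frame(
    neuron_id = rep(seq_along(spikes), vapply(spikes, length, 1L)),
    time_ms = unlist(spikes)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
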