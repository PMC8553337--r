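#' Configuration of the correlation-driven pattern-detection task
#'
#' A leaky integrate-and-fire neuron with delta-shaped postsynaptic
#' currents receives `N` Poisson inputs through plastic synapses bounded in
#' `[0, 1]`. A frozen-noise pattern of duration `T_pattern` is replayed
#' every `T_inter` ms amid Poisson background spiking at rate `nu`; pattern
#' neurons spike at the reduced rate `alpha * nu` between patterns (see
#' [balanced_rate_factor()]) so the pattern cannot be detected through a
#' rate difference. Learning is pairing-based STDP with weight-dependent
#' homeostasis; performance is the signal-to-noise ratio of the free
#' membrane potential between pattern windows and inter-pattern intervals.
#'
#' Defaults follow the task construction: `N = 500`, `nu = 5` Hz,
#' `T_pattern = 100` ms, `T_inter = 400` ms, eligibility constant
#' `tau_elig = 20` ms, learning rate `eta = 0.01`. `J` (PSC amplitude per
#' unit weight, mV) and `w_hom` (the baseline rule's postsynaptic
#' homeostatic constant) are package calibrations chosen once so that an
#' untrained neuron fires irregularly and the baseline rule trains within
#' `n_train_cycles` pattern presentations.
#'
#' @param N number of inputs.
#' @param nu input rate (Hz).
#' @param T_pattern,T_inter pattern / inter-pattern durations (ms).
#' @param tau_elig eligibility (pairing) time constant (ms).
#' @param eta learning rate.
#' @param w_hom postsynaptic homeostatic constant of the baseline rule
#'   (dimensionless, `< 0`).
#' @param J membrane jump per input spike at unit weight (mV).
#' @param n_train_cycles training pattern presentations.
#' @param n_eval_cycles evaluation pattern presentations (frozen weights).
#' @param n_exp experiments per fitness evaluation (minimum aggregation).
#' @param w_init_range initial weights drawn uniformly from this range.
#' @param w_floor lower clip bound applied when a rule divides by the
#'   weight (`1e-3`); plain rules clip at 0.
#' @param neuron [neuron_params()]; hard-threshold LIF.
#' @param dt integration step (ms).
#' @return a `corr_task_config` list.
#' @export
corr_task_config <- function(N = 500L, nu = 5, T_pattern = 100, T_inter = 400,
                             tau_elig = 20, eta = 0.01, w_hom = -0.2,
                             J = 1.5, n_train_cycles = 200L,
                             n_eval_cycles = 20L, n_exp = 3L,
                             w_init_range = c(0.3, 0.7), w_floor = 1e-3,
                             neuron = neuron_params(
                               tau_m = 10, u_rest = -70, u_th = -55,
                               delta_u = 1, rho = 0, reset_mode = "lif"
                             ),
                             dt = 0.1) {
  stopifnot(n_exp >= 1L, T_inter > 0, eta > 0)
  structure(
    list(
      N = as.integer(N), nu = nu, T_pattern = T_pattern, T_inter = T_inter,
      tau_elig = tau_elig, eta = eta, w_hom = w_hom, J = J,
      n_train_cycles = as.integer(n_train_cycles),
      n_eval_cycles = as.integer(n_eval_cycles), n_exp = as.integer(n_exp),
      w_init_range = w_init_range, w_floor = w_floor, neuron = neuron, dt = dt
    ),
    class = "corr_task_config"
  )
}

#' Define a pairing-based STDP rule with homeostasis
#'
#' An STDP rule has four branches: `f_dep(w, E)` applied at presynaptic
#' spikes against the most recent postsynaptic spike (anticausal pairings,
#' `dt < 0`), `f_fac(w, E)` applied at postsynaptic spikes against the most
#' recent presynaptic spike (causal, `dt >= 0`), and homeostatic terms
#' `f_pre_hom(w)` / `f_post_hom(w)` triggered by every pre-/postsynaptic
#' spike. `E = exp(-|dt|/tau)` is the pairing eligibility. Branches are
#' given as infix expressions over `x0 = w` and (for the pairing branches)
#' `x1 = E`.
#'
#' @param dep,fac,pre_hom,post_hom infix expressions (characters).
#' @param name optional rule name.
#' @param needs_w_floor set `TRUE` for rules that divide by the weight so
#'   that clipping uses the `w_floor` of the task configuration.
#' @return an `stdp_rule` object with compiled branches.
#' @export
#' @examples
#' baseline <- stdp_rule(dep = "0.0", fac = "x1", pre_hom = "0.0",
#'                       post_hom = "-0.2")
stdp_rule <- function(dep, fac, pre_hom, post_hom, name = NULL,
                      needs_w_floor = FALSE) {
  branches <- list(
    dep = compile_rule(dep, c("w", "E")),
    fac = compile_rule(fac, c("w", "E")),
    pre_hom = compile_rule(pre_hom, c("w", "E")),
    post_hom = compile_rule(post_hom, c("w", "E"))
  )
  structure(
    list(
      branches = branches, name = name %||% "stdp_rule",
      needs_w_floor = needs_w_floor,
      key = paste(vapply(branches, `[[`, "", "expression_key"), collapse = "|")
    ),
    class = "stdp_rule"
  )
}

#' @export
print.stdp_rule <- function(x, ...) {
  b <- x$branches
  cat(sprintf(
    "<stdp_rule> %s\n  dep(w,E) = %s\n  fac(w,E) = %s\n  pre_hom(w) = %s\n  post_hom(w) = %s\n",
    x$name, b$dep$expression_key, b$fac$expression_key,
    b$pre_hom$expression_key, b$post_hom$expression_key
  ))
  invisible(x)
}

#' Built-in correlation-driven reference rules
#'
#' The homeostatic STDP baseline (no anticausal pairing term, causal term
#' `E`, constant negative homeostasis on postsynaptic spikes) and the two
#' discovered weight-dependent rules:
#' \describe{
#'   \item{baseline}{dep `0`, fac `E`, pre-hom `0`, post-hom `w_hom < 0`}
#'   \item{LR1}{dep `-(w-1)*E`, fac `E`, pre-hom `w`, post-hom `-w`}
#'   \item{LR2}{dep `-E/w`, fac `(w*E)^w`, pre-hom `w`, post-hom `-1`}
#' }
#'
#' @param w_hom homeostatic constant of the baseline rule.
#' @return named list of [stdp_rule()] objects.
#' @export
corr_reference_rules <- function(w_hom = -0.2) {
  list(
    baseline = stdp_rule(
      dep = "0.0", fac = "x1", pre_hom = "0.0",
      post_hom = format(w_hom, digits = 15),
      name = "baseline", needs_w_floor = FALSE
    ),
    LR1 = stdp_rule(
      dep = "(0.0-((x0-1.0)*x1))", fac = "x1",
      pre_hom = "x0", post_hom = "(0.0-x0)",
      name = "LR1", needs_w_floor = FALSE
    ),
    LR2 = stdp_rule(
      dep = "(0.0-(x1/x0))", fac = "(x0*x1)^x0",
      pre_hom = "x0", post_hom = "-1.0",
      name = "LR2", needs_w_floor = TRUE
    )
  )
}

#' Single STDP update for one pairing or spike event
#'
#' Reference implementation of the per-event weight change: pairing branch
#' chosen by the sign of `dt = t_post - t_pre` with eligibility
#' `E = exp(-|dt|/tau)`, plus the homeostatic term of the triggering side
#' (`pre` events add `f_pre_hom`, `post` events add `f_post_hom`). The
#' result `w + eta * f` is clipped to the weight bounds.
#'
#' @param rule an [stdp_rule()].
#' @param w current weight in `[0, 1]`.
#' @param dt_pair spike-time difference `t_post - t_pre` (ms); its sign
#'   selects the branch.
#' @param tau pairing time constant (ms).
#' @param eta learning rate.
#' @param trigger `"pre"` or `"post"`: which spike triggered the update.
#' @param w_floor lower clip bound.
#' @return list with `dw` (the applied `eta * f`) and `w_new` (clipped).
#' @export
#' @examples
#' lr2 <- corr_reference_rules()$LR2
#' stdp_update(lr2, w = 0.5, dt_pair = 10, tau = 20, eta = 0.01,
#'             trigger = "post")
stdp_update <- function(rule, w, dt_pair, tau, eta, trigger = c("post", "pre"),
                        w_floor = 0) {
  trigger <- match.arg(trigger)
  E <- exp(-abs(dt_pair) / tau)
  pair <- if (dt_pair < 0) {
    rule$branches$dep$fun(w, E)
  } else {
    rule$branches$fac$fun(w, E)
  }
  hom <- if (trigger == "pre") {
    rule$branches$pre_hom$fun(w, 0)
  } else {
    rule$branches$post_hom$fun(w, 0)
  }
  f <- pair + hom
  if (!is.finite(f)) invalid_evaluation("non-finite STDP update")
  dw <- eta * f
  list(dw = dw, w_new = min(1, max(w_floor, w + dw)))
}

#' STDP kernel of a rule
#'
#' The pairing-induced weight change `eta * f(w, E)` as a function of the
#' spike-timing difference, for plotting and for checking branch signs.
#'
#' @param rule an [stdp_rule()].
#' @param w weight at which to evaluate the kernel.
#' @param dt_range vector of `t_post - t_pre` values (ms).
#' @param tau pairing time constant (ms).
#' @param eta learning rate.
#' @return data.frame with columns `dt`, `w`, `dw`.
#' @export
stdp_kernel <- function(rule, w, dt_range = seq(-50, 50, by = 1), tau = 20,
                        eta = 0.01) {
  E <- exp(-abs(dt_range) / tau)
  dw <- ifelse(dt_range < 0,
    rule$branches$dep$fun(rep(w, length(E)), E),
    rule$branches$fac$fun(rep(w, length(E)), E)
  )
  data.frame(dt = dt_range, w = w, dw = eta * dw)
}

# Build the full input spike sequence for n_cycles of [inter | pattern]:
# background neurons spike Poisson(nu) during inter segments and are silent
# during the pattern; pattern neurons replay their frozen spikes in every
# pattern window and spike at the reduced rate alpha_j*nu in between so
# their long-run rate matches the background neurons'. For a neuron with a
# single pattern spike alpha_j is the balanced_rate_factor() value; neurons
# that drew several pattern spikes get a proportionally smaller alpha_j
# (clipped at 0), keeping the balance exact in expectation. Returns the
# sorted event list plus the pattern windows (ms).
build_corr_input <- function(config, pattern, n_cycles) {
  bal <- balanced_rate_factor(config$T_pattern, config$T_inter, config$nu)
  cycle <- config$T_inter + config$T_pattern
  is_pat <- seq_len(config$N) %in% pattern$pattern_neurons
  times <- vector("list", config$N)
  for (j in seq_len(config$N)) {
    n_j <- length(pattern$spikes[[j]])
    rate_inter <- if (is_pat[j]) {
      max(0, (bal$nu_inter - n_j * 1000 / cycle) * cycle / config$T_inter)
    } else {
      config$nu
    }
    tj <- numeric(0)
    for (k in seq_len(n_cycles)) {
      off <- (k - 1) * cycle
      tj <- c(tj, off + poisson_train(rate_inter, config$T_inter))
      if (is_pat[j]) {
        tj <- c(tj, off + config$T_inter + pattern$spikes[[j]])
      }
    }
    times[[j]] <- tj
  }
  windows <- cbind(
    start = (seq_len(n_cycles) - 1) * cycle + config$T_inter,
    end = (seq_len(n_cycles) - 1) * cycle + config$T_inter + config$T_pattern
  )
  sc <- sim_config(dt = config$dt, T_total = n_cycles * cycle)
  list(
    events = pattern_events(times, sc), sim = sc, windows = windows,
    times = times
  )
}

corr_sim <- function(input, w, config, rule, spiking, plastic, record_u) {
  np <- config$neuron
  b <- rule$branches
  corr_train_cpp(
    input$events$step, input$events$syn, input$sim$n_steps, config$N, w,
    b$dep$program, b$fac$program, b$pre_hom$program, b$post_hom$program,
    dt = config$dt, tau_m = np$tau_m, u_rest = np$u_rest, u_th = np$u_th,
    J = config$J, tau_elig = config$tau_elig, eta = config$eta,
    w_min = if (rule$needs_w_floor) config$w_floor else 0,
    spiking = spiking, plastic = plastic, record_u = record_u
  )
}

#' Free membrane potential with frozen weights
#'
#' Simulates the output neuron with the spiking mechanism disabled
#' (threshold and reset off) and weights frozen, removing the measurement
#' noise that resets would add to the signal-to-noise ratio.
#'
#' @param weights frozen weight vector.
#' @param input an input sequence from `build_corr_input` (or compatible
#'   list with `events` and `sim`).
#' @param config a [corr_task_config()].
#' @return numeric membrane-potential trace (mV) on the simulation grid.
#' @export
free_membrane_trace <- function(weights, input, config) {
  rule <- corr_reference_rules()$baseline
  res <- corr_sim(input, weights, config, rule,
    spiking = FALSE, plastic = FALSE, record_u = TRUE
  )
  res$u
}

#' Signal-to-noise ratio of a membrane trace
#'
#' `SNR = (<u_max per pattern window> - <u_inter>) / Std(u_inter)`, where
#' `u_max` is the maximal free membrane potential within each pattern
#' window and `u_inter` the trace restricted to the inter-pattern
#' intervals. Adding a constant to the whole trace leaves the SNR
#' unchanged.
#'
#' @param trace membrane trace on the simulation grid.
#' @param windows two-column matrix of pattern window `start`/`end` times
#'   (ms).
#' @param dt grid step (ms).
#' @return scalar SNR; `+Inf` with a warning if the inter-pattern variance
#'   is zero.
#' @export
snr <- function(trace, windows, dt) {
  stopifnot(nrow(windows) >= 2)
  n <- length(trace)
  t_grid <- seq_len(n) * dt
  in_pattern <- rep(FALSE, n)
  u_max <- numeric(nrow(windows))
  for (k in seq_len(nrow(windows))) {
    idx <- which(t_grid > windows[k, 1] & t_grid <= windows[k, 2])
    u_max[k] <- max(trace[idx])
    in_pattern[idx] <- TRUE
  }
  u_inter <- trace[!in_pattern]
  if (length(u_inter) < 1L) stop("snr: no inter-pattern samples", call. = FALSE)
  s <- sd(u_inter)
  if (s == 0) {
    warning("snr: zero inter-pattern variance; SNR undefined, returning Inf")
    return(Inf)
  }
  (mean(u_max) - mean(u_inter)) / s
}

#' Run one correlation-task experiment
#'
#' Draws a fresh frozen pattern and initial weights, trains the synapses
#' with the given STDP rule for `n_train_cycles` pattern presentations,
#' then evaluates the frozen final weights on a fresh evaluation sequence:
#' the free-membrane SNR plus the spiking neuron's hit rate (fraction of
#' pattern windows with >= 1 spike) and inter-window false-alarm rate.
#'
#' @param rule an [stdp_rule()].
#' @param config a [corr_task_config()].
#' @return list with `snr`, `snr_untrained`, `hit_rate`, `false_rate`,
#'   `w_final`, `valid`, `pattern`.
#' @export
run_corr_experiment <- function(rule, config) {
  pattern <- frozen_pattern(config$N, config$T_pattern, config$nu)
  w0 <- runif(config$N, config$w_init_range[1], config$w_init_range[2])
  if (rule$needs_w_floor) w0 <- pmax(w0, config$w_floor)

  train_in <- build_corr_input(config, pattern, config$n_train_cycles)
  trained <- corr_sim(train_in, w0, config, rule,
    spiking = TRUE, plastic = TRUE, record_u = FALSE
  )
  if (!trained$valid) {
    return(list(valid = FALSE, snr = -Inf))
  }

  eval_in <- build_corr_input(config, pattern, config$n_eval_cycles)
  free_trained <- free_membrane_trace(trained$w_final, eval_in, config)
  free_untrained <- free_membrane_trace(w0, eval_in, config)
  snr_trained <- snr(free_trained, eval_in$windows, config$dt)
  snr_untrained <- snr(free_untrained, eval_in$windows, config$dt)

  spiking_eval <- corr_sim(eval_in, trained$w_final, config,
    corr_reference_rules()$baseline,
    spiking = TRUE, plastic = FALSE, record_u = FALSE
  )
  post_t <- (spiking_eval$post_steps + 1) * config$dt
  wins <- eval_in$windows
  hits <- vapply(seq_len(nrow(wins)), function(k) {
    any(post_t > wins[k, 1] & post_t <= wins[k, 2])
  }, logical(1))
  # False alarms: spikes in equal-length windows ending at each pattern start.
  false <- vapply(seq_len(nrow(wins)), function(k) {
    any(post_t > wins[k, 1] - config$T_pattern & post_t <= wins[k, 1])
  }, logical(1))

  list(
    valid = TRUE, snr = snr_trained, snr_untrained = snr_untrained,
    hit_rate = mean(hits), false_rate = mean(false),
    w_final = trained$w_final, pattern = pattern
  )
}

#' Fitness of a rule on the correlation-driven task
#'
#' Trains on `n_exp` independent experiments (fresh pattern, background and
#' initial weights each) and returns the **minimum** SNR across
#' experiments -- the worst-case aggregation used for this task family.
#'
#' @param rule an [stdp_rule()].
#' @param config a [corr_task_config()].
#' @param seed integer seed; experiment `k` uses stream `seed + k`.
#' @return scalar fitness (`-Inf` for invalid rules) with attribute
#'   `per_experiment`.
#' @export
fitness_corr <- function(rule, config, seed = 1L) {
  per <- numeric(config$n_exp)
  for (k in seq_len(config$n_exp)) {
    set.seed(seed + k)
    res <- run_corr_experiment(rule, config)
    if (!res$valid) {
      return(structure(-Inf, per_experiment = rep(-Inf, config$n_exp)))
    }
    per[k] <- res$snr
  }
  structure(min(per), per_experiment = per)
}
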