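#' Toy symbolic-regression fitness (evolution smoke task)
#'
#' Builds a fitness function for [evolve_rules()] that scores an individual
#' by the negative mean squared error between its expression and a target
#' function on fixed probe points. Used to exercise the full evolutionary
#' loop at desk scale with a known optimum.
#'
#' @param target_fn function of the probe matrix rows returning the target
#'   values, e.g. `function(X) X[, 1] * X[, 3]`.
#' @param n_inputs arity of the evolved expressions.
#' @param n_probes number of probe points.
#' @param probe_range range to draw probes from.
#' @param seed seed for the (fixed) probe sample.
#' @return function(individual) -> fitness (`-Inf` if the expression is
#'   non-finite on any probe).
#' @export
symbolic_regression_fitness <- function(target_fn, n_inputs, n_probes = 40L,
                                        probe_range = c(-2, 2), seed = 1L) {
  rng <- local({
    set.seed(seed)
    matrix(runif(n_probes * n_inputs, probe_range[1], probe_range[2]),
      nrow = n_probes
    )
  })
  target <- target_fn(rng)
  function(individual) {
    vals <- do.call(
      individual$fun %||% compile_rule_fun(individual$graph),
      lapply(seq_len(n_inputs), function(j) rng[, j])
    )
    if (!all(is.finite(vals))) {
      return(-Inf)
    }
    -mean((vals - target)^2)
  }
}

#' Read and validate a run configuration
#'
#' Run configurations are YAML files with the blocks `task` (one of
#' `reward`, `error`, `correlation`, `regression`), `seed`, `evolution`
#' (fields of [evolution_params()]), `cgp` (fields of [cgp_dims()] plus
#' `include_pow`) and `task_config` (fields of the task's config
#' constructor). Unknown keys anywhere are rejected to guard against silent
#' misconfiguration. All stochastic components derive from the single
#' `seed`.
#'
#' @param path YAML file path.
#' @return a validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("read_run_config requires the 'yaml' package", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  known_top <- c("task", "seed", "evolution", "cgp", "task_config")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown) > 0) {
    stop(
      "unknown configuration keys: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  task <- match.arg(raw$task, c("reward", "error", "correlation", "regression"))
  check_block <- function(block, allowed, label) {
    bad <- setdiff(names(block), allowed)
    if (length(bad) > 0) {
      stop("unknown ", label, " keys: ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    block
  }
  evo <- check_block(
    raw$evolution %||% list(),
    setdiff(names(formals(evolution_params)), "seed"), "evolution"
  )
  cgp <- check_block(
    raw$cgp %||% list(),
    c(names(formals(cgp_dims)), "include_pow"), "cgp"
  )
  ctor <- switch(task,
    reward = reward_task_config, error = error_task_config,
    correlation = corr_task_config, regression = NULL
  )
  tc <- raw$task_config %||% list()
  if (!is.null(ctor)) {
    tc <- check_block(tc, setdiff(names(formals(ctor)), c("neuron")), "task_config")
  }
  structure(
    list(
      task = task, seed = as.integer(raw$seed %||% 1L),
      evolution = evo, cgp = cgp, task_config = tc
    ),
    class = "run_config"
  )
}

# Task input signature and fitness wiring used for evolution.
task_evolution_setup <- function(run_config) {
  tc <- run_config$task_config
  seed <- run_config$seed
  switch(run_config$task,
    reward = {
      config <- do.call(reward_task_config, tc)
      n_in <- if (config$baseline_mode == "split") 4L else 3L
      list(
        n_inputs = n_in, n_outputs = 1L,
        fitness_fn = function(ind) {
          rule <- compile_rule(ind$graph, paste0("x", seq_len(n_in) - 1L))
          as.numeric(fitness_reward(rule, config, seed = seed, scale = "paper"))
        }
      )
    },
    error = {
      config <- do.call(error_task_config, tc)
      list(
        n_inputs = 3L, n_outputs = 1L,
        fitness_fn = function(ind) {
          rule <- compile_rule(ind$graph, c("v", "u", "sbar"))
          as.numeric(fitness_error(rule, config, seed = seed))
        }
      )
    },
    correlation = {
      config <- do.call(corr_task_config, tc)
      # One genome with four outputs: dep, fac, pre-hom, post-hom branches.
      list(
        n_inputs = 2L, n_outputs = 4L,
        fitness_fn = function(ind) {
          ex <- ind$graph$expressions
          rule <- stdp_rule(ex[1], ex[2], ex[3], ex[4],
            needs_w_floor = TRUE
          )
          as.numeric(fitness_corr(rule, config, seed = seed))
        }
      )
    },
    regression = {
      list(
        n_inputs = 3L, n_outputs = 1L,
        fitness_fn = symbolic_regression_fitness(
          function(X) X[, 1] * X[, 3], 3L,
          seed = seed
        )
      )
    }
  )
}

#' Run an evolutionary search from a configuration
#'
#' Drives the full loop for one task family: builds the task fitness
#' function (the identical task sample, derived from the run seed, is used
#' in every generation), runs [evolve_rules()] and optionally writes a
#' JSON-lines per-generation log plus a best-expression file.
#'
#' @param run_config a [read_run_config()] object (or a list with the same
#'   fields).
#' @param out_dir optional output directory for `evolution_log.jsonl` and
#'   `best_expression.txt`.
#' @return the [evolve_rules()] result.
#' @export
evolve_run <- function(run_config, out_dir = NULL) {
  setup <- task_evolution_setup(run_config)
  cgp <- run_config$cgp
  include_pow <- isTRUE(cgp$include_pow)
  cgp$include_pow <- NULL
  dims <- do.call(cgp_dims, modifyList(
    list(n_inputs = setup$n_inputs, n_outputs = setup$n_outputs), cgp
  ))
  primitives <- default_primitives(include_pow = include_pow)
  params <- do.call(evolution_params, modifyList(
    list(seed = run_config$seed), run_config$evolution
  ))
  log_file <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    log_file <- file.path(out_dir, "evolution_log.jsonl")
    if (file.exists(log_file)) file.remove(log_file)
  }
  res <- evolve_rules(setup$fitness_fn, dims, primitives, params,
    log_file = log_file
  )
  if (!is.null(out_dir)) {
    writeLines(res$best$graph$key, file.path(out_dir, "best_expression.txt"))
  }
  res
}

#' Evaluate a named or explicit rule on a task
#'
#' Checks printed or hand-written rules without running evolution: reports
#' per-experiment and aggregate fitness over one or more seeds.
#'
#' @param task `"reward"`, `"error"` or `"correlation"`.
#' @param expression an infix expression (for reward/error tasks), a
#'   reference-rule name (e.g. `"LR0"`, `"grad"`, `"baseline"`), or an
#'   [stdp_rule()] for the correlation task.
#' @param config the task's configuration object (defaults are used when
#'   `NULL`).
#' @param seeds integer vector of evaluation seeds.
#' @param scale forwarded to [fitness_reward()] for the reward task.
#' @return data.frame with one row per seed (`seed`, `fitness`) plus the
#'   attribute `aggregate` (mean and sd).
#' @export
eval_rule <- function(task = c("reward", "error", "correlation"), expression,
                      config = NULL, seeds = 1L, scale = "paper") {
  task <- match.arg(task)
  fit_one <- switch(task,
    reward = {
      config <- config %||% reward_task_config()
      rules <- reward_reference_rules()
      rule <- if (is.character(expression) && expression %in% names(rules)) {
        rules[[expression]]
      } else {
        n_in <- if (config$baseline_mode == "split") 4L else 3L
        compile_rule(expression, paste0("x", seq_len(n_in) - 1L))
      }
      function(s) as.numeric(fitness_reward(rule, config, seed = s, scale = scale))
    },
    error = {
      config <- config %||% error_task_config()
      rules <- error_reference_rules()
      rule <- if (is.character(expression) && expression %in% names(rules)) {
        rules[[expression]]
      } else {
        compile_rule(expression, c("v", "u", "sbar"))
      }
      function(s) as.numeric(fitness_error(rule, config, seed = s))
    },
    correlation = {
      config <- config %||% corr_task_config()
      rules <- corr_reference_rules(w_hom = config$w_hom)
      rule <- if (inherits(expression, "stdp_rule")) {
        expression
      } else if (is.character(expression) && expression %in% names(rules)) {
        rules[[expression]]
      } else {
        stop("correlation task: expression must name a reference rule ",
          "or be an stdp_rule object",
          call. = FALSE
        )
      }
      function(s) as.numeric(fitness_corr(rule, config, seed = s))
    }
  )
  fitness <- vapply(seeds, fit_one, numeric(1))
  out <- data.frame(seed = seeds, fitness = fitness)
  attr(out, "aggregate") <- c(
    mean = mean(fitness),
    sd = if (length(fitness) > 1) sd(fitness) else NA_real_
  )
  out
}

#' Write deterministic miniature task fixtures
#'
#' Generates small instances used by the unit-test suite: one frozen-noise
#' pattern set (correlation task), one teacher configuration (error task)
#' and one reward pattern set, all as plain-text CSV/JSON derived
#' deterministically from the seed.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return invisible character vector of the written file paths.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  paths <- character(0)

  pat <- frozen_pattern(n_neurons = 20, T_pattern = 50, rate_hz = 20)
  p1 <- file.path(dir, "frozen_pattern.csv")
  write_spikes_csv(pat$spikes, p1)

  teacher <- list(
    rates_hz = round(runif(5, 10, 50), 4),
    w_teacher = round(runif(5, 0.5, 1.5), 4),
    w_shift = round(runif(1, -0.25, 0.25), 4)
  )
  p2 <- file.path(dir, "teacher_config.json")
  jsonlite::write_json(teacher, p2, digits = NA)

  cfg <- reward_task_config(N = 10L, M = 2L, T_trial = 200)
  exp_small <- make_reward_experiment(cfg)
  p3 <- file.path(dir, "reward_patterns.csv")
  df <- do.call(rbind, lapply(seq_along(exp_small$patterns), function(m) {
    sp <- exp_small$patterns[[m]]$spikes
    data.frame(
      pattern = m, active = exp_small$active[m],
      neuron_id = rep(seq_along(sp), vapply(sp, length, 1L)),
      time_ms = round(unlist(sp), 6)
    )
  }))
  utils::write.csv(df, p3, row.names = FALSE)

  invisible(c(p1, p2, p3))
}
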