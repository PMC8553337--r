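#' Parameters of the mu+lambda evolution strategy
#'
#' Each generation, `lam` offspring are created from the `mu` parents by
#' tournament selection (default tournament size one, i.e. uniform parent
#' choice) followed by per-gene mutation; the best `mu` of the combined
#' parent+offspring population become the next parents. *Neutral search*:
#' an offspring is preferred over a parent of equal fitness, letting silent
#' mutations accumulate and drift across fitness plateaus.
#'
#' @param mu parent population size.
#' @param lam offspring population size.
#' @param n_generations number of generations to run.
#' @param tournament_size subset size for tournament selection (without
#'   replacement); size one reduces to uniform random parent choice.
#' @param p_mutate per-gene mutation probability.
#' @param seed integer seed fixing the full evolution trajectory.
#' @param n_sample_tasks number of task samples per fitness evaluation
#'   (forwarded to the task's fitness function).
#' @return an `evolution_params` list.
#' @export
evolution_params <- function(mu = 4L, lam = 4L, n_generations = 100L,
                             tournament_size = 1L, p_mutate = 0.1,
                             seed = 1L, n_sample_tasks = 1L) {
  stopifnot(mu >= 1L, lam >= 1L, tournament_size >= 1L, n_generations >= 0L)
  structure(
    list(
      mu = as.integer(mu), lam = as.integer(lam),
      n_generations = as.integer(n_generations),
      tournament_size = as.integer(tournament_size),
      p_mutate = p_mutate, seed = as.integer(seed),
      n_sample_tasks = as.integer(n_sample_tasks)
    ),
    class = "evolution_params"
  )
}

#' Tournament selection
#'
#' Draws a uniform subset (without replacement) of the population and
#' returns its maximal-fitness member; ties within the subset resolve to the
#' first drawn.
#'
#' @param population list of individuals, each with a numeric `fitness`.
#' @param size tournament size, `1 <= size <= length(population)`.
#' @return the selected individual.
#' @export
tournament_select <- function(population, size) {
  if (length(population) == 0L) {
    stop("tournament_select: empty population", call. = FALSE)
  }
  stopifnot(size >= 1L, size <= length(population))
  idx <- sample.int(length(population), size)
  fit <- vapply(population, function(i) i$fitness, numeric(1))[idx]
  population[[idx[which.max(fit)]]]
}

#' Aggregate per-task fitness values into a scalar
#'
#' Mean aggregation is used for the reward- and error-driven task families,
#' minimum aggregation for the correlation-driven family (worst-case
#' signal-to-noise ratio). Any `-Inf` element (invalid rule evaluation) is
#' absorbing.
#'
#' @param values non-empty numeric vector of per-task fitness values.
#' @param mode `"mean"` or `"min"`.
#' @return a scalar fitness.
#' @export
aggregate_fitness <- function(values, mode = c("mean", "min")) {
  mode <- match.arg(mode)
  if (length(values) == 0L) {
    stop("aggregate_fitness: empty value collection", call. = FALSE)
  }
  if (any(values == -Inf)) {
    return(-Inf)
  }
  if (mode == "mean") mean(values) else min(values)
}

new_individual <- function(genome) {
  graph <- decode(genome)
  list(genome = genome, graph = graph, key = graph$key, fitness = NA_real_)
}

#' Evaluate an individual through the phenotype-level fitness cache
#'
#' The cache is keyed on the canonical expression key (plus a caller-chosen
#' task-sample signature appended by [evolve_rules()]), so genomes that
#' differ only in inactive genes trigger a single simulation. `-Inf` results
#' are cached like any other value. An error of class
#' `evoplast_invalid_evaluation` raised by the fitness function -- or a
#' non-finite return -- is converted to `-Inf`.
#'
#' @param individual an individual (list with `graph`, `key`).
#' @param fitness_fn function taking the individual and returning a scalar.
#' @param cache an environment used as key-value store, or `NULL` to disable
#'   caching (values are then always recomputed; results are unchanged).
#' @param cache_key optional explicit key; defaults to the expression key.
#' @return the fitness value (may be `-Inf`).
#' @export
evaluate_with_cache <- function(individual, fitness_fn, cache = NULL,
                                cache_key = individual$key) {
  if (!is.null(cache) && !is.null(cache[[cache_key]])) {
    return(cache[[cache_key]])
  }
  fit <- tryCatch(
    fitness_fn(individual),
    evoplast_invalid_evaluation = function(e) -Inf
  )
  if (!is.numeric(fit) || length(fit) != 1L || is.na(fit) || is.nan(fit)) fit <- -Inf
  if (!is.null(cache)) cache[[cache_key]] <- fit
  fit
}

#' Signal an invalid rule evaluation
#'
#' Used by task environments when a rule produces a non-finite weight change
#' (e.g. division by zero); evolution converts it to fitness `-Inf` instead
#' of letting non-finite values propagate into simulation state.
#'
#' @param message error message.
#' @export
invalid_evaluation <- function(message = "invalid rule evaluation") {
  stop(structure(
    class = c("evoplast_invalid_evaluation", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

# One mu+lambda generation with neutral tie-breaking. `state` carries
# parents (all evaluated), the cache environment and counters.
step_generation <- function(state, fitness_fn, params) {
  parents <- state$parents
  offspring <- vector("list", params$lam)
  for (i in seq_len(params$lam)) {
    parent <- tournament_select(parents, min(params$tournament_size, length(parents)))
    off <- mutate(parent$genome, params$p_mutate)
    offspring[[i]] <- new_individual(off$genome)
  }
  for (i in seq_along(offspring)) {
    hit <- !is.null(state$cache) && !is.null(state$cache[[offspring[[i]]$key]])
    if (hit) state$cache_hits <- state$cache_hits + 1L else {
      state$cache_misses <- state$cache_misses + 1L
    }
    offspring[[i]]$fitness <- evaluate_with_cache(
      offspring[[i]], fitness_fn, state$cache
    )
  }
  combined <- c(parents, offspring)
  fit <- vapply(combined, function(i) i$fitness, numeric(1))
  is_parent <- c(rep(1L, length(parents)), rep(0L, length(offspring)))
  # Offspring first among equal fitness: neutral search.
  ord <- order(-fit, is_parent)
  state$parents <- combined[ord[seq_len(params$mu)]]
  state$generation <- state$generation + 1L
  state
}

#' Run the evolutionary search for plasticity rules
#'
#' Implements the mu+lambda evolution strategy with tournament selection,
#' mutation-only variation (no crossover), neutral search and fitness
#' caching at the phenotype level. The fitness function receives a
#' `compiled_rule`-like individual (with `graph`, `key` and, for
#' convenience, `fun`) and must return a scalar; invalid expressions get
#' `-Inf` and never abort the run. The identical task sample is used in
#' every generation (the sample seed is derived from `params$seed` only), so
#' fitness values are comparable across generations.
#'
#' @param fitness_fn function(individual) -> scalar fitness.
#' @param dims a [cgp_dims()] object.
#' @param primitives a [default_primitives()] set.
#' @param params an [evolution_params()] object.
#' @param use_cache logical; disabling the cache changes evaluation counts,
#'   never fitness values.
#' @param log_file optional path; one JSON line per generation is appended.
#' @return an `evolution_result` list: `best` individual, `parents`,
#'   `history` (data.frame per generation), `cache_hits`, `cache_misses`,
#'   `n_evaluations`.
#' @export
evolve_rules <- function(fitness_fn, dims, primitives, params,
                         use_cache = TRUE, log_file = NULL) {
  set.seed(params$seed)
  eval_count <- 0L
  counted_fitness <- function(ind) {
    eval_count <<- eval_count + 1L
    ind$fun <- compile_rule_fun(ind$graph)
    fitness_fn(ind)
  }

  state <- new.env(parent = emptyenv())
  state$cache <- if (use_cache) new.env(parent = emptyenv()) else NULL
  state$cache_hits <- 0L
  state$cache_misses <- 0L
  state$generation <- 0L
  state$parents <- lapply(seq_len(params$mu), function(i) {
    new_individual(random_genome(dims, primitives))
  })
  for (i in seq_along(state$parents)) {
    if (!is.null(state$cache) && !is.null(state$cache[[state$parents[[i]]$key]])) {
      state$cache_hits <- state$cache_hits + 1L
    } else {
      state$cache_misses <- state$cache_misses + 1L
    }
    state$parents[[i]]$fitness <- evaluate_with_cache(
      state$parents[[i]], counted_fitness, state$cache
    )
  }

  history <- vector("list", params$n_generations + 1L)
  log_gen <- function() {
    fit <- vapply(state$parents, function(i) i$fitness, numeric(1))
    best <- state$parents[[which.max(fit)]]
    row <- data.frame(
      generation = state$generation,
      best_fitness = best$fitness,
      best_expression = paste(best$graph$expressions, collapse = ";"),
      cache_hits = state$cache_hits,
      cache_misses = state$cache_misses,
      stringsAsFactors = FALSE
    )
    if (!is.null(log_file)) {
      cat(jsonlite::toJSON(as.list(row), auto_unbox = TRUE), "\n",
        file = log_file, append = TRUE, sep = ""
      )
    }
    row
  }
  history[[1L]] <- log_gen()

  for (gen in seq_len(params$n_generations)) {
    state <- step_generation(state, counted_fitness, params)
    history[[gen + 1L]] <- log_gen()
  }

  fit <- vapply(state$parents, function(i) i$fitness, numeric(1))
  structure(
    list(
      best = state$parents[[which.max(fit)]],
      parents = state$parents,
      history = do.call(rbind, history),
      cache_hits = state$cache_hits,
      cache_misses = state$cache_misses,
      n_evaluations = eval_count,
      params = params
    ),
    class = "evolution_result"
  )
}

#' @export
print.evolution_result <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf(
    "<evolution_result> %d generations, best fitness %.6g\n  best: %s\n  evaluations: %d (cache hits %d)\n",
    n - 1L, x$best$fitness, x$best$graph$key, x$n_evaluations, x$cache_hits
  ))
  invisible(x)
}
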