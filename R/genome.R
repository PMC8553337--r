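#' Cartesian graph dimensions
#'
#' The genotype is laid out on a fixed two-dimensional grid of internal nodes
#' (`n_rows` x `n_columns`). Each internal node may read from the input nodes
#' and from internal nodes at most `levels_back` columns to its left, so the
#' decoded computational graph is always acyclic. The default of a single row
#' of 12 columns with full `levels_back` keeps decoded expressions small and
#' interpretable.
#'
#' @param n_inputs number of input nodes (the arity of the evolved function).
#' @param n_outputs number of output genes (one per evolved function branch).
#' @param n_rows,n_columns grid dimensions; `n_rows * n_columns >= 1`.
#' @param levels_back how many columns to the left a node may connect to;
#'   defaults to `n_columns` (full range).
#' @return a `cgp_dims` list.
#' @export
cgp_dims <- function(n_inputs, n_outputs = 1L, n_rows = 1L, n_columns = 12L,
                     levels_back = n_columns) {
  n_inputs <- as.integer(n_inputs)
  n_outputs <- as.integer(n_outputs)
  n_rows <- as.integer(n_rows)
  n_columns <- as.integer(n_columns)
  levels_back <- as.integer(levels_back)
  if (n_inputs < 1L || n_outputs < 1L) {
    stop("cgp_dims: need at least one input and one output", call. = FALSE)
  }
  if (n_rows < 0L || n_columns < 0L || n_rows * n_columns < 0L) {
    stop("cgp_dims: inconsistent grid dimensions", call. = FALSE)
  }
  if (n_rows * n_columns == 0L && (n_rows != 0L || n_columns != 0L)) {
    stop("cgp_dims: inconsistent grid dimensions", call. = FALSE)
  }
  if (levels_back < 1L && n_rows * n_columns > 0L) {
    stop("cgp_dims: levels_back must be >= 1", call. = FALSE)
  }
  structure(
    list(
      n_inputs = n_inputs, n_outputs = n_outputs,
      n_rows = n_rows, n_columns = n_columns, levels_back = levels_back
    ),
    class = "cgp_dims"
  )
}

n_internal <- function(dims) dims$n_rows * dims$n_columns

# Column (1-based) of internal node slot k in column-major order.
internal_column <- function(dims, k) ((k - 1L) %/% dims$n_rows) + 1L

# Node indices (1-based over inputs then internal nodes) that an internal
# node in column `col` may legally read from.
allowed_sources <- function(dims, col) {
  first_col <- max(1L, col - dims$levels_back)
  cols <- seq_len(n_internal(dims))
  legal_internal <- cols[internal_column(dims, cols) >= first_col &
    internal_column(dims, cols) < col]
  c(seq_len(dims$n_inputs), dims$n_inputs + legal_internal)
}

# Node indices an output gene may point at: any input or internal node.
allowed_output_sources <- function(dims) {
  seq_len(dims$n_inputs + n_internal(dims))
}

#' Draw a random Cartesian genome
#'
#' Every operator gene is drawn uniformly over the primitive set and every
#' connection gene uniformly over the node indices permitted by the grid
#' layout and `levels_back`. Connection genes exist for all `max_arity` slots
#' of every internal node, including slots unused by the node's current
#' operator; such unused genes can accumulate silent mutations. Uses R's
#' global RNG stream, so results are reproducible under [set.seed()].
#'
#' @param dims a [cgp_dims()] object.
#' @param primitives a [default_primitives()] set.
#' @return an object of class `cgp_genome`.
#' @export
#' @examples
#' set.seed(1)
#' g <- random_genome(cgp_dims(n_inputs = 3), default_primitives())
#' g
random_genome <- function(dims, primitives) {
  stopifnot(inherits(dims, "cgp_dims"), inherits(primitives, "cgp_primitives"))
  n_int <- n_internal(dims)
  max_arity <- attr(primitives, "max_arity")
  ops <- integer(n_int)
  conn <- matrix(0L, nrow = n_int, ncol = max_arity)
  for (k in seq_len(n_int)) {
    ops[k] <- sample.int(length(primitives), 1L)
    src <- allowed_sources(dims, internal_column(dims, k))
    conn[k, ] <- src[sample.int(length(src), max_arity, replace = TRUE)]
  }
  out_src <- allowed_output_sources(dims)
  outputs <- out_src[sample.int(length(out_src), dims$n_outputs, replace = TRUE)]
  new_genome(dims, primitives, ops, conn, outputs)
}

new_genome <- function(dims, primitives, ops, conn, outputs) {
  g <- structure(
    list(
      dims = dims, primitives = primitives,
      ops = as.integer(ops), conn = conn, outputs = as.integer(outputs)
    ),
    class = "cgp_genome"
  )
  validate_genome(g)
  g
}

#' Validate genome invariants
#'
#' Checks that all operator genes index into the primitive set, that all
#' connection genes respect the `levels_back` constraint (no cycles possible)
#' and that output genes reference existing nodes.
#'
#' @param genome a `cgp_genome`.
#' @return the genome, invisibly; signals a genome-integrity error otherwise.
#' @export
validate_genome <- function(genome) {
  dims <- genome$dims
  n_int <- n_internal(dims)
  if (length(genome$ops) != n_int || (nrow(genome$conn) %||% 0L) != n_int) {
    stop("genome integrity: gene count does not match grid", call. = FALSE)
  }
  if (n_int > 0L) {
    if (any(genome$ops < 1L | genome$ops > length(genome$primitives))) {
      stop("genome integrity: operator gene out of range", call. = FALSE)
    }
    for (k in seq_len(n_int)) {
      src <- allowed_sources(dims, internal_column(dims, k))
      if (!all(genome$conn[k, ] %in% src)) {
        stop("genome integrity: dangling or forward connection gene", call. = FALSE)
      }
    }
  }
  if (!all(genome$outputs %in% allowed_output_sources(dims))) {
    stop("genome integrity: output gene references missing node", call. = FALSE)
  }
  invisible(genome)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cgp_genome <- function(x, ...) {
  d <- x$dims
  cat(sprintf(
    "<cgp_genome> %d inputs, %dx%d grid, %d output(s): %s\n",
    d$n_inputs, d$n_rows, d$n_columns, d$n_outputs,
    paste(decode(x)$expressions, collapse = "; ")
  ))
  invisible(x)
}

#' Mutate a genome
#'
#' Each mutable gene (operator genes, connection genes -- including slots the
#' current operator does not read -- and output genes) is independently
#' resampled with probability `p_mutate` to a *different* legal value. Genes
#' with a single legal value cannot change. A mutation is *silent* when the
#' decoded expressions of parent and offspring are identical, i.e. when only
#' inactive parts of the genotype were touched.
#'
#' @param genome a `cgp_genome`.
#' @param p_mutate per-gene mutation probability in `[0, 1]`.
#' @return a list with elements `genome` (the offspring) and `silent`
#'   (`TRUE` iff the phenotype is unchanged).
#' @export
mutate <- function(genome, p_mutate) {
  stopifnot(p_mutate >= 0, p_mutate <= 1)
  dims <- genome$dims
  n_int <- n_internal(dims)
  ops <- genome$ops
  conn <- genome$conn
  outputs <- genome$outputs
  n_prim <- length(genome$primitives)

  for (k in seq_len(n_int)) {
    if (n_prim > 1L && runif(1) < p_mutate) {
      ops[k] <- resample_excluding(seq_len(n_prim), ops[k])
    }
    src <- allowed_sources(dims, internal_column(dims, k))
    for (a in seq_len(ncol(conn))) {
      if (length(src) > 1L && runif(1) < p_mutate) {
        conn[k, a] <- resample_excluding(src, conn[k, a])
      }
    }
  }
  out_src <- allowed_output_sources(dims)
  for (o in seq_along(outputs)) {
    if (length(out_src) > 1L && runif(1) < p_mutate) {
      outputs[o] <- resample_excluding(out_src, outputs[o])
    }
  }
  child <- new_genome(dims, genome$primitives, ops, conn, outputs)
  silent <- identical(expression_key(decode(child)), expression_key(decode(genome)))
  list(genome = child, silent = silent)
}

resample_excluding <- function(values, current) {
  pool <- values[values != current]
  pool[sample.int(length(pool), 1L)]
}

#' Serialize a genome to JSON
#'
#' Gene arrays, grid dimensions and primitive names round-trip losslessly;
#' [genome_from_json()] restores the genome given the same primitive set.
#'
#' @param genome a `cgp_genome`.
#' @return a JSON string.
#' @export
genome_to_json <- function(genome) {
  d <- genome$dims
  jsonlite::toJSON(
    list(
      dims = list(
        n_inputs = d$n_inputs, n_outputs = d$n_outputs, n_rows = d$n_rows,
        n_columns = d$n_columns, levels_back = d$levels_back
      ),
      primitives = names(genome$primitives),
      ops = genome$ops,
      conn = genome$conn,
      outputs = genome$outputs
    ),
    auto_unbox = TRUE
  )
}

#' @rdname genome_to_json
#' @param json a string produced by [genome_to_json()].
#' @param primitives the primitive set the genome was built with; its names
#'   must match the serialized primitive names.
#' @export
genome_from_json <- function(json, primitives) {
  x <- jsonlite::fromJSON(json)
  if (!identical(as.character(x$primitives), names(primitives))) {
    stop("genome_from_json: primitive set does not match serialized genome",
      call. = FALSE
    )
  }
  dims <- cgp_dims(
    n_inputs = x$dims$n_inputs, n_outputs = x$dims$n_outputs,
    n_rows = x$dims$n_rows, n_columns = x$dims$n_columns,
    levels_back = x$dims$levels_back
  )
  conn <- matrix(as.integer(x$conn), nrow = n_internal(dims))
  new_genome(dims, primitives, as.integer(x$ops), conn, as.integer(x$outputs))
}
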