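#' Decode a genotype into its computational graph
#'
#' Computes the set of *active* nodes by backward reachability from the
#' output genes and builds the canonical, fully parenthesized infix
#' expression of each output. Nodes outside the active set never influence
#' evaluation; mutations confined to them are silent. Re-decoding the same
#' genome always yields the identical expression.
#'
#' @param genome a `cgp_genome`.
#' @return an object of class `cgp_graph` with fields `n_inputs`,
#'   `active` (ordered indices of active internal nodes), `node_op`,
#'   `node_in` (per active node), `outputs` (source node per output),
#'   `expressions` (one canonical infix string per output) and `key`.
#' @export
#' @examples
#' set.seed(8)
#' g <- random_genome(cgp_dims(n_inputs = 3, n_columns = 4), default_primitives())
#' decode(g)$expressions
decode <- function(genome) {
  dims <- genome$dims
  prim <- genome$primitives
  n_in <- dims$n_inputs
  n_int <- n_internal(dims)

  needed <- rep(FALSE, n_in + n_int)
  stack <- genome$outputs
  while (length(stack) > 0L) {
    node <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (needed[node]) next
    needed[node] <- TRUE
    if (node > n_in) {
      k <- node - n_in
      arity <- prim[[genome$ops[k]]]$arity
      if (arity > 0L) stack <- c(stack, genome$conn[k, seq_len(arity)])
    }
  }
  active <- which(needed[seq_len(n_int) + n_in])

  # Expression strings, built in topological (index) order.
  expr <- character(n_in + n_int)
  expr[seq_len(n_in)] <- paste0("x", seq_len(n_in) - 1L)
  for (k in active) {
    p <- prim[[genome$ops[k]]]
    expr[n_in + k] <- if (p$arity == 0L) {
      p$name
    } else {
      a <- genome$conn[k, 1L]
      b <- genome$conn[k, 2L]
      paste0("(", expr[a], p$name, expr[b], ")")
    }
  }
  expressions <- expr[genome$outputs]

  structure(
    list(
      n_inputs = n_in,
      primitives = prim,
      active = active,
      node_op = genome$ops[active],
      node_in = genome$conn[active, , drop = FALSE],
      node_index = n_in + active,
      outputs = genome$outputs,
      expressions = expressions,
      key = paste(expressions, collapse = ";")
    ),
    class = "cgp_graph"
  )
}

#' @export
print.cgp_graph <- function(x, ...) {
  cat(
    "<cgp_graph> f(", paste0("x", seq_len(x$n_inputs) - 1L, collapse = ","),
    ") = ", paste(x$expressions, collapse = "; "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Canonical expression key of a phenotype
#'
#' Two genomes with identical phenotypes yield identical keys (the
#' semicolon-joined canonical infix expressions); the key is the unit of
#' fitness caching. No algebraic normalization is applied beyond constant
#' formatting, so `x0*x2` and `x2*x0` are distinct keys -- a cheap,
#' conservative choice that can only cause extra evaluations, never wrong
#' cache hits.
#'
#' @param graph a decoded `cgp_graph`.
#' @return a character scalar.
#' @export
expression_key <- function(graph) {
  stopifnot(inherits(graph, "cgp_graph"))
  graph$key
}

#' Evaluate a decoded graph at an input vector
#'
#' Active nodes are evaluated in topological order; inactive nodes are never
#' touched. Division by zero or overflow is not masked: if any output is
#' non-finite the result carries `valid = FALSE`, which evolution maps to
#' fitness `-Inf`.
#'
#' @param graph a `cgp_graph`.
#' @param inputs numeric vector of length `n_inputs`. Each element may also
#'   be a vector (all of common length) for vectorized evaluation.
#' @return numeric vector (or matrix for vectorized input) of output values
#'   with attribute `valid`.
#' @export
#' @examples
#' set.seed(8)
#' g <- random_genome(cgp_dims(n_inputs = 2, n_columns = 3), default_primitives())
#' cgp_evaluate(decode(g), c(1, 2))
cgp_evaluate <- function(graph, inputs) {
  f <- compile_rule_fun(graph)
  out <- do.call(f, as.list(inputs))
  structure(out, valid = all(is.finite(unlist(out))))
}

# Compile a decoded graph into an R closure f(x0, x1, ...) returning a
# numeric vector (one element per output; vectorized over vector arguments,
# returning a matrix with one column per output).
compile_rule_fun <- function(graph) {
  prim <- graph$primitives
  n_in <- graph$n_inputs
  force(graph)
  function(...) {
    args <- list(...)
    stopifnot(length(args) == n_in)
    n_vec <- max(vapply(args, length, 1L))
    vals <- vector("list", max(c(graph$node_index, n_in)))
    for (i in seq_len(n_in)) vals[[i]] <- rep_len(args[[i]], n_vec)
    for (j in seq_along(graph$active)) {
      p <- prim[[graph$node_op[j]]]
      vals[[graph$node_index[j]]] <- if (p$arity == 0L) {
        rep_len(p$value, n_vec)
      } else {
        p$fun(
          vals[[graph$node_in[j, 1L]]],
          vals[[graph$node_in[j, 2L]]]
        )
      }
    }
    out <- vapply(graph$outputs, function(o) vals[[o]], numeric(n_vec))
    if (length(graph$outputs) == 1L) as.numeric(out) else out
  }
}

#' Compile a plasticity rule from a decoded graph or an infix expression
#'
#' A compiled rule is a pure evaluator mapping named local synaptic
#' quantities to a weight change, plus the canonical expression key used for
#' fitness caching and a bytecode program consumed by the C++ simulators.
#'
#' @param x a `cgp_graph`, or a character infix expression over inputs named
#'   in `input_names` (e.g. `"(x0-x1)*x2"`; input names are substituted
#'   positionally as `x0`, `x1`, ...).
#' @param input_names ordered names of the rule's inputs, e.g.
#'   `c("R", "E", "Rplus", "Rminus")`.
#' @return an object of class `compiled_rule` with fields `input_names`,
#'   `fun` (vectorized evaluator), `expression_key`, `expressions` and
#'   `program` (numeric matrix bytecode; see [graph_program()]).
#' @export
#' @examples
#' r <- compile_rule("(x0-x1)*x2", c("v", "u", "sbar"))
#' r$fun(2, 1, 3)
compile_rule <- function(x, input_names) {
  if (is.character(x)) {
    x <- parse_expression_graph(x, length(input_names))
  }
  stopifnot(inherits(x, "cgp_graph"), x$n_inputs == length(input_names))
  structure(
    list(
      input_names = input_names,
      fun = compile_rule_fun(x),
      expression_key = x$key,
      expressions = x$expressions,
      n_outputs = length(x$outputs),
      program = graph_program(x)
    ),
    class = "compiled_rule"
  )
}

#' @export
print.compiled_rule <- function(x, ...) {
  cat(
    "<compiled_rule> f(", paste(x$input_names, collapse = ","), ") = ",
    paste(x$expressions, collapse = "; "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Bytecode program of a decoded graph
#'
#' Flattens the active subgraph into a register program evaluated by the
#' compiled simulators: registers `0..n_inputs-1` hold the inputs; each row
#' `(opcode, a1, a2, out, const)` writes one register. Opcodes: 0 constant,
#' 1 `+`, 2 `-`, 3 `*`, 4 `/`, 5 `^`. The final `n_outputs` entries of the
#' attribute `out_regs` name the output registers.
#'
#' @param graph a `cgp_graph`.
#' @return numeric matrix with attributes `n_inputs`, `n_regs`, `out_regs`.
#' @export
graph_program <- function(graph) {
  n_in <- graph$n_inputs
  reg_of <- integer(n_in + max(c(graph$node_index, n_in)))
  reg_of[seq_len(n_in)] <- seq_len(n_in) - 1L
  n_regs <- n_in
  rows <- vector("list", length(graph$active))
  for (j in seq_along(graph$active)) {
    p <- graph$primitives[[graph$node_op[j]]]
    out_reg <- n_regs
    n_regs <- n_regs + 1L
    reg_of[graph$node_index[j]] <- out_reg
    rows[[j]] <- if (p$arity == 0L) {
      c(0, 0, 0, out_reg, p$value)
    } else {
      c(
        p$opcode, reg_of[graph$node_in[j, 1L]], reg_of[graph$node_in[j, 2L]],
        out_reg, 0
      )
    }
  }
  prog <- do.call(rbind, c(rows, list(matrix(0, 0, 5))))
  colnames(prog) <- c("opcode", "a1", "a2", "out", "const")
  structure(prog,
    n_inputs = n_in, n_regs = n_regs,
    out_regs = reg_of[graph$outputs]
  )
}

# Parse a plain infix expression (over x0, x1, ... and numeric literals,
# operators + - * / ^ and parentheses) into a cgp_graph-compatible object,
# so that hand-written reference rules flow through the same evaluation and
# caching machinery as evolved genomes.
parse_expression_graph <- function(text, n_inputs) {
  exprs <- strsplit(text, ";", fixed = TRUE)[[1]]
  env_nodes <- new.env(parent = emptyenv())
  env_nodes$ops <- integer(0)
  env_nodes$ins <- matrix(0L, 0, 2)
  env_nodes$consts <- numeric(0)

  opcode_of <- c("+" = 1L, "-" = 2L, "*" = 3L, "/" = 4L, "^" = 5L)
  add_node <- function(op, a, b, const = 0) {
    env_nodes$ops <- c(env_nodes$ops, op)
    env_nodes$ins <- rbind(env_nodes$ins, c(a, b))
    env_nodes$consts <- c(env_nodes$consts, const)
    n_inputs + length(env_nodes$ops)
  }
  walk <- function(e) {
    if (is.numeric(e)) {
      return(add_node(0L, 0L, 0L, const = as.numeric(e)))
    }
    if (is.name(e)) {
      nm <- as.character(e)
      if (!grepl("^x[0-9]+$", nm)) {
        stop("unknown symbol in rule expression: ", nm, call. = FALSE)
      }
      idx <- as.integer(sub("^x", "", nm)) + 1L
      if (idx > n_inputs) {
        stop("expression references input beyond rule arity: ", nm, call. = FALSE)
      }
      return(idx)
    }
    if (is.call(e)) {
      op <- as.character(e[[1]])
      if (op == "(") {
        return(walk(e[[2]]))
      }
      if (op == "-" && length(e) == 2) { # unary minus -> (0 - a)
        zero <- add_node(0L, 0L, 0L, const = 0)
        operand <- walk(e[[2]]) # force before add_node: nodes append in order
        return(add_node(2L, zero, operand))
      }
      if (!op %in% names(opcode_of) || length(e) != 3) {
        stop("unsupported operator in rule expression: ", op, call. = FALSE)
      }
      a <- walk(e[[2]])
      b <- walk(e[[3]])
      return(add_node(opcode_of[[op]], a, b))
    }
    stop("cannot parse rule expression", call. = FALSE)
  }
  out_nodes <- vapply(exprs, function(s) as.integer(walk(str2lang(s))), integer(1))

  # Wrap in a cgp_graph-like structure with a bespoke primitive list: each
  # node becomes its own "active" entry; constants become zero-arity entries.
  ops <- env_nodes$ops
  prim <- vector("list", length(ops))
  node_op <- integer(length(ops))
  op_funs <- list(
    `1` = function(a, b) a + b, `2` = function(a, b) a - b,
    `3` = function(a, b) a * b, `4` = function(a, b) a / b,
    `5` = function(a, b) a^b
  )
  op_names <- c(`1` = "+", `2` = "-", `3` = "*", `4` = "/", `5` = "^")
  for (j in seq_along(ops)) {
    prim[[j]] <- if (ops[j] == 0L) {
      constant_primitive(env_nodes$consts[j])
    } else {
      list(
        name = op_names[[as.character(ops[j])]], arity = 2L,
        opcode = ops[j], fun = op_funs[[as.character(ops[j])]]
      )
    }
    node_op[j] <- j
  }

  expr_str <- character(n_inputs + length(ops))
  expr_str[seq_len(n_inputs)] <- paste0("x", seq_len(n_inputs) - 1L)
  for (j in seq_along(ops)) {
    expr_str[n_inputs + j] <- if (ops[j] == 0L) {
      format_constant(env_nodes$consts[j])
    } else {
      paste0(
        "(", expr_str[env_nodes$ins[j, 1]],
        op_names[[as.character(ops[j])]],
        expr_str[env_nodes$ins[j, 2]], ")"
      )
    }
  }

  structure(
    list(
      n_inputs = n_inputs,
      primitives = prim,
      active = seq_along(ops),
      node_op = node_op,
      node_in = env_nodes$ins,
      node_index = n_inputs + seq_along(ops),
      outputs = out_nodes,
      expressions = expr_str[out_nodes],
      key = paste(expr_str[out_nodes], collapse = ";")
    ),
    class = "cgp_graph"
  )
}
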