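#' Primitive sets for Cartesian genetic programming
#'
#' A primitive set is the ordered collection of mathematical operators and
#' constants available to internal nodes of a Cartesian genotype. Operators
#' are binary arithmetic functions; constants are zero-arity nodes emitting a
#' fixed value. The default set -- addition, subtraction, multiplication,
#' unprotected division, plus the constants 1.0 and 0.5 -- spans every
#' reference plasticity rule shipped with the package. Division is
#' deliberately unprotected: a rule that divides by zero is flagged invalid
#' and receives fitness `-Inf` during evolution rather than a silently
#' substituted value.
#'
#' @param include_pow if `TRUE`, add a binary power operator `a^b` (needed to
#'   express weight-dependent STDP kernels of the form `(w*E)^w`).
#' @param constants numeric vector of constant-node values.
#'
#' @return an object of class `cgp_primitives`: a list of primitive entries,
#'   each with `name`, `arity`, `fun` and an opcode used by the compiled
#'   evaluator, plus attributes `max_arity` and `n_ops`.
#' @export
#' @examples
#' prim <- default_primitives()
#' names(prim)
default_primitives <- function(include_pow = FALSE, constants = c(1.0, 0.5)) {
  ops <- list(
    list(name = "+", arity = 2L, opcode = 1L, fun = function(a, b) a + b),
    list(name = "-", arity = 2L, opcode = 2L, fun = function(a, b) a - b),
    list(name = "*", arity = 2L, opcode = 3L, fun = function(a, b) a * b),
    list(name = "/", arity = 2L, opcode = 4L, fun = function(a, b) a / b)
  )
  if (include_pow) {
    ops <- c(ops, list(
      list(name = "^", arity = 2L, opcode = 5L, fun = function(a, b) a^b)
    ))
  }
  for (v in constants) {
    ops <- c(ops, list(constant_primitive(v)))
  }
  names(ops) <- vapply(ops, `[[`, "", "name")
  structure(ops,
    class = "cgp_primitives",
    max_arity = max(vapply(ops, `[[`, 0L, "arity")),
    n_ops = length(ops)
  )
}

constant_primitive <- function(value) {
  force(value)
  list(
    name = format_constant(value), arity = 0L, opcode = 0L,
    value = value, fun = function() value
  )
}

#' @export
print.cgp_primitives <- function(x, ...) {
  cat("<cgp_primitives> ", length(x), " primitives: ",
    paste(names(x), collapse = " "), "\n",
    sep = ""
  )
  invisible(x)
}

# Canonical constant formatting used in expression keys: always at least one
# decimal digit so that 1 prints as "1.0" and keys are stable across platforms.
format_constant <- function(v) {
  if (v == round(v)) sprintf("%.1f", v) else format(v, digits = 15)
}
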