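# Independent brute-force evaluation of a Cartesian genotype: a plain
# recursive tree walk over the gene arrays, sharing no code with the
# decode/compile path it checks.
oracle_eval_genome <- function(genome, inputs) {
  prim <- genome$primitives
  n_in <- genome$dims$n_inputs
  eval_node <- function(node) {
    if (node <= n_in) {
      return(inputs[node])
    }
    k <- node - n_in
    p <- prim[[genome$ops[k]]]
    if (p$arity == 0L) {
      return(p$value)
    }
    a <- eval_node(genome$conn[k, 1L])
    b <- eval_node(genome$conn[k, 2L])
    switch(p$name,
      "+" = a + b,
      "-" = a - b,
      "*" = a * b,
      "/" = a / b,
      "^" = a^b,
      stop("oracle: unknown operator ", p$name)
    )
  }
  vapply(genome$outputs, eval_node, numeric(1))
}

# The Cartesian genotype depicted in the package's stock example: three
# inputs, one row of four internal nodes where node 4 (index n_in + 1)
# multiplies inputs x0 and x2 and the single output reads it, so
# f = (x0*x2). Remaining nodes are wired but inactive.
fig_genome <- function(primitives = default_primitives()) {
  dims <- cgp_dims(n_inputs = 3, n_outputs = 1, n_rows = 1, n_columns = 4)
  mul <- which(names(primitives) == "*")
  add <- which(names(primitives) == "+")
  ops <- c(mul, add, add, mul)
  conn <- rbind(
    c(1L, 3L), # node 4: x0 * x2   (active)
    c(2L, 3L), # node 5: x1 + x2   (inactive)
    c(4L, 1L), # node 6: node4 + x0 (inactive)
    c(5L, 2L) # node 7: node5 * x1 (inactive)
  )
  evoplast:::new_genome(dims, primitives, ops, conn, outputs = 4L)
}

small_random_genome <- function(n_inputs = 3, n_columns = 5,
                                primitives = default_primitives()) {
  random_genome(cgp_dims(n_inputs = n_inputs, n_columns = n_columns), primitives)
}
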