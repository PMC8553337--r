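test_that("decode recovers the canonical expression of the stock genome", {
  g <- fig_genome()
  gr <- decode(g)
  expect_equal(gr$expressions, "(x0*x2)")
  expect_equal(cgp_evaluate(gr, c(2, 9, 3))[1], 6)
  # output gene pointing directly at an input: identity, no internal nodes
  g2 <- g
  g2$outputs <- 2L # input x1
  gr2 <- decode(evoplast:::new_genome(g$dims, g$primitives, g$ops, g$conn, 2L))
  expect_equal(gr2$expressions, "x1")
  expect_length(gr2$active, 0)
})

test_that("degenerate grids and bad genomes are rejected or forced legal", {
  # 0 internal nodes: outputs can only reference inputs
  dims0 <- cgp_dims(n_inputs = 2, n_outputs = 1, n_rows = 0, n_columns = 0)
  set.seed(1)
  for (i in 1:20) {
    g <- random_genome(dims0, default_primitives())
    expect_true(g$outputs %in% 1:2)
  }
  expect_error(cgp_dims(n_inputs = 0), "input")
  bad <- fig_genome()
  bad$outputs <- 99L
  expect_error(validate_genome(bad), "output gene")
})

test_that("random genomes are reproducible and operator genes uniform", {
  set.seed(7)
  g1 <- small_random_genome()
  set.seed(7)
  g2 <- small_random_genome()
  expect_identical(g1, g2)

  # empirical operator-gene frequencies uniform within 3-sigma binomial
  prim <- default_primitives()
  set.seed(42)
  draws <- 2000L
  ops <- unlist(lapply(seq_len(draws), function(i) small_random_genome()$ops))
  n <- length(ops)
  p <- 1 / length(prim)
  for (k in seq_along(prim)) {
    expect_lt(abs(sum(ops == k) - n * p), 3 * sqrt(n * p * (1 - p)))
  }
})

test_that("decoded evaluation equals brute-force recursive genotype evaluation", {
  set.seed(11)
  for (i in 1:60) {
    g <- small_random_genome()
    f <- evoplast:::compile_rule_fun(decode(g))
    for (j in 1:10) {
      x <- runif(3, -3, 3)
      got <- f(x[1], x[2], x[3])
      want <- oracle_eval_genome(g, x)
      if (is.finite(want) && is.finite(got)) expect_equal(got, want)
    }
  }
})

test_that("evaluation flags non-finite results instead of masking them", {
  div <- compile_rule("x0/x1", c("a", "b"))
  expect_true(is.nan(div$fun(1, 0) * 0) || !is.finite(div$fun(1, 0)))
  gr <- evoplast:::parse_expression_graph("x0/x1", 2)
  expect_false(attr(cgp_evaluate(gr, c(1, 0)), "valid"))
  expect_true(attr(cgp_evaluate(gr, c(1, 2)), "valid"))
})

test_that("mutation respects p_mutate bounds and reports silence", {
  g <- fig_genome()
  set.seed(5)
  m0 <- mutate(g, 0)
  expect_identical(m0$genome, g)
  expect_true(m0$silent)

  # mutating only an inactive node leaves the expression unchanged
  g_inact <- g
  g_inact$ops[2] <- which(names(g$primitives) == "-")
  g_inact <- evoplast:::new_genome(g$dims, g$primitives, g_inact$ops, g$conn, g$outputs)
  expect_identical(decode(g_inact)$key, decode(g)$key)

  # p_mutate = 1: every mutable gene with >1 legal value differs
  set.seed(9)
  m1 <- mutate(g, 1)
  expect_false(any(m1$genome$ops == g$ops))
  expect_false(m1$genome$outputs == g$outputs)
  for (k in seq_along(g$ops)) {
    src <- evoplast:::allowed_sources(g$dims, evoplast:::internal_column(g$dims, k))
    for (a in 1:2) {
      if (length(src) > 1L) expect_false(m1$genome$conn[k, a] == g$conn[k, a])
    }
  }
  # closure: decode of any mutated genome succeeds, genes stay legal
  set.seed(13)
  g2 <- small_random_genome()
  for (i in 1:50) {
    g2 <- mutate(g2, 0.3)$genome
    expect_silent(validate_genome(g2))
    expect_s3_class(decode(g2), "cgp_graph")
  }
})

test_that("expression keys identify phenotypes, not genotypes", {
  g <- fig_genome()
  key <- expression_key(decode(g))
  # variant mutated only in an inactive node shares the key
  v <- g
  v$conn[2, 1] <- 1L
  v <- evoplast:::new_genome(g$dims, g$primitives, v$ops, v$conn, g$outputs)
  expect_identical(expression_key(decode(v)), key)
  # distinct functions get distinct keys
  a <- decode(evoplast:::new_genome(g$dims, g$primitives, g$ops, g$conn, 1L))
  b <- decode(evoplast:::new_genome(g$dims, g$primitives, g$ops, g$conn, 2L))
  expect_false(identical(a$key, b$key))

  # key equality <=> value equality on random probes (no collisions at this scale)
  set.seed(21)
  genomes <- lapply(1:40, function(i) small_random_genome())
  keys <- vapply(genomes, function(g) decode(g)$key, "")
  probes <- matrix(runif(30, -2, 2), ncol = 3)
  vals <- lapply(genomes, function(g) {
    apply(probes, 1, function(x) oracle_eval_genome(g, x))
  })
  for (i in seq_along(genomes)) {
    for (j in seq_len(i - 1L)) {
      same_key <- keys[i] == keys[j]
      same_val <- isTRUE(all.equal(vals[[i]], vals[[j]]))
      if (same_key) expect_true(same_val)
    }
  }
})

test_that("bytecode programs agree with the R evaluator, including powers", {
  prim <- default_primitives(include_pow = TRUE)
  set.seed(31)
  for (i in 1:25) {
    g <- random_genome(cgp_dims(n_inputs = 2, n_columns = 4), prim)
    gr <- decode(g)
    rule <- compile_rule(gr, c("a", "b"))
    x <- abs(runif(2, 0.1, 2)) # positive inputs keep powers real
    got_r <- rule$fun(x[1], x[2])
    want <- oracle_eval_genome(g, x)
    if (is.finite(want)) expect_equal(got_r, want, tolerance = 1e-12)
  }
})

test_that("genomes round-trip through JSON", {
  set.seed(17)
  g <- small_random_genome()
  prim <- g$primitives
  j <- genome_to_json(g)
  g2 <- genome_from_json(j, prim)
  expect_identical(decode(g2)$key, decode(g)$key)
  expect_identical(g2$ops, g$ops)
  expect_identical(g2$conn, g$conn)
  expect_error(
    genome_from_json(j, default_primitives(include_pow = TRUE)),
    "primitive set"
  )
})
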