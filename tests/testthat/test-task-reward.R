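test_that("reward baselines follow the moving-average recursion exactly", {
  # mr = 2, rewards (+1, -1, +1): values from iterating the recursion by hand
  b <- list(rplus = 0, rminus = 0)
  b <- update_baselines(b, +1, 2)
  expect_equal(c(b$rplus, b$rminus), c(0.5, 0))
  b <- update_baselines(b, -1, 2)
  expect_equal(c(b$rplus, b$rminus), c(0.25, -0.5))
  b <- update_baselines(b, +1, 2)
  expect_equal(c(b$rplus, b$rminus), c(0.625, -0.25))
  expect_equal(b$rbar, 0.375)
  expect_equal(b$rabs, 0.875)

  # constant R = +1, mr = 100: geometric closed form
  b <- list(rplus = 0, rminus = 0)
  for (k in 1:40) {
    b <- update_baselines(b, +1, 100)
    expect_equal(b$rplus, 1 - (1 - 1 / 100)^k, tolerance = 1e-12)
  }
  expect_error(update_baselines(b, +1, 0.5), "mr")
})

test_that("baseline invariants hold under arbitrary reward sequences", {
  set.seed(14)
  b <- list(rplus = 0, rminus = 0)
  for (i in 1:500) {
    b <- update_baselines(b, sample(c(-1, 1), 1), 100)
    expect_true(b$rplus >= 0 && b$rplus <= 1)
    expect_true(b$rminus >= -1 && b$rminus <= 0)
    expect_equal(b$rbar, b$rplus + b$rminus)
    expect_true(b$rbar >= -1 && b$rbar <= 1)
    expect_true(b$rabs >= 0 && b$rabs <= 1)
  }
})

test_that("eligibility traces decay, saturate at the drive fixed point, and gate on sbar", {
  p <- neuron_params(delta_u = 2, rho = 20)
  tau_M <- 300
  dt <- 0.1
  n <- 5000L
  # sbar = 0: pure exponential decay from E0
  E <- update_eligibility(2, integer(0), rep(p$u_th, n), rep(0, n), p, tau_M, dt)
  expect_equal(E[n], 2 * exp(-n * dt / tau_M), tolerance = 1e-9)
  # clamped u, no post spikes, constant sbar: fixed point -phi_eff*sbar/delta_u
  u0 <- p$u_th - 1
  sbar0 <- 0.5
  E2 <- update_eligibility(0, integer(0), rep(u0, 40000L), rep(sbar0, 40000L), p, tau_M, dt)
  phi <- escape_rate(u0, p)
  phi_eff <- 1000 * (1 - exp(-phi * dt / 1000)) / dt
  expect_equal(E2[40000L], -phi_eff * sbar0 / p$delta_u, tolerance = 1e-3)
  # post spike coinciding with sbar = 0 leaves E unchanged (multiplicative gating)
  E3 <- update_eligibility(0, c(10L), rep(-100, 20L), rep(0, 20L), p, tau_M, dt)
  expect_true(all(E3 == 0))
})

test_that("compiled trial simulator reproduces the reference eligibility integrator", {
  cfg <- reward_task_config(N = 3L, T_trial = 200)
  sc <- sim_config(dt = cfg$dt, T_total = cfg$T_trial)
  set.seed(8)
  spikes <- lapply(1:3, function(i) poisson_train(30, cfg$T_trial))
  ev <- evoplast:::pattern_events(spikes, sc)
  u_clamp <- cfg$neuron$u_th - 2
  set.seed(77)
  res <- evoplast:::reward_trial_cpp(
    ev$step, ev$syn, sc$n_steps, 3L, rep(0.5, 3),
    dt = cfg$dt, tau_m = cfg$neuron$tau_m, tau_syn = cfg$neuron$tau_syn,
    tau_M = cfg$tau_M, u_rest = cfg$neuron$u_rest, u_th = cfg$neuron$u_th,
    delta_u = cfg$neuron$delta_u, rho_hz = cfg$neuron$rho, clamp_u = u_clamp,
    record_u = TRUE
  )
  # rebuild E for every synapse in R from the same spike assignment; the
  # one-step synaptic delay shifts sbar by one step relative to the event
  # grid, and the simulator's post spikes are replayed as jump times
  for (j in 1:3) {
    sbar <- filter_spikes(spikes[[j]], cfg$neuron$tau_syn, sc)
    sbar_delayed <- c(0, sbar[-sc$n_steps])
    E_ref <- update_eligibility(
      0, res$post_steps + 1L, rep(u_clamp, sc$n_steps), sbar_delayed,
      cfg$neuron, cfg$tau_M, cfg$dt
    )
    expect_equal(res$E[j], E_ref[sc$n_steps], tolerance = 1e-9)
  }
})

test_that("trials classify by the spike/no-spike code deterministically under a seed", {
  cfg <- reward_task_config(N = 10L, T_trial = 200)
  set.seed(3)
  ex <- make_reward_experiment(cfg)
  set.seed(5)
  t1 <- run_trial(ex$w0, ex$patterns[[1]], TRUE, cfg)
  set.seed(5)
  t2 <- run_trial(ex$w0, ex$patterns[[1]], TRUE, cfg)
  expect_identical(t1, t2)
  expect_true(t1$reward %in% c(-1, 1))
  expect_equal(t1$reward == 1, t1$spiked) # active pattern: correct iff spiked

  # zero weights and vanishing escape rate: no spikes possible, so an
  # inactive pattern is always classified correctly
  cfg0 <- reward_task_config(
    N = 10L, T_trial = 200,
    neuron = neuron_params(delta_u = 2, rho = 0)
  )
  set.seed(3)
  ex0 <- make_reward_experiment(cfg0)
  t0 <- run_trial(rep(0, 10), ex0$patterns[[1]], FALSE, cfg0)
  expect_equal(t0$reward, 1)
  expect_equal(t0$n_spikes, 0L)
})

test_that("reference rules match their closed forms at landmark inputs", {
  r <- reward_reference_rules()
  E <- c(-0.4, 0.2, 1.3)
  # LR0 at R = +1: factor (R-1) kills the update
  expect_equal(r$LR0$fun(1, E, 0.3, -0.2), rep(0, 3))
  # LR1 at Rbar = 0 equals LR0
  expect_equal(r$LR1$fun(-1, E, 0.3, -0.3), r$LR0$fun(-1, E, 0.3, -0.3))
  # LR2 at Rbar_abs = 0 is R*E; at Rbar_abs = 1 it is (R-1)*E
  expect_equal(r$LR2$fun(1, E, 0, 0), E)
  expect_equal(r$LR2$fun(1, E, 1, 0), rep(0, 3))
  expect_equal(r$LR2$fun(-1, E, 0.5, -0.5), -2 * E)
  # LR3 = LR2 / (1 + Rbar+)
  expect_equal(r$LR3$fun(-1, E, 0.5, -0.25), r$LR2$fun(-1, E, 0.5, -0.25) / 1.5)
  # LR4 at R = +1: both terms carry (R-1)
  expect_equal(r$LR4$fun(1, E, 0.7, -0.1), rep(0, 3))
  # LR5 at R = +1: causal term proportional to (1 - Rbar_abs)*E as in LR2
  rp <- 0.6
  rm <- -0.3
  expect_equal(
    r$LR5$fun(1, E, rp, rm),
    2 * (1 - (rp - rm)) * E - (1 - (rp - rm)) * rm
  )
})

test_that("LR2 is expressible as a genome in the default primitive set", {
  prim <- default_primitives()
  dims <- cgp_dims(n_inputs = 4, n_outputs = 1, n_rows = 1, n_columns = 3)
  sub <- which(names(prim) == "-")
  mul <- which(names(prim) == "*")
  ops <- c(sub, sub, mul)
  conn <- rbind(
    c(3L, 4L), # node 5: Rplus - Rminus
    c(1L, 5L), # node 6: R - node5
    c(6L, 2L) # node 7: node6 * E
  )
  g <- evoplast:::new_genome(dims, prim, ops, conn, outputs = 7L)
  rule_g <- compile_rule(decode(g), c("R", "E", "Rplus", "Rminus"))
  lr2 <- reward_reference_rules()$LR2
  set.seed(30)
  for (i in 1:100) {
    x <- c(sample(c(-1, 1), 1), runif(1, -2, 2), runif(1, 0, 1), runif(1, -1, 0))
    expect_equal(rule_g$fun(x[1], x[2], x[3], x[4]), lr2$fun(x[1], x[2], x[3], x[4]))
  }
})

test_that("apply_rule scales by eta, checks arity and flags non-finite updates", {
  lr0 <- reward_reference_rules()$LR0
  b <- list(rplus = 0.2, rminus = -0.1)
  expect_equal(
    apply_rule(lr0, -1, c(1, 2), b, eta = 0.5),
    0.5 * (-2) * c(1, 2)
  )
  div <- compile_rule("x0/x2", c("R", "E", "Rplus", "Rminus"))
  expect_error(
    apply_rule(div, 1, c(1, 2), list(rplus = 0, rminus = 0), 0.1),
    class = "evoplast_invalid_evaluation"
  )
  two_in <- compile_rule("x0*x1", c("R", "E"))
  expect_error(apply_rule(two_in, 1, 1, b, 0.1), "arity")
})

test_that("an invalid rule yields fitness -Inf, the zero rule sits at chance", {
  cfg <- reward_task_config(N = 10L, M = 2L, T_trial = 200, n_trials = 40L, n_exp = 2L)
  div <- compile_rule("x1/(x2-x2)", c("R", "E", "Rplus", "Rminus"))
  expect_equal(as.numeric(fitness_reward(div, cfg, seed = 1)), -Inf)
  zero <- compile_rule("0.0", c("R", "E", "Rplus", "Rminus"))
  f <- fitness_reward(zero, cfg, seed = 2)
  # chance-level classification: |mean reward| within binomial noise
  expect_lt(abs(as.numeric(f)), 3 / sqrt(cfg$n_trials * cfg$n_exp) + 0.2)
  # paper scale is n_trials * mean scale
  fp <- fitness_reward(zero, cfg, seed = 2, scale = "paper")
  expect_equal(as.numeric(fp), cfg$n_trials * as.numeric(f))
})

test_that("learning occurs: LR0 beats the zero rule and improves within experiments", {
  cfg <- reward_task_config()
  cfg$n_trials <- 300L
  lr0 <- reward_reference_rules()$LR0
  wins <- 0L
  improved <- 0L
  n_seeds <- 6L
  for (s in seq_len(n_seeds)) {
    set.seed(400 + s)
    res <- run_reward_experiment(lr0, cfg)
    first <- mean(res$rewards[1:50])
    last <- mean(res$rewards[251:300])
    if (last > first) improved <- improved + 1L
    if (mean(res$rewards) > 0.1) wins <- wins + 1L
  }
  expect_gte(improved, n_seeds - 1L)
  expect_gte(wins, n_seeds - 2L)
})
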