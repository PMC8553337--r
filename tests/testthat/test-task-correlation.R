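test_that("pairing eligibility is symmetric in dt; branch choice breaks symmetry", {
  lr1 <- corr_reference_rules()$LR1
  tau <- 20
  for (d in c(5, 12.5, 40)) {
    Ep <- exp(-abs(d) / tau)
    Em <- exp(-abs(-d) / tau)
    expect_equal(Ep, Em)
  }
  k <- stdp_kernel(lr1, w = 0.5, dt_range = c(-10, 10), tau = tau, eta = 1)
  # LR1: anticausal -(w-1)E = +0.5E, causal E; same |dt| different values
  expect_equal(k$dw[1], 0.5 * exp(-0.5))
  expect_equal(k$dw[2], exp(-0.5))
})

test_that("stdp updates match hand-computed values for the printed rules", {
  rules <- corr_reference_rules(w_hom = -0.2)
  eta <- 0.01
  # baseline: no anticausal term; causal E; post-homeostasis w_hom
  up <- stdp_update(rules$baseline, 0.5, -10, 20, eta, trigger = "pre")
  expect_equal(up$dw, 0)
  up <- stdp_update(rules$baseline, 0.5, 10, 20, eta, trigger = "post")
  expect_equal(up$dw, eta * (exp(-0.5) - 0.2))
  # LR1 anticausal at w = 1 vanishes; at w = 0 it potentiates (+E)
  e <- exp(-10 / 20)
  up <- stdp_update(rules$LR1, 1, -10, 20, eta, trigger = "pre")
  expect_equal(up$dw, eta * (0 + 1)) # pairing 0 + pre-hom w = 1
  expect_equal(
    stdp_update(rules$LR1, 0, -10, 20, eta, trigger = "pre")$dw,
    eta * e
  )
  # LR2 causal at w = 0.5, dt = +10, tau = 20: (w*E)^w
  up <- stdp_update(rules$LR2, 0.5, 10, 20, eta, trigger = "post")
  expect_equal(up$dw, eta * ((0.5 * e)^0.5 - 1), tolerance = 1e-12)
  expect_equal((0.5 * e)^0.5, 0.5507, tolerance = 1e-3)
  # LR2 anticausal at dt = -10: -E/w
  up <- stdp_update(rules$LR2, 0.5, -10, 20, eta, trigger = "pre")
  expect_equal(up$dw, eta * (-e / 0.5 + 0.5), tolerance = 1e-12)
  expect_equal(e / 0.5, 1.213, tolerance = 1e-3)
  # LR2 causal at w = 1, dt = 0: (1*1)^1 = 1
  expect_equal(
    stdp_update(rules$LR2, 1, 0, 20, eta, trigger = "post")$dw,
    eta * (1 - 1)
  ) # pairing 1 + post-hom -1
  # LR2 anticausal at w = 0 divides by zero: flagged, not propagated
  expect_error(
    stdp_update(rules$LR2, 0, -5, 20, eta, trigger = "pre"),
    class = "evoplast_invalid_evaluation"
  )
})

test_that("kernel branch signs match the published shapes", {
  rules <- corr_reference_rules()
  dts <- seq(-50, 50, by = 2.5)
  for (w in c(0.25, 0.5, 1.0)) {
    for (nm in names(rules)) {
      k <- stdp_kernel(rules[[nm]], w, dts, tau = 20, eta = 0.01)
      causal <- k$dw[k$dt >= 0]
      anticausal <- k$dw[k$dt < 0]
      expect_true(all(causal >= 0)) # all three rules potentiate causally
      if (nm == "LR2") expect_true(all(anticausal <= 0))
      if (nm == "baseline") expect_true(all(anticausal == 0))
      if (nm == "LR1") expect_true(all(anticausal >= 0))
    }
  }
})

test_that("weights stay within bounds under arbitrary update sequences", {
  rules <- corr_reference_rules()
  set.seed(40)
  for (nm in c("baseline", "LR1")) {
    w <- runif(1, 0.3, 0.7)
    for (i in 1:500) {
      up <- stdp_update(rules[[nm]], w, runif(1, -60, 60), 20, 0.05,
        trigger = sample(c("pre", "post"), 1)
      )
      w <- up$w_new
      expect_true(w >= 0 && w <= 1)
    }
  }
})

test_that("snr follows its definition and is affine invariant", {
  dt <- 1
  trace <- rep(-60, 100)
  windows <- rbind(c(10, 20), c(50, 60))
  trace[11:20] <- -52 # peak -52 in window 1
  trace[51:60] <- -52
  inter <- setdiff(seq_len(100), c(11:20, 51:60))
  trace[inter] <- rnorm(length(inter), -60, 2)
  s <- snr(trace, windows, dt)
  expect_equal(
    s,
    (-52 - mean(trace[inter])) / sd(trace[inter])
  )
  expect_equal(snr(trace + 7.3, windows, dt), s, tolerance = 1e-12)
  # zero inter-pattern variance: warned Inf
  flat <- rep(-60, 100)
  flat[11:20] <- -50
  flat[51:60] <- -50
  expect_warning(s_inf <- snr(flat, windows, dt), "variance")
  expect_equal(s_inf, Inf)
})

test_that("the free membrane trace is linear in the weights and spiking only lowers it", {
  cfg <- corr_task_config(N = 50L, n_train_cycles = 2L)
  set.seed(50)
  pattern <- frozen_pattern(cfg$N, cfg$T_pattern, cfg$nu)
  input <- evoplast:::build_corr_input(cfg, pattern, 3L)
  w <- runif(cfg$N, 0.3, 0.7)
  tr0 <- free_membrane_trace(rep(0, cfg$N), input, cfg)
  expect_equal(tr0, rep(cfg$neuron$u_rest, length(tr0)))
  tr1 <- free_membrane_trace(w, input, cfg)
  tr2 <- free_membrane_trace(2 * w, input, cfg)
  expect_equal(tr2 - cfg$neuron$u_rest, 2 * (tr1 - cfg$neuron$u_rest),
    tolerance = 1e-9
  )
  # pathwise: disabling spiking can only raise the trace (resets lower u)
  spk <- evoplast:::corr_sim(input, w, cfg, corr_reference_rules()$baseline,
    spiking = TRUE, plastic = FALSE, record_u = TRUE
  )
  expect_true(all(tr1 - spk$u >= -1e-9))
})

test_that("the baseline homeostatic STDP rule trains a reliable pattern detector", {
  cfg <- corr_task_config()
  rule <- corr_reference_rules(w_hom = cfg$w_hom)$baseline
  set.seed(61)
  res <- run_corr_experiment(rule, cfg)
  expect_true(res$valid)
  expect_gte(res$snr / res$snr_untrained, 5)
  expect_gte(res$hit_rate, 0.8)
  expect_lte(res$false_rate, 0.2)
})

test_that("min aggregation over experiments and the zero rule's null effect", {
  expect_equal(aggregate_fitness(c(6.1, 3.2, 8.0), "min"), 3.2)
  cfg <- corr_task_config(n_train_cycles = 60L, n_eval_cycles = 5L, n_exp = 2L)
  null_rule <- stdp_rule("0.0", "0.0", "0.0", "0.0", name = "null")
  f0 <- fitness_corr(null_rule, cfg, seed = 3)
  base <- fitness_corr(corr_reference_rules(cfg$w_hom)$baseline, cfg, seed = 3)
  expect_gt(as.numeric(base), as.numeric(f0))
  # with no learning the trained SNR equals the untrained level
  set.seed(9)
  res <- run_corr_experiment(null_rule, cfg)
  expect_equal(res$snr, res$snr_untrained)
})
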