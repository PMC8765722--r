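test_that("a single uncoupled agent advances exactly linearly", {
  for (id in c("standard", "adaptive", "weighted", "delayed")) {
    spec <- switch(id,
      standard = model_spec("standard", coupling_c = 1),
      adaptive = model_spec("adaptive", coupling_c = 1, r_threshold = 0.5),
      weighted = model_spec("weighted", coupling_c = 1,
                            weights = matrix(1, 1, 1)),
      # a lone delayed agent only decouples from its own past under the
      # partners-only convention
      delayed = model_spec("delayed", coupling_c = 1, delay_tau = 0.1,
                           include_delayed_self_coupling = FALSE))
    traj <- simulate_model(spec, agent_ensemble(4),
                           sim_config(duration = 5, seed = 1,
                                      initial_phases = 0.3,
                                      frequency_draw = "fixed-means"))
    expect_equal(traj$phases[, 1], 0.3 + 4 * traj$times, tolerance = 1e-12,
                 info = id)
  }
})

test_that("two standard oscillators lock at the mean frequency with sin(gap) = dw/(2c)", {
  traj <- simulate_model(model_spec("standard", coupling_c = 2),
                         agent_ensemble(c(3, 5)),
                         sim_config(duration = 12, seed = 1,
                                    initial_phases = c(0, 0),
                                    frequency_draw = "fixed-means"))
  tail_idx <- which(traj$times >= 10)
  gap <- traj$phases[tail_idx, 2] - traj$phases[tail_idx, 1]
  expect_equal(sin(mean(gap)), 0.5, tolerance = 1e-6)   # gap = pi/6
  expect_equal(group_frequency(traj, discard_transient = 10), 4,
               tolerance = 1e-6)
})

test_that("reduction identities reproduce the standard trajectory bitwise", {
  ens <- table1_ensemble()
  cfg <- sim_config(duration = 5, seed = 42)
  std <- simulate_model(model_spec("standard", coupling_c = 1.2), ens, cfg)

  delayed0 <- simulate_model(model_spec("delayed", coupling_c = 1.2,
                                        delay_tau = 0), ens, cfg)
  expect_identical(delayed0$phases, std$phases)

  eq_sigma <- agent_ensemble(ens$omega_mean, rep(0.3, 5))
  std_eq <- simulate_model(model_spec("standard", coupling_c = 1.2), eq_sigma, cfg)
  wgt_eq <- simulate_model(model_spec("weighted", coupling_c = 1.2), eq_sigma, cfg)
  expect_identical(wgt_eq$phases, std_eq$phases)

  adapt_lo <- simulate_model(model_spec("adaptive", coupling_c = 1.2,
                                        r_threshold = 1e-9), ens, cfg)
  expect_identical(adapt_lo$phases, std$phases)
})

test_that("standard coupling conserves the mean frequency at every discrete step", {
  ens <- table1_ensemble()
  traj <- simulate_model(model_spec("standard", coupling_c = 1.7), ens,
                         sim_config(duration = 5, seed = 9,
                                    frequency_draw = "fixed-means"))
  inst <- rowMeans(apply(traj$phases, 2, diff)) / traj$dt
  expect_equal(inst, rep(mean(ens$omega_mean), length(inst)),
               tolerance = 1e-10)
})

test_that("variability-weighted coupling conserves the 1/sigma^2-weighted frequency sum", {
  ens <- table1_ensemble()
  w2 <- 1 / ens$omega_std^2
  traj <- simulate_model(model_spec("weighted", coupling_c = 1.1), ens,
                         sim_config(duration = 10, seed = 3,
                                    frequency_draw = "fixed-means"))
  inst <- apply(traj$phases, 2, diff) / traj$dt
  lhs <- as.numeric(inst %*% w2)
  expect_equal(lhs, rep(sum(ens$omega_mean * w2), length(lhs)),
               tolerance = 1e-8)
  # consequently a tightly locked ensemble oscillates at the weighted mean
  tight <- simulate_model(model_spec("weighted", coupling_c = 5), ens,
                          sim_config(duration = 20, seed = 4,
                                     frequency_draw = "fixed-means"))
  expect_equal(group_frequency(tight, discard_transient = 10),
               sum(ens$omega_mean * w2) / sum(w2), tolerance = 0.01)
})

test_that("adaptive frequency update matches a hand Euler step and stays non-negative", {
  # two phases at 0 and 2pi/3 give r = 0.5 exactly
  traj <- simulate_model(model_spec("adaptive", coupling_c = 0,
                                    r_threshold = 0.9),
                         agent_ensemble(c(4, 4)),
                         sim_config(duration = 0.02, seed = 1,
                                    initial_phases = c(0, 2 * pi / 3),
                                    frequency_draw = "fixed-means"))
  expect_equal(traj$omega[2, 1], 4 - 0.01 * (1 / 0.25) * 4)  # 3.84

  long <- simulate_model(model_spec("adaptive", coupling_c = 1.3,
                                    r_threshold = 0.55),
                         table1_ensemble(),
                         sim_config(duration = 10, seed = 17))
  expect_true(all(long$omega >= 0))
  expect_true(all(apply(long$omega, 2, diff) <= 1e-12))
  # frequencies freeze once the threshold is reached
  ss <- sync_series(long, 100)
  frozen <- which(ss$r >= 0.55)
  frozen <- frozen[frozen < nrow(long$omega)]
  expect_equal(long$omega[frozen + 1, ], long$omega[frozen, ],
               tolerance = 1e-12)
})

test_that("delayed locking frequency matches the transcendental root within 1%", {
  omega <- 5.21; c_gain <- 1.9; tau <- 0.17; n <- 5
  ens <- agent_ensemble(rep(omega, n))
  traj <- simulate_model(model_spec("delayed", coupling_c = c_gain,
                                    delay_tau = tau,
                                    include_delayed_self_coupling = FALSE),
                         ens, sim_config(duration = 30, seed = 2,
                                         frequency_draw = "fixed-means"))
  omega_sim <- group_frequency(traj, discard_transient = 20)
  root <- uniroot(function(x) x - omega + c_gain * (n - 1) * sin(x * tau),
                  c(0.1, omega))$root
  expect_lt(abs(omega_sim - root) / root, 0.01)

  # literal convention: the delayed self term adds one more sin(Omega*tau)
  traj_s <- simulate_model(model_spec("delayed", coupling_c = c_gain,
                                      delay_tau = tau), ens,
                           sim_config(duration = 30, seed = 2,
                                      frequency_draw = "fixed-means"))
  root_s <- uniroot(function(x) x - omega + c_gain * n * sin(x * tau),
                    c(0.1, omega))$root
  expect_lt(abs(group_frequency(traj_s, discard_transient = 20) - root_s) /
              root_s, 0.01)
})

test_that("attention weights follow the solo variability ratios", {
  ens <- table1_ensemble()
  W <- build_attention_weights(ens)
  expect_equal(W[1, 2], 1.55 / 0.11, tolerance = 1e-12)  # ~14.09
  expect_equal(W[2, 1], 0.11 / 1.55, tolerance = 1e-12)  # ~0.0710
  expect_equal(diag(W), rep(1, 5))
  for (s in 1:5) {
    set.seed(s)
    We <- build_attention_weights(agent_ensemble(rep(3, 4), runif(4, .1, 2)))
    expect_equal(We * t(We), matrix(1, 4, 4), tolerance = 1e-12)
  }
  expect_equal(build_attention_weights(agent_ensemble(rep(3, 4), rep(0.2, 4))),
               matrix(1, 4, 4))
  expect_error(build_attention_weights(agent_ensemble(rep(3, 2), c(0.1, 0))),
               "positive")
})

test_that("phase and frequency draws are reproducible and correctly distributed", {
  expect_identical(draw_initial_phases(5, 99), draw_initial_phases(5, 99))
  ph <- draw_initial_phases(1000, 1)
  expect_true(all(ph >= 0 & ph < 2 * pi))

  ens <- table1_ensemble()
  expect_identical(draw_natural_frequencies(ens, "fixed-means"),
                   c(3.40, 3.04, 6.36, 3.34, 9.91))
  zero_sd <- agent_ensemble(ens$omega_mean, 0)
  expect_equal(as.numeric(draw_natural_frequencies(zero_sd,
                                                   "gaussian-per-agent", 1)),
               ens$omega_mean)
  draws <- vapply(seq_len(5000), function(k)
    draw_natural_frequencies(ens, "gaussian-per-agent", k)[2], numeric(1))
  se_mean <- 0.11 / sqrt(5000)
  expect_lt(abs(mean(draws) - 3.04), 3 * se_mean)
  expect_lt(abs(sd(draws) - 0.11), 3 * 0.11 / sqrt(2 * 4999))
  expect_true(all(draws > 0))
})

test_that("halving dt changes trial summaries by less than 1e-3", {
  ens <- table1_ensemble()
  ph0 <- draw_initial_phases(5, 8)
  s1 <- summarize_trial(simulate_model(
    model_spec("standard", coupling_c = 1.6), ens,
    sim_config(dt = 0.01, duration = 20, initial_phases = ph0,
               frequency_draw = "fixed-means")), 100)
  s2 <- summarize_trial(simulate_model(
    model_spec("standard", coupling_c = 1.6), ens,
    sim_config(dt = 0.005, duration = 20, initial_phases = ph0,
               frequency_draw = "fixed-means")), 200)
  expect_lt(abs(s1$r_bar - s2$r_bar), 1e-3)
  expect_lt(abs(s1$rho_bar - s2$rho_bar), 1e-3)
  expect_lt(abs(s1$omega_g - s2$omega_g), 1e-3)
  # Euler agrees with RK4 at the analysis step
  s3 <- summarize_trial(simulate_model(
    model_spec("standard", coupling_c = 1.6), ens,
    sim_config(dt = 0.01, duration = 20, initial_phases = ph0,
               frequency_draw = "fixed-means", integrator = "rk4")), 100)
  expect_lt(abs(s1$r_bar - s3$r_bar), 1e-3)
})

test_that("model specs validate their required parameters", {
  expect_error(model_spec("adaptive", coupling_c = 1), "r_threshold")
  expect_error(model_spec("delayed", coupling_c = 1), "delay_tau")
  expect_error(model_spec("standard", coupling_c = -1), "non-negative")
  expect_error(model_spec("adaptive", coupling_c = 1, r_threshold = 1.2),
               "r_threshold")
  expect_error(simulate_model(model_spec("delayed", coupling_c = 1,
                                         delay_tau = 0.1),
                              table1_ensemble(),
                              sim_config(integrator = "rk4")),
               "RK4")
})
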