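make_tone_trial <- function(freq_hz, duration = 30, rate = 10, amp = 1,
                            phase0 = 0, n_players = 1) {
  times <- seq(0, duration, by = 1 / rate)
  pos <- vapply(seq_len(n_players), function(j)
    amp * sin(2 * pi * freq_hz * times + phase0), numeric(length(times)))
  position_trial(times, pos, "solo")
}

test_that("spline resampling is exact on constants and accurate on slow tones", {
  const <- position_trial(seq(0, 5, by = 0.1), matrix(2.5, 51, 1), "solo")
  out <- resample_positions(const, 100)
  expect_equal(out$positions[, 1], rep(2.5, nrow(out$positions)),
               tolerance = 1e-12)
  expect_equal(diff(out$times), rep(0.01, length(out$times) - 1),
               tolerance = 1e-12)

  tone <- make_tone_trial(0.8, duration = 10, rate = 10)
  res <- resample_positions(tone, 100)
  truth <- sin(2 * pi * 0.8 * res$times)
  interior <- res$times > 0.5 & res$times < 9.5
  expect_lt(max(abs(res$positions[interior, 1] - truth[interior])), 1e-3)
  expect_error(resample_positions(position_trial(c(0, .1, .2),
                                                 matrix(1:3, 3, 1), "solo")),
               "at least 4")
})

test_that("zero-phase Butterworth low-pass passes DC and attenuates out-of-band tones", {
  times <- seq(0, 10, by = 0.01)
  dc <- position_trial(times, matrix(3, length(times), 1), "group")
  expect_equal(lowpass_positions(dc, 6, 2)$positions[, 1],
               rep(3, length(times)), tolerance = 1e-9)

  x <- sin(2 * pi * 0.8 * times) + sin(2 * pi * 30 * times)
  filt <- lowpass_positions(position_trial(times, cbind(x), "group"), 6, 2)
  resid <- filt$positions[, 1] - sin(2 * pi * 0.8 * times)
  interior <- times > 1 & times < 9
  # two-pass attenuation at 30 Hz of an order-2 filter with 6 Hz cutoff
  gain2 <- (1 / sqrt(1 + (30 / 6)^(2 * 2)))^2
  expect_lt(max(abs(resid[interior])), gain2 * 1.5 + 2e-3)
  expect_error(lowpass_positions(dc, 50, 2), "Nyquist")

  # re-filtering well inside the passband is near-idempotent
  once <- lowpass_positions(position_trial(times,
                                           cbind(sin(2 * pi * 0.5 * times)),
                                           "group"), 6, 2)
  twice <- lowpass_positions(once, 6, 2)
  expect_lt(max(abs(twice$positions - once$positions)[interior]), 1e-4)
})

test_that("analytic-signal phase extraction recovers tone frequency, quadrature and scale invariance", {
  tone <- make_tone_trial(0.8, duration = 30, rate = 100)
  traj <- extract_phase(tone)
  interior <- traj$times > 1 & traj$times < 29
  slope <- mean(diff(traj$phases[interior, 1])) / traj$dt
  expect_lt(abs(slope - 2 * pi * 0.8) / (2 * pi * 0.8), 0.01)

  times <- seq(0, 30, by = 0.01)
  w <- 2 * pi * 0.8
  tr_cs <- position_trial(times, cbind(cos(w * times), sin(w * times)), "solo")
  ph <- extract_phase(tr_cs)
  gap <- ph$phases[interior, 1] - ph$phases[interior, 2]
  expect_equal(mean(gap), pi / 2, tolerance = 1e-3)

  scaled <- position_trial(tone$times, 3 * tone$positions, "solo")
  expect_equal(extract_phase(scaled)$phases, traj$phases, tolerance = 1e-9)
  expect_error(extract_phase(position_trial(times, cbind(0 * times), "solo")),
               "constant")
})

test_that("tone frequency error stays below 1% across the solo frequency range", {
  for (f in c(0.3, 0.55, 1.0, 1.4, 1.7)) {
    tone <- make_tone_trial(f, duration = 30, rate = 10)
    traj <- preprocess_trial(tone)
    keep <- traj$times > 0.5 & traj$times < 29.5
    slope <- mean(diff(traj$phases[keep, 1])) / traj$dt
    expect_lt(abs(slope - 2 * pi * f) / (2 * pi * f), 0.01)
  }
})

test_that("solo frequency statistics recover generator values", {
  # noiseless, zero spread: exact recovery up to phase-extraction tolerance
  cfg <- synth_config(noise_std = 0, solo_freq_std = 0, n_trials = 3, seed = 5)
  ens <- solo_frequency_stats(generate_solo_trials(cfg))
  expect_equal(ens$omega_mean, cfg$solo_freq_mean, tolerance = 0.01)
  expect_equal(ens$omega_std, rep(0, 5), tolerance = 0.02)

  # ordering invariance
  trials <- generate_solo_trials(synth_config(n_trials = 4, seed = 6))
  e1 <- solo_frequency_stats(trials)
  e2 <- solo_frequency_stats(rev(trials))
  expect_equal(e1$omega_mean, e2$omega_mean, tolerance = 1e-12)
  expect_equal(e1$omega_std, e2$omega_std, tolerance = 1e-12)
})

test_that("Monte-Carlo solo recovery: player-3-like trials return (6.36, 0.58) within 3 SE", {
  n_rep <- 12  # trials pooled across replicates of the 7-trial protocol
  cfg <- synth_config(n_players = 1, solo_freq_mean = 6.36,
                      solo_freq_std = 0.58, n_trials = n_rep, seed = 77)
  ens <- solo_frequency_stats(generate_solo_trials(cfg))
  expect_lt(abs(ens$omega_mean - 6.36), 3 * 0.58 / sqrt(n_rep) + 0.02)
  expect_lt(abs(ens$omega_std - 0.58), 3 * 0.58 / sqrt(2 * (n_rep - 1)) + 0.02)
})

test_that("simulated trials round-trip through the preprocessing chain", {
  specs <- list(model_spec("weighted", coupling_c = 1.1),
                model_spec("standard", coupling_c = 1.6))
  for (i in seq_along(specs)) {
    cfg <- synth_config(group_model = specs[[i]], noise_std = 0.02,
                        n_trials = 1, seed = 40 + i)
    trial <- generate_group_trials(cfg)[[1]]
    # compare on a common span: trim the same edges from truth and estimate
    truth <- summarize_trial(trim_trajectory(attr(trial, "true_trajectory"),
                                             0.5, 0.5))
    rec <- summarize_trial(trim_trajectory(preprocess_trial(trial), 0.5, 0.5))
    expect_lt(abs(rec$r_bar - truth$r_bar), 0.02)
    expect_lt(abs(rec$omega_g - truth$omega_g), 0.05)
  }
})

test_that("position trials reject gaps and round-trip through text files", {
  times <- seq(0, 1, by = 0.1)
  expect_error(position_trial(times, cbind(c(1:10, NA))), "NA")
  trial <- generate_solo_trials(synth_config(n_trials = 1, seed = 3))[[1]]
  path <- tempfile(fileext = ".csv")
  write_position_trial(trial, path)
  back <- read_position_trial(path, "solo")
  expect_identical(back$positions, trial$positions)
  expect_identical(back$times, trial$times)
})
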