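#' Configuration for synthetic Chronos-like trials
#'
#' Describes a synthetic study emulating the acquisition platform's output:
#' per-player sinusoidal finger-position traces sampled at `sample_rate` Hz
#' with additive Gaussian noise. Defaults follow the published study
#' conditions: 5 players with the packaged solo frequency statistics, 30 s
#' trials at 10 Hz, 7 solo / 6 group trials, unit amplitude with noise sd
#' 5% of amplitude.
#'
#' @param n_players number of players.
#' @param solo_freq_mean,solo_freq_std per-player solo frequency mean/sd in
#'   rad/s (defaults: the packaged five-player values).
#' @param group_model a [model_spec()] driving group trials (ignored for solo
#'   trials).
#' @param amplitude oscillation amplitude (arbitrary units).
#' @param noise_std additive noise sd as a fraction of `amplitude`.
#' @param sample_rate output sampling rate in Hz.
#' @param duration trial length in seconds.
#' @param n_trials trials to generate (defaults: 7 solo, 6 group).
#' @param seed master seed; per-trial sub-seeds are derived from it.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_players = 5L,
                         solo_freq_mean = chronos_solo_ensemble()$omega_mean,
                         solo_freq_std = chronos_solo_ensemble()$omega_std,
                         group_model = NULL, amplitude = 1, noise_std = 0.05,
                         sample_rate = 10, duration = 30, n_trials = NULL,
                         seed = 1L) {
  stopifnot(n_players >= 1L, amplitude > 0, noise_std >= 0,
            sample_rate > 0, duration > 0)
  solo_freq_mean <- rep_len(solo_freq_mean, n_players)
  solo_freq_std <- rep_len(solo_freq_std, n_players)
  structure(list(n_players = as.integer(n_players),
                 solo_freq_mean = solo_freq_mean,
                 solo_freq_std = solo_freq_std, group_model = group_model,
                 amplitude = amplitude, noise_std = noise_std,
                 sample_rate = sample_rate, duration = duration,
                 n_trials = n_trials, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate synthetic solo trials
#'
#' Each trial draws, per player, a trial frequency from
#' \eqn{N(\bar\omega_i, \sigma_i)} (non-positive draws redrawn) and a uniform
#' starting phase, then emits \eqn{x(t) = A \sin(\omega t + \phi_0)} plus
#' Gaussian noise on the `sample_rate` grid. Frequency variability is
#' realized across trials, not within a trial, matching how solo statistics
#' are estimated (mean frequency per trial, spread across trials). The
#' drawn ground-truth frequencies are attached to each trial as attribute
#' `true_freqs`.
#'
#' @param config a [synth_config()].
#' @return List of [position_trial()] objects (length `n_trials`, default 7).
#' @export
generate_solo_trials <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n_trials <- if (is.null(config$n_trials)) 7L else config$n_trials
  times <- seq(0, config$duration, by = 1 / config$sample_rate)
  lapply(seq_len(n_trials), function(k) {
    set.seed(derive_seed(config$seed, k))
    omega <- rnorm(config$n_players, config$solo_freq_mean,
                   config$solo_freq_std)
    while (any(omega <= 0)) {
      bad <- which(omega <= 0)
      omega[bad] <- rnorm(length(bad), config$solo_freq_mean[bad],
                          config$solo_freq_std[bad])
    }
    phi0 <- runif(config$n_players, 0, 2 * pi)
    pos <- vapply(seq_len(config$n_players), function(j) {
      config$amplitude * sin(omega[j] * times + phi0[j]) +
        rnorm(length(times), 0, config$noise_std * config$amplitude)
    }, numeric(length(times)))
    trial <- position_trial(times, pos, "solo", sprintf("solo-%02d", k))
    attr(trial, "true_freqs") <- omega
    trial
  })
}

#' Generate synthetic group trials from a model
#'
#' Each trial simulates `config$group_model` (via [simulate_model()], 0.01 s
#' Euler step, uniform initial phases, per-agent Gaussian frequencies), maps
#' phases to positions \eqn{x = A \sin\theta}, downsamples to `sample_rate`
#' and adds Gaussian noise. The true [phase_trajectory()] and its
#' [summarize_trial()] ground truth are attached to each trial as attributes
#' `true_trajectory` and `true_summary`, enabling round-trip testing of the
#' preprocessing chain.
#'
#' @param config a [synth_config()] with a non-NULL `group_model`.
#' @param dt simulation step in seconds; must divide `1/sample_rate`.
#' @return List of [position_trial()] objects (length `n_trials`, default 6).
#' @export
generate_group_trials <- function(config, dt = 0.01) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(config$group_model))
    stop("`config$group_model` must be a model_spec for group trials")
  n_trials <- if (is.null(config$n_trials)) 6L else config$n_trials
  step <- round(1 / (config$sample_rate * dt))
  if (abs(step * dt * config$sample_rate - 1) > 1e-9)
    stop("`dt` must divide the output sampling interval")
  ensemble <- agent_ensemble(config$solo_freq_mean, config$solo_freq_std)
  lapply(seq_len(n_trials), function(k) {
    sub_seed <- derive_seed(config$seed, 100L + k)
    traj <- simulate_model(config$group_model, ensemble,
                           sim_config(dt = dt, duration = config$duration,
                                      seed = sub_seed))
    idx <- seq(1L, length(traj$times), by = step)
    set.seed(derive_seed(sub_seed, 1L))
    noise <- matrix(rnorm(length(idx) * config$n_players, 0,
                          config$noise_std * config$amplitude),
                    nrow = length(idx))
    pos <- config$amplitude * sin(traj$phases[idx, , drop = FALSE]) + noise
    trial <- position_trial(traj$times[idx], pos, "group",
                            sprintf("group-%02d", k))
    attr(trial, "true_trajectory") <- traj
    attr(trial, "true_summary") <- summarize_trial(traj)
    trial
  })
}
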