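#' Agent ensemble: per-player natural frequency statistics
#'
#' Bundles the number of agents with each agent's solo natural-frequency mean
#' \eqn{\bar\omega_i} and standard deviation \eqn{\sigma_i} (rad/s), as
#' estimated from solo trials. These statistics parameterize the frequency
#' draws of every simulated trial and the attention weights of the
#' variability-weighted model.
#'
#' @param omega_mean numeric vector of per-agent mean natural frequencies
#'   (rad/s), all positive.
#' @param omega_std numeric vector of per-agent standard deviations (rad/s),
#'   all non-negative; recycled if scalar.
#' @return Object of class `agent_ensemble`.
#' @seealso [chronos_solo_ensemble()] for the packaged five-player values.
#' @export
agent_ensemble <- function(omega_mean, omega_std = 0) {
  omega_mean <- as.numeric(omega_mean)
  omega_std <- rep_len(as.numeric(omega_std), length(omega_mean))
  if (length(omega_mean) < 1L) stop("need at least one agent")
  if (any(!is.finite(omega_mean)) || any(omega_mean <= 0))
    stop("`omega_mean` must be positive and finite")
  if (any(!is.finite(omega_std)) || any(omega_std < 0))
    stop("`omega_std` must be non-negative and finite")
  structure(list(n_agents = length(omega_mean), omega_mean = omega_mean,
                 omega_std = omega_std),
            class = "agent_ensemble")
}

#' Specify a group-synchronization model
#'
#' Selects one member of the coupled phase-oscillator family and its
#' parameters:
#'
#' * `"standard"` — heterogeneous Kuramoto oscillators on a complete graph,
#'   \eqn{\dot\theta_i = \omega_i + c \sum_j \sin(\theta_j - \theta_i)}.
#' * `"adaptive"` — behavioral plasticity: natural frequencies decay,
#'   \eqn{\dot\omega_i = -\omega_i / r^2}, whenever the order parameter is
#'   below the threshold `r_threshold`, modeling individuals slowing down
#'   until the group reaches a desired coordination level.
#' * `"weighted"` — selective attention: coupling weighted by
#'   \eqn{w_{ij} = \sigma_i/\sigma_j}, the ratio of solo motor variabilities,
#'   so agents attend most to their most predictable partners.
#' * `"delayed"` — perception-action latency: each agent sees its partners'
#'   phases delayed by `delay_tau` seconds,
#'   \eqn{\dot\theta_i = \omega_i + c \sum_j \sin(\theta_j(t-\tau) - \theta_i(t))}.
#'
#' For the delayed model, a literal reading of the coupling sum includes the
#' `j = i` term, whose delayed self-coupling \eqn{\sin(\theta_i(t-\tau) -
#' \theta_i(t))} is nonzero and measurably lowers the locked frequency. The
#' default includes it; set `include_delayed_self_coupling = FALSE` to sum
#' over partners only. The choice is echoed in every simulation result.
#'
#' @param model_id one of `"standard"`, `"adaptive"`, `"weighted"`,
#'   `"delayed"`.
#' @param coupling_c coupling gain \eqn{c \ge 0} (1/s).
#' @param r_threshold order-parameter threshold \eqn{\tilde r \in (0, 1]}
#'   (adaptive model only).
#' @param delay_tau perception-action delay \eqn{\tau \ge 0} in seconds
#'   (delayed model only).
#' @param weights optional attention-weight matrix for the weighted model;
#'   computed from the ensemble via [build_attention_weights()] when omitted.
#' @param include_delayed_self_coupling logical flag (delayed model only).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(model_id = c("standard", "adaptive", "weighted", "delayed"),
                       coupling_c, r_threshold = NULL, delay_tau = NULL,
                       weights = NULL, include_delayed_self_coupling = TRUE) {
  model_id <- match.arg(model_id)
  if (missing(coupling_c) || !is.finite(coupling_c) || coupling_c < 0)
    stop("`coupling_c` must be a non-negative number")
  if (model_id == "adaptive") {
    if (is.null(r_threshold))
      stop("adaptive model requires `r_threshold`")
    if (!is.finite(r_threshold) || r_threshold <= 0 || r_threshold > 1)
      stop("`r_threshold` must lie in (0, 1]")
  }
  if (model_id == "delayed") {
    if (is.null(delay_tau))
      stop("delayed model requires `delay_tau`")
    if (!is.finite(delay_tau) || delay_tau < 0)
      stop("`delay_tau` must be non-negative")
  }
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (any(weights < 0)) stop("weights must be non-negative")
  }
  structure(list(model_id = model_id, coupling_c = coupling_c,
                 r_threshold = r_threshold, delay_tau = delay_tau,
                 weights = weights,
                 include_delayed_self_coupling = include_delayed_self_coupling),
            class = "model_spec")
}

#' Simulation configuration
#'
#' @param dt integration step in seconds (default 0.01 s, matching the 100 Hz
#'   analysis grid; for the delayed model `delay_tau` is rounded to an integer
#'   number of steps and the rounding recorded in the result).
#' @param duration trial length in seconds (default 30 s).
#' @param seed integer seed controlling initial phases and frequency draws.
#' @param initial_phases `"uniform-random"` (i.i.d. uniform on \eqn{[0, 2\pi)})
#'   or a numeric vector of starting phases in radians.
#' @param frequency_draw `"gaussian-per-agent"` (per-agent
#'   \eqn{N(\bar\omega_i, \sigma_i)}, non-positive draws rejected and redrawn)
#'   or `"fixed-means"` (use \eqn{\bar\omega_i} verbatim).
#' @param integrator `"euler"` (fixed step, default) or `"rk4"`
#'   (standard/weighted models only, for convergence checks).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01, duration = 30, seed = 1L,
                       initial_phases = "uniform-random",
                       frequency_draw = c("gaussian-per-agent", "fixed-means"),
                       integrator = c("euler", "rk4")) {
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be positive")
  if (!is.finite(duration) || duration < dt) stop("`duration` must be >= dt")
  frequency_draw <- match.arg(frequency_draw)
  integrator <- match.arg(integrator)
  structure(list(dt = dt, duration = duration, seed = as.integer(seed),
                 initial_phases = initial_phases,
                 frequency_draw = frequency_draw, integrator = integrator),
            class = "sim_config")
}

#' Attention weights from solo motor variability
#'
#' Builds the selective-attention coupling matrix \eqn{w_{ij} =
#' \sigma_i/\sigma_j}: agents with larger solo variability (large
#' \eqn{\sigma_i}) adjust more to others, and everyone attends more to
#' partners whose motion is more predictable (small \eqn{\sigma_j}). The
#' matrix is reciprocal (\eqn{w_{ij} w_{ji} = 1}) with unit diagonal.
#'
#' @param ensemble an [agent_ensemble()] with strictly positive `omega_std`.
#' @return An `n_agents` x `n_agents` numeric matrix.
#' @export
build_attention_weights <- function(ensemble) {
  stopifnot(inherits(ensemble, "agent_ensemble"))
  s <- ensemble$omega_std
  if (any(s <= 0))
    stop("attention weights need strictly positive `omega_std`; ",
         "apply a positive floor to zero variabilities first")
  outer(s, s, "/")
}

#' Draw uniform random initial phases
#'
#' @param n_agents number of agents.
#' @param seed integer seed.
#' @return Numeric vector of i.i.d. phases uniform on \eqn{[0, 2\pi)}.
#' @export
draw_initial_phases <- function(n_agents, seed) {
  stopifnot(n_agents >= 1)
  set.seed(as.integer(seed))
  runif(n_agents, 0, 2 * pi)
}

#' Draw per-agent natural frequencies
#'
#' `"fixed-means"` returns the ensemble means verbatim; `"gaussian-per-agent"`
#' draws each agent's frequency from \eqn{N(\bar\omega_i, \sigma_i)},
#' rejecting and redrawing non-positive values (the number of redraws is
#' attached as attribute `n_redraws`).
#'
#' @param ensemble an [agent_ensemble()].
#' @param mode `"gaussian-per-agent"` or `"fixed-means"`.
#' @param seed integer seed.
#' @return Numeric vector of frequencies in rad/s.
#' @export
draw_natural_frequencies <- function(ensemble,
                                     mode = c("gaussian-per-agent", "fixed-means"),
                                     seed = 1L) {
  stopifnot(inherits(ensemble, "agent_ensemble"))
  mode <- match.arg(mode)
  if (mode == "fixed-means") return(ensemble$omega_mean)
  set.seed(as.integer(seed))
  omega <- rnorm(ensemble$n_agents, ensemble$omega_mean, ensemble$omega_std)
  n_redraws <- 0L
  while (any(omega <= 0)) {
    bad <- which(omega <= 0)
    omega[bad] <- rnorm(length(bad), ensemble$omega_mean[bad],
                        ensemble$omega_std[bad])
    n_redraws <- n_redraws + length(bad)
  }
  attr(omega, "n_redraws") <- n_redraws
  omega
}

#' Simulate a group-synchronization model
#'
#' Integrates the chosen model with a fixed-step explicit Euler scheme (or
#' RK4 for the undelayed, non-adaptive variants) on a complete interaction
#' graph. All four variants share a single integration code path, so setting
#' `delay_tau = 0`, equal `omega_std`, or `r_threshold` below the realized
#' order parameter reproduces the standard model trajectory bitwise.
#'
#' Delay history: for `t < 0` the partners' phases are held at their initial
#' values \eqn{\theta_j(0)}; `delay_tau` is rounded to an integer number of
#' `dt` steps (`delay_steps` in the result records the rounding).
#'
#' @param spec a [model_spec()].
#' @param ensemble an [agent_ensemble()].
#' @param config a [sim_config()].
#' @return A [phase_trajectory()] with extra attributes: `spec`, `config`,
#'   `omega0` (the drawn natural frequencies), `delay_steps`, and for the
#'   adaptive model a populated `omega` element with \eqn{\omega_i(t)}.
#' @export
simulate_model <- function(spec, ensemble, config = sim_config()) {
  stopifnot(inherits(spec, "model_spec"), inherits(ensemble, "agent_ensemble"),
            inherits(config, "sim_config"))
  n <- ensemble$n_agents
  set.seed(config$seed)
  theta0 <- if (is.character(config$initial_phases)) {
    runif(n, 0, 2 * pi)
  } else {
    ph <- as.numeric(config$initial_phases)
    if (length(ph) != n) stop("`initial_phases` must have one entry per agent")
    ph
  }
  omega0 <- if (config$frequency_draw == "fixed-means") {
    ensemble$omega_mean
  } else {
    om <- rnorm(n, ensemble$omega_mean, ensemble$omega_std)
    while (any(om <= 0)) {
      bad <- which(om <= 0)
      om[bad] <- rnorm(length(bad), ensemble$omega_mean[bad],
                       ensemble$omega_std[bad])
    }
    om
  }

  weights <- matrix(1, n, n)
  delay_steps <- 0L
  adaptive <- FALSE
  r_threshold <- 0
  if (spec$model_id == "weighted") {
    weights <- if (is.null(spec$weights)) build_attention_weights(ensemble)
               else spec$weights
    if (!all(dim(weights) == c(n, n)))
      stop("weights matrix must be n_agents x n_agents")
  } else if (spec$model_id == "delayed") {
    delay_steps <- as.integer(round(spec$delay_tau / config$dt))
    if (!spec$include_delayed_self_coupling)
      diag(weights) <- 0
  } else if (spec$model_id == "adaptive") {
    adaptive <- TRUE
    r_threshold <- spec$r_threshold
  }

  n_steps <- as.integer(round(config$duration / config$dt)) + 1L
  times <- (seq_len(n_steps) - 1L) * config$dt

  if (config$integrator == "rk4") {
    if (spec$model_id %in% c("adaptive", "delayed"))
      stop("RK4 integration is available for the standard and weighted models only")
    theta <- .sim_phase_rk4(theta0, omega0, spec$coupling_c, weights,
                            n_steps, config$dt)
    res <- list(theta = theta, omega = NULL)
  } else {
    res <- .sim_phase_euler(theta0, omega0, spec$coupling_c, weights,
                            delay_steps, adaptive, r_threshold,
                            n_steps, config$dt, adaptive)
  }

  traj <- phase_trajectory(times, res$theta, omega = res$omega)
  attr(traj, "spec") <- spec
  attr(traj, "config") <- config
  attr(traj, "omega0") <- omega0
  attr(traj, "delay_steps") <- delay_steps
  traj
}
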