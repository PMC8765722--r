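# Independent brute-force oracles, written as literal element-by-element
# loops over the defining sums; deliberately un-vectorized so they share no
# code with the package implementation.

oracle_order_parameter <- function(phases) {
  re <- 0; im <- 0
  for (p in phases) {
    re <- re + cos(p)
    im <- im + sin(p)
  }
  sqrt((re / length(phases))^2 + (im / length(phases))^2)
}

oracle_group_phase <- function(phases) {
  re <- 0; im <- 0
  for (p in phases) {
    re <- re + cos(p)
    im <- im + sin(p)
  }
  atan2(im / length(phases), re / length(phases))
}

# literal loop over the frequency-coordination definitions: relative phase
# phi_i = theta_i - psi, trailing windowed mean of e^{j phi_i} (growing
# window at the start), its angle, and rho = |mean_i e^{j Delta phi_i}|
oracle_rho_series <- function(theta, w) {
  n_t <- nrow(theta); n <- ncol(theta)
  psi <- numeric(n_t)
  for (t in seq_len(n_t)) psi[t] <- oracle_group_phase(theta[t, ])
  phi <- matrix(0, n_t, n)
  for (t in seq_len(n_t)) for (i in seq_len(n)) {
    v <- (theta[t, i] - psi[t]) %% (2 * pi)
    if (v > pi) v <- v - 2 * pi
    phi[t, i] <- v
  }
  rho <- numeric(n_t)
  for (t in seq_len(n_t)) {
    sre <- 0; sim <- 0
    for (i in seq_len(n)) {
      lo <- max(1L, t - w + 1L)
      mre <- 0; mim <- 0
      for (l in lo:t) {
        mre <- mre + cos(phi[l, i])
        mim <- mim + sin(phi[l, i])
      }
      phibar <- atan2(mim / (t - lo + 1), mre / (t - lo + 1))
      dphi <- phi[t, i] - phibar
      sre <- sre + cos(dphi)
      sim <- sim + sin(dphi)
    }
    rho[t] <- sqrt(sre^2 + sim^2) / n
  }
  rho
}

# random-walk phase trajectory (not a model output) for metric stress tests
random_walk_trajectory <- function(n_t = 300, n_agents = 5, dt = 0.01,
                                   seed = 1) {
  set.seed(seed)
  steps <- matrix(rnorm(n_t * n_agents, 0.05, 0.1), n_t, n_agents)
  phase_trajectory((seq_len(n_t) - 1) * dt, apply(steps, 2, cumsum))
}

table1_ensemble <- function() chronos_solo_ensemble()
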