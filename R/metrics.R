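#' Kuramoto order parameter of a set of phases
#'
#' Magnitude of the mean unit phasor, \eqn{r = |N^{-1} \sum_i e^{j\theta_i}|}.
#' `r = 1` means all agents share the same phase; values near 0 indicate
#' incoherence. Invariant under agent relabeling and under adding a common
#' constant to all phases.
#'
#' @param phases numeric vector of phases in radians (one per agent).
#' @return A scalar in `[0, 1]`.
#' @export
#' @examples
#' order_parameter(rep(1.3, 5))            # 1
#' order_parameter(c(0, pi/2, pi, 3*pi/2)) # 0
order_parameter <- function(phases) {
  if (length(phases) == 0L) stop("need at least one agent phase")
  if (!all(is.finite(phases))) stop("phases must be finite")
  Mod(mean(exp(1i * phases)))
}

#' Group phase of a set of phases
#'
#' Four-quadrant angle of the complex mean phasor \eqn{q(t)}, the collective
#' phase of the ensemble, reported in \eqn{(-\pi, \pi]}.
#'
#' @inheritParams order_parameter
#' @param tol magnitude below which the mean phasor is treated as zero and the
#'   group phase as undefined.
#' @return A scalar in radians.
#' @export
group_phase <- function(phases, tol = 1e-12) {
  if (length(phases) == 0L) stop("need at least one agent phase")
  if (!all(is.finite(phases))) stop("phases must be finite")
  q <- mean(exp(1i * phases))
  if (Mod(q) < tol)
    stop("group phase undefined: order parameter is (numerically) zero")
  Arg(q)
}

# wrap angles to (-pi, pi]
wrap_pi <- function(x) {
  y <- x %% (2 * pi)
  y[y > pi] <- y[y > pi] - 2 * pi
  y
}

#' Full synchronization time series of a trajectory
#'
#' Computes, at every sample of a [phase_trajectory()]: the order parameter
#' `r(t)`, the group phase `psi(t)`, each agent's relative phase
#' \eqn{\phi_i(t) = \theta_i(t) - \psi(t)}, the moving-average relative phase
#' \eqn{\bar\phi_i(t)} (angle of the trailing windowed mean of
#' \eqn{e^{j\phi_i}}), and the frequency-coordination index
#' \eqn{\rho(t) = |N^{-1}\sum_i e^{j\Delta\phi_i(t)}|} with
#' \eqn{\Delta\phi_i = \phi_i - \bar\phi_i}. \eqn{\rho = 1} corresponds to a
#' perfect match of the agents' oscillation frequencies at time `t`.
#'
#' For samples earlier than one full window the moving average is taken over
#' the available (growing) window, so every series is defined on the whole
#' trial.
#'
#' @param traj a [phase_trajectory()].
#' @param window_w moving-average window length in samples (positive integer).
#'   Defaults to 1 s worth of samples (100 at the 100 Hz analysis grid).
#' @return An object of class `sync_series`: list with `times`, `r`, `psi`
#'   (wrapped to \eqn{(-\pi,\pi]}), `psi_unwrapped`, `rho`, `rel_phase`,
#'   `rel_phase_avg` (both time-by-agent matrices) and `window_w`.
#' @export
sync_series <- function(traj, window_w = round(1 / traj$dt)) {
  stopifnot(inherits(traj, "phase_trajectory"))
  window_w <- as.integer(window_w)
  if (is.na(window_w) || window_w < 1L)
    stop("`window_w` must be a positive integer number of samples")
  n_t <- length(traj$times)
  if (n_t <= window_w)
    stop("trajectory must be longer than `window_w`")

  z <- exp(1i * traj$phases)
  q <- rowMeans(z)
  r <- Mod(q)
  psi <- Arg(q)
  psi_un <- as.numeric(signal::unwrap(psi))

  phi <- wrap_pi(traj$phases - psi)        # theta_i - psi, mod 2pi
  zphi <- exp(1i * phi)
  # trailing windowed mean of e^{j phi_i}, growing window at the start
  cum <- apply(zphi, 2L, cumsum)
  lagged <- rbind(matrix(0i, window_w, traj$n_agents),
                  cum[seq_len(n_t - window_w), , drop = FALSE])
  counts <- pmin(seq_len(n_t), window_w)
  mov <- (cum - lagged) / counts
  phibar <- Arg(mov)
  dphi <- phi - phibar
  rho <- Mod(rowMeans(exp(1i * dphi)))

  structure(
    list(times = traj$times, r = r, psi = wrap_pi(psi), psi_unwrapped = psi_un,
         rho = rho, rel_phase = phi, rel_phase_avg = phibar,
         window_w = window_w),
    class = "sync_series"
  )
}

#' Frequency-coordination index over time
#'
#' Convenience accessor returning only the \eqn{\rho(t)} series of
#' [sync_series()].
#'
#' @inheritParams sync_series
#' @return Numeric vector of \eqn{\rho(t)} values in `[0, 1]`.
#' @export
frequency_coordination <- function(traj, window_w = round(1 / traj$dt)) {
  sync_series(traj, window_w)$rho
}

#' Group oscillation frequency of a trajectory
#'
#' Time-averaged finite-difference derivative of the group phase. Two
#' estimators are available: `"group-phase"` differentiates the unwrapped
#' group phase \eqn{\psi(t)} (robust to single drifting outliers, the
#' reported default), `"agent-mean"` averages the per-agent instantaneous
#' frequencies (for the standard model this equals the mean natural frequency
#' at every step, by antisymmetry of the coupling).
#'
#' @inheritParams sync_series
#' @param discard_transient initial time span in seconds excluded from the
#'   average (default 0).
#' @param method `"group-phase"` or `"agent-mean"`.
#' @return Scalar frequency in rad/s.
#' @export
group_frequency <- function(traj, discard_transient = 0,
                            method = c("group-phase", "agent-mean")) {
  stopifnot(inherits(traj, "phase_trajectory"))
  method <- match.arg(method)
  keep <- traj$times >= traj$times[1L] + discard_transient
  if (sum(keep) < 2L)
    stop("fewer than 2 samples remain after discarding the transient")
  if (method == "group-phase") {
    psi <- Arg(rowMeans(exp(1i * traj$phases[keep, , drop = FALSE])))
    psi <- as.numeric(signal::unwrap(psi))
    mean(diff(psi)) / traj$dt
  } else {
    inst <- apply(traj$phases[keep, , drop = FALSE], 2L, diff) / traj$dt
    mean(rowMeans(as.matrix(inst)))
  }
}

#' Summarize a trial into scalar synchronization statistics
#'
#' Time averages of the order parameter and frequency-coordination index plus
#' the group oscillation frequency; the per-trial triple \eqn{(\bar r,
#' \bar\rho, \bar\omega_g)} that calibration and model comparison consume.
#'
#' @inheritParams group_frequency
#' @param window_w moving-average window (samples) for \eqn{\rho}.
#' @return Object of class `trial_summary`: list with `r_bar`, `rho_bar`,
#'   `omega_g`, `window_w`, `discard_transient`.
#' @export
summarize_trial <- function(traj, window_w = round(1 / traj$dt),
                            discard_transient = 0) {
  ss <- sync_series(traj, window_w)
  keep <- ss$times >= ss$times[1L] + discard_transient
  if (sum(keep) < 2L)
    stop("fewer than 2 samples remain after discarding the transient")
  trial_summary(
    r_bar = mean(ss$r[keep]),
    rho_bar = mean(ss$rho[keep]),
    omega_g = mean(diff(ss$psi_unwrapped[keep])) / (ss$times[2L] - ss$times[1L]),
    window_w = ss$window_w,
    discard_transient = discard_transient
  )
}

#' Construct a trial summary
#'
#' @param r_bar time-averaged order parameter, in `[0, 1]`.
#' @param rho_bar time-averaged frequency-coordination index, in `[0, 1]`.
#' @param omega_g group oscillation frequency in rad/s.
#' @param window_w,discard_transient metadata recording how the summary was
#'   computed.
#' @return Object of class `trial_summary`.
#' @export
trial_summary <- function(r_bar, rho_bar, omega_g, window_w = NA_integer_,
                          discard_transient = 0) {
  stopifnot(is.finite(r_bar), is.finite(rho_bar), is.finite(omega_g))
  structure(
    list(r_bar = r_bar, rho_bar = rho_bar, omega_g = omega_g,
         window_w = window_w, discard_transient = discard_transient),
    class = "trial_summary"
  )
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf("<trial_summary> r_bar = %.3f, rho_bar = %.3f, omega_g = %.3f rad/s\n",
              x$r_bar, x$rho_bar, x$omega_g))
  invisible(x)
}
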