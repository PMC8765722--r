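#' Phase trajectory of a group of oscillating agents
#'
#' Container for the unwrapped phases \eqn{\theta_i(t)} of `n_agents` agents on
#' a uniform time grid. This is the object all synchronization metrics consume,
#' produced either by [simulate_model()] or by [extract_phase()] from raw
#' position traces.
#'
#' @param times numeric vector of time stamps in seconds, strictly increasing
#'   and uniformly spaced (relative step tolerance 1e-9).
#' @param phases numeric matrix of unwrapped phases in radians, one row per
#'   time stamp, one column per agent.
#' @param omega optional matrix of per-agent instantaneous natural frequencies
#'   (rad/s), same shape as `phases`; populated by the adaptive model.
#'
#' @return An object of class `phase_trajectory`: a list with elements
#'   `times`, `phases`, `n_agents`, `dt` and optionally `omega`.
#' @export
phase_trajectory <- function(times, phases, omega = NULL) {
  phases <- as.matrix(phases)
  if (length(times) != nrow(phases))
    stop("`times` and `phases` must have matching length/rows")
  if (length(times) < 2L)
    stop("a phase trajectory needs at least 2 samples")
  if (!all(is.finite(times)) || !all(is.finite(phases)))
    stop("times and phases must be finite")
  steps <- diff(times)
  if (any(steps <= 0))
    stop("`times` must be strictly increasing")
  dt <- steps[1L]
  if (any(abs(steps - dt) > 1e-9 * max(abs(dt), 1)))
    stop("`times` must be uniformly spaced")
  if (!is.null(omega)) {
    omega <- as.matrix(omega)
    stopifnot(identical(dim(omega), dim(phases)))
  }
  structure(
    list(times = as.numeric(times), phases = unname(phases),
         n_agents = ncol(phases), dt = dt, omega = omega),
    class = "phase_trajectory"
  )
}

#' Trim a phase trajectory at its edges
#'
#' Drops `head` seconds at the start and `tail` seconds at the end. Useful
#' before slope-based frequency estimates on reconstructed phases, whose
#' first and last fraction of a second carry analytic-signal edge artifacts.
#'
#' @param traj a [phase_trajectory()].
#' @param head,tail seconds to drop at each end.
#' @return A shorter [phase_trajectory()].
#' @export
trim_trajectory <- function(traj, head = 0, tail = 0) {
  stopifnot(inherits(traj, "phase_trajectory"))
  t0 <- traj$times[1L]
  t1 <- traj$times[length(traj$times)]
  keep <- traj$times >= t0 + head & traj$times <= t1 - tail
  if (sum(keep) < 2L) stop("trimming leaves fewer than 2 samples")
  phase_trajectory(traj$times[keep], traj$phases[keep, , drop = FALSE],
                   omega = if (!is.null(traj$omega))
                     traj$omega[keep, , drop = FALSE])
}

#' @export
print.phase_trajectory <- function(x, ...) {
  cat(sprintf("<phase_trajectory> %d agents, %d samples, dt = %g s, span %.2f s\n",
              x$n_agents, length(x$times), x$dt,
              x$times[length(x$times)] - x$times[1L]))
  invisible(x)
}
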