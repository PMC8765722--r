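#' Multi-player position trial
#'
#' Raw position traces of one trial: a uniform time grid (nominally 10 Hz as
#' recorded by the acquisition platform) and one displacement column per
#' player. Gaps (NA/NaN) are rejected at construction: the preprocessing
#' chain fails loudly rather than imputing.
#'
#' @param times numeric vector of sample times in seconds, uniformly spaced.
#' @param positions matrix of displacements (arbitrary consistent units),
#'   one row per time stamp, one column per player.
#' @param trial_kind `"solo"` or `"group"`.
#' @param trial_id optional identifier.
#' @return Object of class `position_trial`.
#' @export
position_trial <- function(times, positions, trial_kind = c("group", "solo"),
                           trial_id = NA_character_) {
  trial_kind <- match.arg(trial_kind)
  positions <- as.matrix(positions)
  if (length(times) != nrow(positions))
    stop("`times` and `positions` must have matching length/rows")
  if (length(times) < 2L) stop("need at least 2 samples")
  if (anyNA(positions) || any(!is.finite(positions)))
    stop("positions contain NA/non-finite values; fill or drop gaps before ingest")
  steps <- diff(times)
  if (any(steps <= 0) || any(abs(steps - steps[1L]) > 1e-9 * steps[1L]))
    stop("`times` must be strictly increasing and uniformly spaced")
  structure(list(times = as.numeric(times), positions = unname(positions),
                 n_players = ncol(positions), rate = 1 / steps[1L],
                 trial_kind = trial_kind, trial_id = trial_id),
            class = "position_trial")
}

#' Resample a position trial to a finer uniform grid
#'
#' Cubic-spline interpolation of each player's trace onto a uniform grid at
#' `rate` Hz spanning the original support (default 100 Hz, the grid used for
#' all phase analysis). Endpoints are preserved.
#'
#' @param trial a [position_trial()].
#' @param rate target sampling rate in Hz.
#' @return A [position_trial()] on the new grid.
#' @export
resample_positions <- function(trial, rate = 100) {
  stopifnot(inherits(trial, "position_trial"))
  if (length(trial$times) < 4L)
    stop("spline resampling needs at least 4 samples")
  t0 <- trial$times[1L]
  t1 <- trial$times[length(trial$times)]
  xout <- t0 + seq(0L, floor((t1 - t0) * rate + 1e-9)) / rate
  pos <- vapply(seq_len(trial$n_players), function(j) {
    spline(trial$times, trial$positions[, j], xout = xout, method = "fmm")$y
  }, numeric(length(xout)))
  position_trial(xout, pos, trial$trial_kind, trial$trial_id)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) Butterworth low-pass of each player's trace.
#' The default cutoff of 6 Hz is twice the ~3 Hz upper rate of natural human
#' oscillatory movement; DC gain is 1 so slow drifts pass unchanged.
#'
#' @param trial a [position_trial()].
#' @param cutoff_hz cutoff frequency in Hz, strictly below Nyquist.
#' @param order filter order (default 2; applied twice by filtering in both
#'   directions, so the effective attenuation is the squared magnitude
#'   response).
#' @return A filtered [position_trial()].
#' @export
lowpass_positions <- function(trial, cutoff_hz = 6, order = 2) {
  stopifnot(inherits(trial, "position_trial"))
  nyq <- trial$rate / 2
  if (cutoff_hz >= nyq)
    stop(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                 cutoff_hz, nyq))
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  # odd-symmetric padding before the forward-backward pass suppresses the
  # start-up transient of the recursion at both ends
  n <- length(trial$times)
  pad <- min(3L * (2L * order + 1L) * 5L, n - 1L)
  pos <- apply(trial$positions, 2L, function(x) {
    ext <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
    signal::filtfilt(bf, ext)[(pad + 1L):(pad + n)]
  })
  position_trial(trial$times, pos, trial$trial_kind, trial$trial_id)
}

# FFT-based analytic signal: x + j*H[x]. Negative frequencies zeroed,
# positive doubled, DC (and Nyquist for even n) kept.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Reconstruct phases from position traces
#'
#' Per player: subtract the trial mean (finger-position DC offset), form the
#' analytic signal via the Hilbert transform, take its angle and unwrap. The
#' result lives on the trial's own grid, so apply [resample_positions()] and
#' [lowpass_positions()] first for the standard 100 Hz chain.
#'
#' @param trial a [position_trial()].
#' @return A [phase_trajectory()] of unwrapped phases in radians.
#' @export
extract_phase <- function(trial) {
  stopifnot(inherits(trial, "position_trial"))
  phases <- vapply(seq_len(trial$n_players), function(j) {
    x <- trial$positions[, j]
    x <- x - mean(x)
    if (all(abs(x) < .Machine$double.eps * 100))
      stop(sprintf("player %d signal is constant; phase undefined", j))
    as.numeric(signal::unwrap(Arg(analytic_signal(x))))
  }, numeric(length(trial$times)))
  phase_trajectory(trial$times, phases)
}

#' Full preprocessing chain: positions to phases
#'
#' Convenience wrapper: spline-resample to `rate` Hz, zero-phase Butterworth
#' low-pass, analytic-signal phase extraction.
#'
#' @inheritParams lowpass_positions
#' @param rate analysis sampling rate in Hz (default 100).
#' @return A [phase_trajectory()].
#' @export
preprocess_trial <- function(trial, rate = 100, cutoff_hz = 6, order = 2) {
  extract_phase(lowpass_positions(resample_positions(trial, rate),
                                  cutoff_hz, order))
}

#' Per-player solo frequency statistics from solo trials
#'
#' Estimates each player's natural-frequency mean and standard deviation from
#' repeated solo trials: per trial and player, the mean instantaneous
#' frequency (phase slope) is computed with `edge_trim` seconds excluded at
#' both ends (analytic-signal edge artifacts); the per-player mean and sd
#' across trials form the ensemble.
#'
#' @param solo_trials list of [position_trial()] objects, all with the same
#'   players in the same column order.
#' @param rate,cutoff_hz,order preprocessing settings, see
#'   [preprocess_trial()].
#' @param edge_trim seconds excluded at each end of the phase-slope estimate.
#' @return An [agent_ensemble()] with attribute `per_trial_freqs` (trial x
#'   player matrix of the underlying estimates).
#' @export
solo_frequency_stats <- function(solo_trials, rate = 100, cutoff_hz = 6,
                                 order = 2, edge_trim = 0.5) {
  if (length(solo_trials) < 1L) stop("need at least one solo trial")
  n_players <- solo_trials[[1L]]$n_players
  freqs <- vapply(solo_trials, function(trial) {
    if (trial$n_players != n_players)
      stop("all solo trials must cover the same players")
    traj <- preprocess_trial(trial, rate, cutoff_hz, order)
    keep <- traj$times >= traj$times[1L] + edge_trim &
      traj$times <= traj$times[length(traj$times)] - edge_trim
    if (sum(keep) < 2L) stop("trial too short for the edge trim")
    apply(traj$phases[keep, , drop = FALSE], 2L,
          function(th) mean(diff(th)) / traj$dt)
  }, numeric(n_players))
  freqs <- t(matrix(freqs, nrow = n_players))  # trial x player
  ens <- agent_ensemble(
    omega_mean = colMeans(freqs),
    omega_std = if (nrow(freqs) > 1L) apply(freqs, 2L, sd) else rep(0, n_players)
  )
  attr(ens, "per_trial_freqs") <- freqs
  ens
}

#' Read / write position trials as columnar text
#'
#' Plain CSV with a `t` column followed by `p1..pN` player columns — the
#' exchange format of the acquisition platform and of
#' [generate_solo_trials()] / [generate_group_trials()].
#'
#' @param path file path.
#' @param trial_kind,trial_id metadata for the constructed trial.
#' @return `read_position_trial()` returns a [position_trial()];
#'   `write_position_trial()` invisibly returns `path`.
#' @export
read_position_trial <- function(path, trial_kind = c("group", "solo"),
                                trial_id = NA_character_) {
  df <- read.csv(path)
  if (names(df)[1L] != "t")
    stop("expected a `t` time column followed by player columns")
  position_trial(df$t, as.matrix(df[, -1L, drop = FALSE]),
                 match.arg(trial_kind), trial_id)
}

#' @rdname read_position_trial
#' @param trial a [position_trial()] to write.
#' @export
write_position_trial <- function(trial, path) {
  stopifnot(inherits(trial, "position_trial"))
  df <- data.frame(t = trial$times, trial$positions)
  names(df) <- c("t", paste0("p", seq_len(trial$n_players)))
  # %.17g so doubles survive the text round trip bit-identically
  df[] <- lapply(df, function(x) sprintf("%.17g", x))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
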