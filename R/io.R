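#' Write a phase trajectory as columnar text with a JSON sidecar
#'
#' The trajectory goes to `path` as CSV (`t`, `theta_1..theta_N`); the model
#' specification and simulation configuration, when present as attributes,
#' are echoed bit-exactly to `<path>.json`.
#'
#' @param traj a [phase_trajectory()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "phase_trajectory"))
  df <- data.frame(t = traj$times, traj$phases)
  names(df) <- c("t", paste0("theta_", seq_len(traj$n_agents)))
  df[] <- lapply(df, function(x) sprintf("%.17g", x))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(spec = attr(traj, "spec"), config = attr(traj, "config"),
               omega0 = attr(traj, "omega0"),
               delay_steps = attr(traj, "delay_steps"))
  meta <- Filter(Negate(is.null), lapply(meta, function(x)
    if (is.object(x)) unclass(x) else x))
  if (length(meta))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  invisible(path)
}

#' Read a phase trajectory written by [write_trajectory()]
#'
#' @param path CSV path.
#' @return A [phase_trajectory()].
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path)
  phase_trajectory(df$t, as.matrix(df[, -1L, drop = FALSE]))
}

#' Write a trial summary as a JSON record
#'
#' Keys: `r_bar`, `rho_bar`, `omega_g`, `window_w`, `discard_transient`.
#'
#' @param summary a [trial_summary()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "trial_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
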