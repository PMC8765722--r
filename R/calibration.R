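#' Experimental summary statistics
#'
#' Trial-averaged group observables of an experiment: order parameter
#' \eqn{\bar r}, frequency-coordination index \eqn{\bar\rho}, and group
#' oscillation frequency \eqn{\bar\omega_g}, optionally with the per-trial
#' values. When per-trial values are unavailable (only published averages),
#' pairwise-cost routines fall back on the table-average approximation:
#' every experimental trial is taken equal to the average.
#'
#' @param r_bar,rho_bar averaged order parameter / coordination index in
#'   `[0, 1]`.
#' @param omega_g averaged group frequency, rad/s.
#' @param per_trial optional list of [trial_summary()] objects.
#' @param n_trials number of experimental trials (defaults to
#'   `length(per_trial)` or 1).
#' @param sds optional named numeric vector of published standard deviations.
#' @return Object of class `experiment_summary`.
#' @export
experiment_summary <- function(r_bar, rho_bar, omega_g, per_trial = NULL,
                               n_trials = NULL, sds = NULL) {
  stopifnot(r_bar >= 0, r_bar <= 1, rho_bar >= 0, rho_bar <= 1,
            is.finite(omega_g))
  if (is.null(n_trials))
    n_trials <- if (is.null(per_trial)) 1L else length(per_trial)
  structure(list(r_bar = r_bar, rho_bar = rho_bar, omega_g = omega_g,
                 per_trial = per_trial, n_trials = as.integer(n_trials),
                 sds = sds),
            class = "experiment_summary")
}

#' Synchronization-agreement cost (standard-model tuning)
#'
#' Weighted squared relative error between simulated and experimental
#' synchronization levels,
#' \deqn{J_s = \lambda \left(\frac{\bar r_{exp} - \bar r_{sim}}{\bar r_{exp}}\right)^2
#'   + (1-\lambda) \left(\frac{\bar\rho_{exp} - \bar\rho_{sim}}{\bar\rho_{exp}}\right)^2.}
#' The default \eqn{\lambda = 0.3} biases the fit toward agreement on the
#' frequency-coordination index.
#'
#' @param sim simulated summary (anything with `r_bar` and `rho_bar`, e.g. a
#'   [trial_summary()] or across-trial averages).
#' @param exp an [experiment_summary()] with nonzero `r_bar`, `rho_bar`.
#' @param lambda weight in `[0, 1]` on the order-parameter term.
#' @return Non-negative scalar; zero iff both quantities match exactly.
#' @export
cost_js <- function(sim, exp, lambda = 0.3) {
  stopifnot(lambda >= 0, lambda <= 1)
  if (exp$r_bar == 0 || exp$rho_bar == 0)
    stop("experimental r_bar and rho_bar must be nonzero")
  lambda * ((exp$r_bar - sim$r_bar) / exp$r_bar)^2 +
    (1 - lambda) * ((exp$rho_bar - sim$rho_bar) / exp$rho_bar)^2
}

#' Synchronization-and-frequency cost (extended-model tuning)
#'
#' [cost_js()] plus a squared relative error on the group oscillation
#' frequency, \eqn{J_m = J_s + ((\bar\omega_{exp} - \bar\omega_{sim}) /
#' \bar\omega_{exp})^2}; the added term scores a model's ability to capture
#' the slowed group frequency.
#'
#' @inheritParams cost_js
#' @return Non-negative scalar.
#' @export
cost_jm <- function(sim, exp, lambda = 0.3) {
  if (exp$omega_g == 0) stop("experimental omega_g must be nonzero")
  cost_js(sim, exp, lambda) +
    ((exp$omega_g - sim$omega_g) / exp$omega_g)^2
}

#' Pairwise experimental-vs-simulated trial cost
#'
#' The per-pair analogue of [cost_jm()], evaluated between one experimental
#' trial `e` and one simulated trial `l`:
#' \deqn{J^{e,l} = \left(\frac{\omega_e - \omega_l}{\omega_e}\right)^2
#'  + (1-\lambda)\left(\frac{\rho_e - \rho_l}{\rho_e}\right)^2
#'  + \lambda\left(\frac{r_e - r_l}{r_e}\right)^2.}
#' When both trials coincide with their set averages this reduces to
#' [cost_jm()].
#'
#' @param sim_trial,exp_trial [trial_summary()]-like objects with `r_bar`,
#'   `rho_bar`, `omega_g`; the experimental values must be nonzero.
#' @param lambda weight in `[0, 1]`.
#' @return Non-negative scalar.
#' @export
cost_pair <- function(sim_trial, exp_trial, lambda = 0.3) {
  stopifnot(lambda >= 0, lambda <= 1)
  if (exp_trial$omega_g == 0 || exp_trial$r_bar == 0 || exp_trial$rho_bar == 0)
    stop("experimental trial values must be nonzero")
  ((exp_trial$omega_g - sim_trial$omega_g) / exp_trial$omega_g)^2 +
    (1 - lambda) * ((exp_trial$rho_bar - sim_trial$rho_bar) / exp_trial$rho_bar)^2 +
    lambda * ((exp_trial$r_bar - sim_trial$r_bar) / exp_trial$r_bar)^2
}

#' Parameter grid for calibration
#'
#' Admissible parameter sets for each model family, with the study defaults:
#' coupling `c` in `[0, 2]` step 0.1 for every model; adaptive threshold
#' \eqn{\tilde r} in `[0.40, 0.95]` step 0.05 (0.40 is the expected order
#' parameter of 5 random phases, 0.95 has all phases within \eqn{\pi/3});
#' delay \eqn{\tau} in `[0.01, 0.35]` s step 0.01 (the sensorimotor
#' transmission-delay range); 10 simulations per grid point;
#' \eqn{\lambda = 0.30}.
#'
#' @param model_id model family to calibrate.
#' @param c_values,r_threshold_values,tau_values candidate parameter values.
#' @param n_sims_per_point simulated trials per grid point.
#' @param lambda_weight cost-function weight.
#' @return Object of class `grid_spec`.
#' @export
grid_spec <- function(model_id = c("standard", "adaptive", "weighted", "delayed"),
                      c_values = seq(0, 2, by = 0.1),
                      r_threshold_values = seq(0.40, 0.95, by = 0.05),
                      tau_values = seq(0.01, 0.35, by = 0.01),
                      n_sims_per_point = 10L, lambda_weight = 0.3) {
  model_id <- match.arg(model_id)
  stopifnot(length(c_values) >= 1L, n_sims_per_point >= 1L,
            lambda_weight >= 0, lambda_weight <= 1)
  structure(list(model_id = model_id, c_values = c_values,
                 r_threshold_values = r_threshold_values,
                 tau_values = tau_values,
                 n_sims_per_point = as.integer(n_sims_per_point),
                 lambda_weight = lambda_weight),
            class = "grid_spec")
}

# parameter tuples of a grid, one row per point
grid_points <- function(grid) {
  switch(grid$model_id,
    standard = data.frame(coupling_c = grid$c_values),
    weighted = data.frame(coupling_c = grid$c_values),
    adaptive = expand.grid(coupling_c = grid$c_values,
                           r_threshold = grid$r_threshold_values,
                           KEEP.OUT.ATTRS = FALSE),
    delayed = expand.grid(coupling_c = grid$c_values,
                          delay_tau = grid$tau_values,
                          KEEP.OUT.ATTRS = FALSE)
  )
}

# build the model_spec for one grid point
spec_for_point <- function(grid, point, include_delayed_self_coupling = TRUE) {
  switch(grid$model_id,
    standard = model_spec("standard", coupling_c = point$coupling_c),
    weighted = model_spec("weighted", coupling_c = point$coupling_c),
    adaptive = model_spec("adaptive", coupling_c = point$coupling_c,
                          r_threshold = point$r_threshold),
    delayed = model_spec("delayed", coupling_c = point$coupling_c,
                         delay_tau = point$delay_tau,
                         include_delayed_self_coupling =
                           include_delayed_self_coupling)
  )
}

#' Grid-search calibration of a model family
#'
#' For every parameter tuple of the grid, runs `n_sims_per_point` seeded
#' simulations (uniform random initial phases, per-agent Gaussian natural
#' frequencies), averages \eqn{(\bar r, \bar\rho, \bar\omega_g)} across the
#' simulated trials, and evaluates the tuning cost: [cost_js()] for the
#' standard model (whose locked frequency is structurally fixed at the mean
#' natural frequency), [cost_jm()] for the three extensions. Fully
#' reproducible given `master_seed`; per-point simulation failures are
#' recorded and the point marked invalid rather than aborting the search.
#'
#' Ties in the minimum cost break deterministically: smallest `coupling_c`,
#' then smallest second parameter.
#'
#' @param grid a [grid_spec()].
#' @param ensemble an [agent_ensemble()].
#' @param exp an [experiment_summary()] to calibrate against.
#' @param duration,dt trial length and integration step in seconds (defaults
#'   mirror the experiment: 30 s at 0.01 s).
#' @param window_w \eqn{\rho} window in samples.
#' @param discard_transient seconds discarded from trial summaries.
#' @param master_seed integer; per-simulation sub-seeds are derived from it.
#' @param include_delayed_self_coupling convention flag for the delayed model.
#' @return Object of class `cost_report`: list with `table` (one row per grid
#'   point: parameters, mean summaries, cost, failure count), `argmin` (best
#'   row), `per_point_trials` (list of per-simulation summary data frames),
#'   and the search settings.
#' @export
run_grid_search <- function(grid, ensemble, exp, duration = 30, dt = 0.01,
                            window_w = round(1 / dt), discard_transient = 0,
                            master_seed = 1L,
                            include_delayed_self_coupling = TRUE) {
  stopifnot(inherits(grid, "grid_spec"), inherits(ensemble, "agent_ensemble"),
            inherits(exp, "experiment_summary"))
  pts <- grid_points(grid)
  n_pts <- nrow(pts)
  res <- data.frame(pts, r_bar = NA_real_, rho_bar = NA_real_,
                    omega_g = NA_real_, cost = NA_real_, n_failed = 0L)
  per_point <- vector("list", n_pts)
  use_jm <- grid$model_id != "standard"

  for (p in seq_len(n_pts)) {
    spec <- spec_for_point(grid, pts[p, , drop = FALSE],
                           include_delayed_self_coupling)
    sims <- vector("list", grid$n_sims_per_point)
    failed <- 0L
    for (k in seq_len(grid$n_sims_per_point)) {
      seed_k <- derive_seed(master_seed, (p - 1L) * grid$n_sims_per_point + k)
      sims[[k]] <- tryCatch({
        traj <- simulate_model(spec, ensemble,
                               sim_config(dt = dt, duration = duration,
                                          seed = seed_k))
        s <- summarize_trial(traj, window_w, discard_transient)
        data.frame(sim = k, r_bar = s$r_bar, rho_bar = s$rho_bar,
                   omega_g = s$omega_g)
      }, error = function(e) {
        failed <<- failed + 1L
        NULL
      })
    }
    res$n_failed[p] <- failed
    sims <- do.call(rbind, sims)
    per_point[[p]] <- sims
    if (!is.null(sims) && nrow(sims) > 0L) {
      res$r_bar[p] <- mean(sims$r_bar)
      res$rho_bar[p] <- mean(sims$rho_bar)
      res$omega_g[p] <- mean(sims$omega_g)
      avg <- list(r_bar = res$r_bar[p], rho_bar = res$rho_bar[p],
                  omega_g = res$omega_g[p])
      res$cost[p] <- if (use_jm) cost_jm(avg, exp, grid$lambda_weight)
                     else cost_js(avg, exp, grid$lambda_weight)
    }
  }

  ord <- do.call(order, c(list(res$cost), as.list(pts), list(na.last = TRUE)))
  best <- ord[1L]
  if (is.na(res$cost[best])) stop("every grid point failed to simulate")
  structure(list(table = res, argmin = res[best, , drop = FALSE],
                 per_point_trials = per_point, model_id = grid$model_id,
                 lambda_weight = grid$lambda_weight,
                 n_sims_per_point = grid$n_sims_per_point,
                 master_seed = master_seed,
                 include_delayed_self_coupling = include_delayed_self_coupling),
            class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf("<cost_report> %s model, %d grid points, %d sims/point\n",
              x$model_id, nrow(x$table), x$n_sims_per_point))
  cat("argmin:\n")
  print(x$argmin, row.names = FALSE)
  invisible(x)
}
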