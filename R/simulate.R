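# Seeded Langevin simulation of working-memory trials. Integration is
# Euler-Maruyama in current space (where the injected noise is isotropic
# with diffusion coefficient D), expressed equivalently in gating space
# through the inverse coupling map. At the edges of the gating square the
# state is mirror-reflected in current coordinates (conormal reflection),
# matching the zero-flux boundary of the Fokker-Planck solver.

param_vector <- function(params) {
  c(params$a, params$b, params$d, params$gamma, params$tau_S,
    params$J11, params$J12, params$J21, params$J22, params$I0)
}

check_dt <- function(dt, params) {
  if (dt <= 0) stop("dt must be positive")
  if (dt >= params$tau_S / 10)
    warning(sprintf("dt = %g s is coarse relative to tau_S = %g s; expect discretization bias", dt, params$tau_S))
}

#' Simulate a single stochastic working-memory trial
#'
#' @param params a [circuit_params()] object (per-phase external currents
#'   come from the protocol, not from `params`).
#' @param protocol a [stimulus_protocol()] or preset name for
#'   [protocol_preset()].
#' @param D current-space diffusion coefficient (default 1.4e-2).
#' @param dt integration step in seconds (default 1e-4).
#' @param seed RNG seed; identical seeds reproduce trajectories exactly.
#' @param S0 initial gating state; defaults to the resting attractor of
#'   the stimulus-free circuit (or `c(0.1, 0.1)` if absent).
#' @param record_every record every this-many steps (default 10, i.e.
#'   1 ms at the default dt).
#' @return A data.frame of class `wm_trajectory` with columns `time`,
#'   `S1`, `S2`, `r1`, `r2` (firing rates from [fi_curve()]), `phase`.
#' @export
simulate_trial <- function(params, protocol = "trial", D = 1.4e-2,
                           dt = 1e-4, seed = 1, S0 = NULL,
                           record_every = 10L) {
  stopifnot(inherits(params, "circuit_params"))
  if (is.character(protocol)) protocol <- protocol_preset(protocol)
  stopifnot(inherits(protocol, "stimulus_protocol"))
  check_dt(dt, params)
  if (is.null(S0)) {
    fps <- classify_attractors(find_fixed_points(set_stimulus(params, 0, 0)))
    S0 <- if ("r" %in% fps$label) attractor_location(fps, "r") else c(0.1, 0.1)
  }
  set.seed(seed)
  raw <- cpp_simulate(param_vector(params), as.matrix(protocol),
                      S0[1], S0[2], D, dt, as.integer(record_every))
  S <- cbind(raw$S1, raw$S2)
  ph <- raw$phase
  Ie <- as.matrix(protocol)[ph, 2:3, drop = FALSE]
  I1 <-params$J11 * S[, 1] - params$J12 * S[, 2] + params$I0 + Ie[, 1]
  I2 <- params$J22 * S[, 2] - params$J21 * S[, 1] + params$I0 + Ie[, 2]
  out <- data.frame(time = raw$time, S1 = S[, 1], S2 = S[, 2],
                    r1 = fi_curve(I1, params), r2 = fi_curve(I2, params),
                    phase = ph)
  structure(out, class = c("wm_trajectory", "data.frame"),
            seed = seed, dt = dt, D = D, S0 = S0)
}

#' Monte-Carlo first passage times between attractor regions
#'
#' Repeated seeded trials from a start point until first entry into a
#' destination disk; the Monte-Carlo oracle for the backward-equation
#' solver [solve_mfpt()]. Censored trials (no arrival within `horizon`)
#' are reported separately and never averaged in silently.
#'
#' @param params a [circuit_params()] (stimulus currents included).
#' @param D diffusion coefficient.
#' @param start label of the start attractor (e.g. `"m1"`) or a length-2
#'   gating point.
#' @param destination a [destination_disk()], or an attractor label
#'   resolved against the circuit's stable fixed points.
#' @param n_trials number of trials.
#' @param dt integration step (s).
#' @param seed RNG seed.
#' @param horizon per-trial time limit in seconds (default `1e4 * tau_S`).
#' @param dest_radius disk radius when `destination` is a label.
#' @return An object of class `first_passage_sample`: list with `times`
#'   (uncensored passage times), `n_censored`, `mean`, `se`, `horizon`,
#'   `unreliable` (TRUE when more than half the trials censored).
#' @export
first_passage_times <- function(params, D = 1.4e-2, start = "m1",
                                destination = "r", n_trials = 500,
                                dt = 1e-4, seed = 1,
                                horizon = 1e4 * params$tau_S,
                                dest_radius = 0.02) {
  stopifnot(inherits(params, "circuit_params"))
  check_dt(dt, params)
  fps <- NULL
  resolve <- function(x) {
    if (is.character(x)) {
      if (is.null(fps))
        fps <<- classify_attractors(find_fixed_points(params))
      attractor_location(fps, x)
    } else x
  }
  start_pt <- resolve(start)
  if (inherits(destination, "destination")) dest <- destination
  else dest <- destination_disk(resolve(destination), dest_radius)
  set.seed(seed)
  times <- cpp_first_passage(param_vector(params),
                             params$I_ext1, params$I_ext2,
                             start_pt, dest$center, dest$radius,
                             as.integer(n_trials), D, dt, horizon)
  obs <- times[!is.na(times)]
  n_cens <- sum(is.na(times))
  out <- list(times = obs, n_censored = n_cens, n_trials = n_trials,
              mean = if (length(obs)) mean(obs) else NA_real_,
              se = if (length(obs) > 1) stats::sd(obs) / sqrt(length(obs))
                   else NA_real_,
              horizon = horizon, unreliable = n_cens > n_trials / 2,
              start = start_pt, destination = dest)
  if (out$unreliable)
    warning("more than half of the trials were censored; the mean passage time is unreliable")
  class(out) <- "first_passage_sample"
  out
}

#' @exportS3Method base::print
print.first_passage_sample <- function(x, ...) {
  cat(sprintf("<first_passage_sample> n = %d (%d censored at %g s): mean = %.4g s, se = %.3g s%s\n",
              x$n_trials, x$n_censored, x$horizon, x$mean, x$se,
              if (x$unreliable) " [UNRELIABLE]" else ""))
  invisible(x)
}

#' Occupancy density of switching transition paths
#'
#' Histograms the gating-plane occupancy of switching segments -- the
#' pieces of stochastic trajectories between the last exit from the
#' start-attractor disk and the first entry into the destination disk --
#' normalized to unit mass. Reproduces the transition-path densities used
#' to compare direct memory-to-memory switching with switching through
#' the intermediate state.
#'
#' @param params a [circuit_params()] (include the distractor stimulus for
#'   driven switching).
#' @param D diffusion coefficient.
#' @param start,destination attractor labels or gating points.
#' @param n_events number of switching events to collect.
#' @param grid_n histogram resolution per axis.
#' @param dt integration step (s).
#' @param seed RNG seed.
#' @param horizon per-trial time limit (s).
#' @param region_radius radius of the start/destination disks.
#' @return A list with `density` (grid_n x grid_n matrix summing to 1),
#'   `events`, and the region definitions.
#' @export
transition_path_density <- function(params, D = 1.4e-2, start = "m1",
                                    destination = "m2", n_events = 50,
                                    grid_n = 100, dt = 1e-4, seed = 1,
                                    horizon = 1e4 * params$tau_S,
                                    region_radius = 0.02) {
  stopifnot(inherits(params, "circuit_params"))
  fps <- NULL
  resolve <- function(x) {
    if (is.character(x)) {
      if (is.null(fps))
        fps <<- classify_attractors(find_fixed_points(params))
      attractor_location(fps, x)
    } else x
  }
  start_pt <- resolve(start); dest_pt <- resolve(destination)
  set.seed(seed)
  H <- cpp_path_histogram(param_vector(params),
                          params$I_ext1, params$I_ext2,
                          start_pt, region_radius, dest_pt, region_radius,
                          as.integer(n_events), D, dt, horizon,
                          as.integer(grid_n), as.integer(grid_n))
  events <- attr(H, "events")
  list(density = H / sum(H), events = events,
       start = start_pt, destination = dest_pt,
       region_radius = region_radius,
       grid = grid2d(grid_n))
}

#' Long-run occupancy histogram of a single trajectory
#'
#' @param params a [circuit_params()] object.
#' @param D diffusion coefficient.
#' @param T_total trajectory length (s).
#' @param grid_n histogram resolution per axis over the gating square.
#' @param dt integration step (s).
#' @param seed RNG seed.
#' @param S0 start point (defaults to the resting state).
#' @return A `grid_n` x `grid_n` matrix of cell probabilities summing to 1.
#' @export
occupancy_histogram <- function(params, D = 1.4e-2, T_total = 100,
                                grid_n = 50, dt = 1e-4, seed = 1,
                                S0 = c(0.05, 0.05)) {
  set.seed(seed)
  pos <- cpp_simulate_positions(param_vector(params),
                                params$I_ext1, params$I_ext2,
                                S0, D, dt, ceiling(T_total / dt), 1L)
  i <- pmin(pmax(floor(pos[, 1] * grid_n), 0), grid_n - 1) + 1
  j <- pmin(pmax(floor(pos[, 2] * grid_n), 0), grid_n - 1) + 1
  H <- matrix(0, grid_n, grid_n)
  tab <- table(factor(i + (j - 1) * grid_n, levels = seq_len(grid_n^2)))
  H[] <- as.numeric(tab)
  H / sum(H)
}
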