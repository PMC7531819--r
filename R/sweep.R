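# Sweep drivers reproducing the computational experiments: barrier
# heights, MFPT robustness/flexibility pairs and entropy production rates
# across the (J+, J-) coupling plane, plus D1 neuromodulation ladders and
# the tradeoff report.

#' Run configuration for landscape-flux sweeps
#'
#' Collects the baseline parameters, sweep grids, scenario definitions and
#' numerical settings of a sweep into a single validated object that can
#' be serialized to YAML ([write_config()]) and fully reproduces a run.
#'
#' @param params baseline [circuit_params()].
#' @param J_plus_values self-excitation values to sweep (nA).
#' @param J_minus_values mutual-inhibition values to sweep (nA).
#' @param grid_n Fokker-Planck grid resolution per axis.
#' @param D current-space diffusion coefficient.
#' @param dest_radius absorbing/destination disk radius (gating units).
#' @param stimulus_amplitude target/distractor amplitude (nA).
#' @param floor_rel relative density floor for the potential.
#' @param seed base seed recorded in provenance (the sweep itself is
#'   deterministic; the seed feeds any Monte-Carlo cross-checks).
#' @return A list of class `wm_config`.
#' @export
wm_config <- function(params = circuit_params(),
                      J_plus_values = seq(0.30, 0.37, by = 0.005),
                      J_minus_values = c(0.05, 0.055, 0.06),
                      grid_n = 100, D = 1.4e-2, dest_radius = 0.02,
                      stimulus_amplitude = 0.02, floor_rel = 1e-12,
                      seed = 1L) {
  stopifnot(inherits(params, "circuit_params"),
            grid_n >= 10, D > 0, dest_radius > 0, stimulus_amplitude >= 0)
  structure(list(params = params,
                 J_plus_values = J_plus_values,
                 J_minus_values = J_minus_values,
                 grid_n = as.integer(grid_n), D = D,
                 dest_radius = dest_radius,
                 stimulus_amplitude = stimulus_amplitude,
                 floor_rel = floor_rel, seed = as.integer(seed)),
            class = "wm_config")
}

with_couplings <- function(params, J_plus, J_minus) {
  circuit_params(a = params$a, b = params$b, d = params$d,
                 gamma = params$gamma, tau_S = params$tau_S,
                 J_plus = J_plus, J_minus = J_minus, I0 = params$I0)
}

# analysis of one (J+, J-) point: attractors, landscapes, barriers,
# tau/tau', epr with and without the distractor stimulus
sweep_point <- function(config, J_plus, J_minus) {
  p <- with_couplings(config$params, J_plus, J_minus)
  grid <- grid2d(config$grid_n)
  fps <- classify_attractors(find_fixed_points(p))
  has_m3 <- "m3" %in% fps$label
  dest0 <- if (has_m3) "m3" else "r"

  ls0 <- solve_steady_state(p, config$D, grid, floor_rel = config$floor_rel)
  bar0 <- barrier_height(ls0$U, grid, fps, "m1", dest0)
  ep0 <- entropy_production_rate(ls0)

  pd <- set_stimulus(p, 0, config$stimulus_amplitude)
  fpsd <- classify_attractors(find_fixed_points(pd))
  destd <- if ("m3" %in% fpsd$label) "m3" else "m2"
  lsd <- solve_steady_state(pd, config$D, grid, floor_rel = config$floor_rel)
  bard <- tryCatch(barrier_height(lsd$U, grid, fpsd, "m1", destd),
                   error = function(e) NULL)
  epd <- entropy_production_rate(lsd)

  f0 <- solve_mfpt(p, config$D, grid,
                   destination_disk(attractor_location(fps, dest0),
                                    config$dest_radius),
                   start = attractor_location(fps, "m1"))
  fd <- solve_mfpt(pd, config$D, grid,
                   destination_disk(attractor_location(fpsd, destd),
                                    config$dest_radius),
                   start = attractor_location(fpsd, "m1"))

  data.frame(J_plus = J_plus, J_minus = J_minus,
             n_attractors = sum(fps$stable), has_m3 = has_m3,
             labels = paste(sort(fps$label[fps$stable]), collapse = "+"),
             barrier = bar0$height,
             barrier_distractor = if (is.null(bard)) NA_real_ else bard$height,
             tau = f0$tau_start, tau_prime = fd$tau_start,
             tau_destination = dest0, tau_prime_destination = destd,
             epr = ep0$epr, epr_distractor = epd$epr,
             residual = ls0$residual, error = NA_character_)
}

#' Sweep the coupling plane
#'
#' For each \eqn{(J_+, J_-)} pair: locates and classifies attractors,
#' solves the stationary landscape with and without the distractor
#' stimulus, measures the `m1` escape barrier, the robustness and
#' flexibility MFPTs \eqn{(\tau, \tau')}, and the entropy production
#' rates. Failures at individual points are recorded in the `error`
#' column and do not abort the sweep. The result is fully determined by
#' the configuration.
#'
#' @param config a [wm_config()].
#' @param progress print one line per completed point.
#' @return A data.frame of class `sweep_record`, one row per
#'   \eqn{(J_+, J_-)}, with a `config` attribute.
#' @export
run_sweep <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "wm_config"))
  grid_pts <- expand.grid(J_plus = config$J_plus_values,
                          J_minus = config$J_minus_values)
  rows <- vector("list", nrow(grid_pts))
  for (k in seq_len(nrow(grid_pts))) {
    jp <- grid_pts$J_plus[k]; jm <- grid_pts$J_minus[k]
    rows[[k]] <- tryCatch(sweep_point(config, jp, jm),
      error = function(e) data.frame(
        J_plus = jp, J_minus = jm, n_attractors = NA_integer_,
        has_m3 = NA, labels = NA_character_, barrier = NA_real_,
        barrier_distractor = NA_real_, tau = NA_real_,
        tau_prime = NA_real_, tau_destination = NA_character_,
        tau_prime_destination = NA_character_, epr = NA_real_,
        epr_distractor = NA_real_, residual = NA_real_,
        error = conditionMessage(e)))
    if (progress)
      message(sprintf("[%d/%d] J+ = %.3f, J- = %.3f done",
                      k, nrow(grid_pts), jp, jm))
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    J_plus = numeric(0), J_minus = numeric(0),
    n_attractors = integer(0), has_m3 = logical(0),
    labels = character(0), barrier = numeric(0),
    barrier_distractor = numeric(0), tau = numeric(0),
    tau_prime = numeric(0), tau_destination = character(0),
    tau_prime_destination = character(0), epr = numeric(0),
    epr_distractor = numeric(0), residual = numeric(0),
    error = character(0))
  structure(out, class = c("sweep_record", "data.frame"), config = config)
}

#' D1 neuromodulation experiment
#'
#' Scales both couplings of the baseline circuit by [d1_factor()] at each
#' activation level and recomputes the robustness and flexibility MFPTs.
#'
#' @param config a [wm_config()] whose `params` hold the baseline
#'   couplings (J+ = 0.30, J- = 0.05 by default).
#' @param D1_levels vector of relative D1 activation levels.
#' @param progress print progress lines.
#' @return A data.frame with one row per level: `D1`, `factor`, the
#'   modulated couplings, `tau`, `tau_prime` and destinations.
#' @export
run_d1_experiment <- function(config, D1_levels = c(0.5, 1, 1.5),
                              progress = FALSE) {
  stopifnot(inherits(config, "wm_config"))
  rows <- lapply(D1_levels, function(lev) {
    pm <- modulate_params(config$params, lev)
    pair <- tryCatch(
      robustness_flexibility_pair(pm, config$D, grid2d(config$grid_n),
                                  dest_radius = config$dest_radius,
                                  amplitude = config$stimulus_amplitude),
      error = function(e) list(tau = NA_real_, tau_prime = NA_real_,
                               tau_destination = NA_character_,
                               tau_prime_destination = conditionMessage(e)))
    if (progress) message(sprintf("D1 = %.2f done", lev))
    data.frame(D1 = lev, factor = d1_factor(lev),
               J_plus = pm$J11, J_minus = pm$J12,
               tau = pair$tau, tau_prime = pair$tau_prime,
               tau_destination = pair$tau_destination,
               tau_prime_destination = pair$tau_prime_destination)
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  out
}

#' Robustness-flexibility-energy tradeoff report
#'
#' Summarizes a sweep into per-\eqn{J_-} curves parameterized by
#' \eqn{J_+}, marks the inflection (emergence of the intermediate state),
#' and evaluates the qualitative trend verdicts: barrier and \eqn{\tau}
#' increase with \eqn{J_-}; barrier and \eqn{\tau} rise then fall in
#' \eqn{J_+} with the turnover at the emergence threshold; epr increases
#' with both couplings in both scenarios; and at matched flexibility the
#' configuration with the intermediate state is the more robust one.
#'
#' @param records a `sweep_record` from [run_sweep()].
#' @param tau_prime_match_tol relative tolerance for "equal" flexibility
#'   when pairing configurations across the inflection.
#' @return A list of class `tradeoff_report` with `table` (the cleaned
#'   records), `inflection` (per-\eqn{J_-} emergence \eqn{J_+}),
#'   `verdicts` (named logicals), `matched_pairs`, and `n_excluded`.
#' @export
tradeoff_report <- function(records, tau_prime_match_tol = 0.15) {
  stopifnot(is.data.frame(records))
  bad <- !is.na(records$error) | is.na(records$tau) | is.na(records$epr)
  tab <- records[!bad, , drop = FALSE]
  n_excluded <- sum(bad)
  jms <- sort(unique(tab$J_minus))
  inflection <- vapply(jms, function(jm) {
    cur <- tab[tab$J_minus == jm, ]
    cur <- cur[order(cur$J_plus), ]
    hit <- which(cur$has_m3)
    if (length(hit)) cur$J_plus[min(hit)] else NA_real_
  }, numeric(1))
  names(inflection) <- format(jms)

  monotone_in_jm <- function(col) {
    if (length(jms) < 2) return(NA)
    common <- Reduce(intersect, lapply(jms, function(jm)
      tab$J_plus[tab$J_minus == jm]))
    if (!length(common)) return(NA)
    all(vapply(common, function(jp) {
      v <- vapply(jms, function(jm)
        tab[[col]][tab$J_minus == jm & tab$J_plus == jp][1], numeric(1))
      all(diff(v) > 0)
    }, logical(1)))
  }
  rise_fall <- function(col) {
    all(vapply(jms, function(jm) {
      cur <- tab[tab$J_minus == jm, ]
      cur <- cur[order(cur$J_plus), ]
      if (nrow(cur) < 3 || all(!cur$has_m3) || all(cur$has_m3)) return(NA)
      pk <- which.max(cur[[col]])
      emer <- min(which(cur$has_m3))
      # turnover at the emergence: peak right at or adjacent to threshold
      abs(pk - (emer - 1)) <= 1
    }, logical(1)), na.rm = TRUE)
  }
  epr_monotone <- all(vapply(jms, function(jm) {
    cur <- tab[tab$J_minus == jm, ]
    cur <- cur[order(cur$J_plus), ]
    all(diff(cur$epr) > 0) && all(diff(cur$epr_distractor) > 0)
  }, logical(1))) &&
    isTRUE(monotone_in_jm("epr")) && isTRUE(monotone_in_jm("epr_distractor"))

  # matched flexibility: pairs (no-m3, m3) with ~equal tau' at the same J-
  pairs <- list()
  for (jm in jms) {
    cur <- tab[tab$J_minus == jm, ]
    pre <- cur[!cur$has_m3, ]; post <- cur[cur$has_m3, ]
    for (i in seq_len(nrow(pre))) {
      if (!nrow(post)) break
      rel <- abs(post$tau_prime - pre$tau_prime[i]) / pre$tau_prime[i]
      j <- which.min(rel)
      if (rel[j] <= tau_prime_match_tol)
        pairs[[length(pairs) + 1L]] <- data.frame(
          J_minus = jm, J_plus_no_m3 = pre$J_plus[i],
          J_plus_m3 = post$J_plus[j],
          tau_no_m3 = pre$tau[i], tau_m3 = post$tau[j],
          tau_prime_no_m3 = pre$tau_prime[i],
          tau_prime_m3 = post$tau_prime[j])
    }
  }
  matched <- if (length(pairs)) do.call(rbind, pairs) else NULL
  verdicts <- c(
    barrier_monotone_in_Jminus = isTRUE(monotone_in_jm("barrier")),
    tau_monotone_in_Jminus = isTRUE(monotone_in_jm("tau")),
    barrier_rise_fall_in_Jplus = isTRUE(rise_fall("barrier")),
    tau_rise_fall_in_Jplus = isTRUE(rise_fall("tau")),
    epr_monotone_in_couplings = isTRUE(epr_monotone),
    matched_flexibility_m3_more_robust =
      if (is.null(matched)) NA else all(matched$tau_m3 > matched$tau_no_m3))
  structure(list(table = tab, inflection = inflection,
                 verdicts = verdicts, matched_pairs = matched,
                 n_excluded = n_excluded),
            class = "tradeoff_report")
}

#' @exportS3Method base::print
print.tradeoff_report <- function(x, ...) {
  cat("<tradeoff_report>\n")
  cat("  inflection J+ per J-:",
      paste(sprintf("%s -> %s", names(x$inflection),
                    format(x$inflection)), collapse = ", "), "\n")
  for (nm in names(x$verdicts))
    cat(sprintf("  %-38s %s\n", nm, x$verdicts[nm]))
  if (x$n_excluded) cat(sprintf("  (%d rows excluded)\n", x$n_excluded))
  invisible(x)
}
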