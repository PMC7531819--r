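# Entropy production rate and landscape-flux decomposition of the
# driving force. At the non-equilibrium steady state (temperature set to
# 1) the free-energy dissipation rate equals the entropy production rate
#   epr = integral of (J . D^-1 . J) / P over the state plane,
# and the drift decomposes as F = Jss/Pss - D grad U.

#' Entropy production rate of a steady-state landscape
#'
#' Cell-wise sum of \eqn{(J \cdot D^{-1} \cdot J)/P} times cell area over
#' cells above the density floor. Cells excluded by the floor are counted
#' and their probability mass reported, so the integral is never silently
#' truncated. The value is invariant (within discretization error) under
#' the linear change between gating and current coordinates.
#'
#' @param landscape a `landscape` from [solve_steady_state()] /
#'   [fpe_steady_state()].
#' @param floor_rel relative density floor for exclusion (defaults to the
#'   landscape's own floor).
#' @return An object of class `thermo_result`: list with `epr` (1/s),
#'   `excluded_mass`, `n_excluded`.
#' @export
entropy_production_rate <- function(landscape, floor_rel = landscape$floor) {
  stopifnot(inherits(landscape, "landscape"))
  P <- landscape$P
  area <- landscape$grid$hx * landscape$grid$hy
  Dinv <- solve(landscape$Dt)
  keep <- P > floor_rel * max(P)
  Jx <- landscape$Jx; Jy <- landscape$Jy
  quad <- Dinv[1, 1] * Jx^2 + 2 * Dinv[1, 2] * Jx * Jy + Dinv[2, 2] * Jy^2
  epr <- sum((quad[keep] / P[keep])) * area
  excluded_mass <- sum(P[!keep]) * area
  if (excluded_mass > 1e-6)
    warning(sprintf("density floor excludes %.2e of the probability mass from the epr integral", excluded_mass))
  structure(list(epr = epr, excluded_mass = excluded_mass,
                 n_excluded = sum(!keep)),
            class = "thermo_result")
}

#' @exportS3Method base::print
print.thermo_result <- function(x, ...) {
  cat(sprintf("<thermo_result> epr = %.6g per s (%d cells, %.2e mass excluded)\n",
              x$epr, x$n_excluded, x$excluded_mass))
  invisible(x)
}

#' Landscape-flux decomposition of the driving force
#'
#' Splits the deterministic drift into the gradient part
#' \eqn{-D \nabla U} and the flux part \eqn{J_{ss}/P_{ss}}, and reports
#' the pointwise residual \eqn{F - (J_{ss}/P_{ss} - D\nabla U)}, which
#' vanishes in the continuum and shrinks under grid refinement.
#'
#' @param landscape a `landscape` object.
#' @return A list of matrices `F_x`, `F_y` (drift), `grad_x`, `grad_y`
#'   (gradient component \eqn{-D\nabla U}), `flux_x`, `flux_y`
#'   (\eqn{J/P}), `resid_x`, `resid_y`, plus `median_rel_residual` over
#'   evaluated (unfloored, interior) cells and the excluded-cell count.
#' @export
decompose_force <- function(landscape) {
  stopifnot(inherits(landscape, "landscape"))
  g <- landscape$grid
  P <- landscape$P; U <- landscape$U
  Dt <- landscape$Dt
  pts <- grid_points(g)
  Fv <- landscape$drift_fn(pts)
  F_x <- matrix(Fv[, 1], g$nx, g$ny)
  F_y <- matrix(Fv[, 2], g$nx, g$ny)
  dUdx <- center_grad(U, g$hx, 1)
  dUdy <- center_grad(U, g$hy, 2)
  grad_x <- -(Dt[1, 1] * dUdx + Dt[1, 2] * dUdy)
  grad_y <- -(Dt[2, 1] * dUdx + Dt[2, 2] * dUdy)
  flux_x <- landscape$Jx / P
  flux_y <- landscape$Jy / P
  resid_x <- F_x - (flux_x + grad_x)
  resid_y <- F_y - (flux_y + grad_y)
  ok <- !is.na(resid_x) & !is.na(resid_y) & is.finite(resid_x) & is.finite(resid_y)
  ok[c(1, g$nx), ] <- FALSE; ok[, c(1, g$ny)] <- FALSE
  rel <- sqrt(resid_x[ok]^2 + resid_y[ok]^2) /
    pmax(sqrt(F_x[ok]^2 + F_y[ok]^2), 1e-12)
  list(F_x = F_x, F_y = F_y, grad_x = grad_x, grad_y = grad_y,
       flux_x = flux_x, flux_y = flux_y,
       resid_x = resid_x, resid_y = resid_y,
       median_rel_residual = stats::median(rel),
       n_excluded = sum(!ok))
}

# centered differences along margin 1 (x) or 2 (y); NA-propagating
center_grad <- function(Z, h, margin) {
  n <- dim(Z)[margin]
  G <- Z * NA_real_
  if (margin == 1) {
    G[2:(n - 1), ] <- (Z[3:n, ] - Z[1:(n - 2), ]) / (2 * h)
    G[1, ] <- (Z[2, ] - Z[1, ]) / h
    G[n, ] <- (Z[n, ] - Z[n - 1, ]) / h
  } else {
    G[, 2:(n - 1)] <- (Z[, 3:n] - Z[, 1:(n - 2)]) / (2 * h)
    G[, 1] <- (Z[, 2] - Z[, 1]) / h
    G[, n] <- (Z[, n] - Z[, n - 1]) / h
  }
  G
}

#' Trajectory-based estimator of the entropy production rate
#'
#' Long-run Langevin estimate \eqn{(1/T)\int (J/P)(x) \cdot D^{-1} \circ
#' dx} evaluated at Stratonovich midpoints along a simulated trajectory,
#' using the grid fields of a solved landscape. Serves as an independent
#' cross-check of the grid integral in [entropy_production_rate()].
#'
#' @param landscape a gating-frame `landscape` with `params` attached
#'   (i.e. from [solve_steady_state()]).
#' @param T_total trajectory length in seconds.
#' @param dt integration step (s).
#' @param seed RNG seed.
#' @param S0 start point (defaults to the landscape density maximum).
#' @return A list with `epr` (1/s) and the trajectory length used.
#' @export
trajectory_epr <- function(landscape, T_total = 200, dt = 1e-4, seed = 1,
                           S0 = NULL) {
  stopifnot(inherits(landscape, "landscape"),
            !is.null(landscape$params), landscape$frame == "gating")
  g <- landscape$grid
  if (is.null(S0)) {
    k <- which(landscape$P == max(landscape$P), arr.ind = TRUE)[1, ]
    S0 <- c(g$xc[k[1]], g$yc[k[2]])
  }
  n_steps <- ceiling(T_total / dt)
  set.seed(seed)
  path <- cpp_simulate_positions(param_vector(landscape$params), 0, 0,
                                 S0, landscape$D, dt, n_steps, 1L)
  vx_field <- landscape$Jx / landscape$P
  vy_field <- landscape$Jy / landscape$P
  mid <- (path[-1, , drop = FALSE] + path[-nrow(path), , drop = FALSE]) / 2
  dxs <- path[-1, , drop = FALSE] - path[-nrow(path), , drop = FALSE]
  vx <- interp_field(g, vx_field, mid)
  vy <- interp_field(g, vy_field, mid)
  Dinv <- solve(landscape$Dt)
  incr <- (Dinv[1, 1] * vx + Dinv[2, 1] * vy) * dxs[, 1] +
    (Dinv[1, 2] * vx + Dinv[2, 2] * vy) * dxs[, 2]
  list(epr = sum(incr) / (n_steps * dt), T_total = n_steps * dt)
}
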