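test_that("equilibrium gradient systems produce essentially no entropy", {
  k <- 1; D <- 2e-3
  g <- grid2d(100)
  ls <- fpe_steady_state(g, function(x) -k * sweep(x, 2, c(0.5, 0.5)),
                         D * diag(2))
  ep <- entropy_production_rate(ls)
  # baseline circuit epr is ~0.1 per s; detailed balance sits far below
  expect_lt(ep$epr, 1e-4 * 0.1)
})

test_that("manufactured rotational flux reproduces the closed-form epr", {
  # F = -k(x-x0) + omega * rot(x-x0) with sigma^2 = D/k leaves the isotropic
  # Gaussian stationary with J = rot * P; then epr = 2 omega^2 sigma^2 / D
  k <- 2; D <- 2e-3; om <- 1.5; x0 <- c(0.5, 0.5)
  g <- grid2d(150)
  drift <- function(x) {
    dx <- sweep(x, 2, x0)
    cbind(-k * dx[, 1] - om * dx[, 2], -k * dx[, 2] + om * dx[, 1])
  }
  ls <- fpe_steady_state(g, drift, D * diag(2))
  s2 <- D / k
  epr_exact <- 2 * om^2 * s2 / D
  ep <- entropy_production_rate(ls)
  expect_equal(ep$epr, epr_exact, tolerance = 0.02)
  # recovered flux matches the rotational term where the density lives
  pts <- grid_points(g)
  dx <- sweep(pts, 2, x0)
  Jx_exact <- matrix(-om * dx[, 2], 150, 150) * ls$P
  core <- ls$P > 0.05 * max(ls$P)
  expect_lt(max(abs(ls$Jx - Jx_exact)[core]) / max(abs(Jx_exact[core])), 0.05)
})

test_that("force decomposition recovers equilibrium and circuit structure", {
  # OU: gradient part carries the whole drift, flux part vanishes
  k <- 1; D <- 2e-3
  g <- grid2d(100)
  ls <- fpe_steady_state(g, function(x) -k * sweep(x, 2, c(0.5, 0.5)),
                         D * diag(2))
  dc <- decompose_force(ls)
  core <- ls$P > 0.05 * max(ls$P)
  Fmag <- sqrt(dc$F_x^2 + dc$F_y^2)
  expect_lt(max(sqrt(dc$flux_x^2 + dc$flux_y^2)[core]) / max(Fmag[core]),
            0.02)
  expect_lt(stats::median(abs(dc$grad_x - dc$F_x)[core] /
                          pmax(Fmag[core], 1e-9)), 0.02)
})

test_that("decomposition residual shrinks under grid refinement", {
  p <- baseline_params()
  res <- vapply(c(75, 150), function(n)
    decompose_force(solve_steady_state(p, D_NOISE, grid2d(n)))$median_rel_residual,
    numeric(1))
  expect_lt(res[2], 0.6 * res[1])
  expect_lt(res[2], 0.05)
})

test_that("the flux component dominates along the inter-memory channel at high J+", {
  p <- circuit_params(J_plus = 0.36)
  ls <- solve_steady_state(p, D_NOISE, grid2d(100))
  dc <- decompose_force(ls)
  # sample the barrier top of the m1 -> m3 transition channel, where the
  # gradient force stalls and only the rotational flux can carry the system
  fps <- classify_attractors(find_fixed_points(p))
  b <- barrier_height(ls$U, ls$grid, fps, "m1", "m3")
  g <- ls$grid
  i <- round((b$saddle[1] - g$xc[1]) / g$hx) + 1
  j <- round((b$saddle[2] - g$yc[1]) / g$hy) + 1
  flux_mag <- sqrt(dc$flux_x[i, j]^2 + dc$flux_y[i, j]^2)
  grad_mag <- sqrt(dc$grad_x[i, j]^2 + dc$grad_y[i, j]^2)
  expect_gt(flux_mag, grad_mag)
})

test_that("epr is invariant under the gating/current change of coordinates", {
  p <- baseline_params()
  eg <- entropy_production_rate(solve_steady_state(p, D_NOISE, grid2d(150)))$epr
  ec <- entropy_production_rate(solve_steady_state(p, D_NOISE,
                                                   current_grid(p, 150)))$epr
  expect_lt(abs(eg - ec) / eg, 0.03)
})

test_that("epr is stable under grid refinement", {
  p <- baseline_params()
  e1 <- entropy_production_rate(solve_steady_state(p, D_NOISE, grid2d(100)))$epr
  e2 <- entropy_production_rate(solve_steady_state(p, D_NOISE, grid2d(200)))$epr
  expect_lt(abs(e1 - e2) / e2, 0.03)
})

test_that("the trajectory estimator corroborates the grid epr integral", {
  p <- baseline_params()
  ls <- solve_steady_state(p, D_NOISE, grid2d(150))
  grid_epr <- entropy_production_rate(ls)$epr
  traj <- trajectory_epr(ls, T_total = 300, dt = 1e-4, seed = 3)
  expect_lt(abs(traj$epr - grid_epr) / grid_epr, 0.10)
})
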