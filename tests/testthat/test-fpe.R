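test_that("stationary solver reproduces the isotropic OU Gaussian exactly", {
  k <- 1; D <- 2e-3; x0 <- c(0.5, 0.5)
  g <- grid2d(100)
  ls <- fpe_steady_state(g, function(x) -k * sweep(x, 2, x0), D * diag(2))
  pts <- grid_points(g)
  s2 <- D / k
  Pex <- exp(-((pts[, 1] - x0[1])^2 + (pts[, 2] - x0[2])^2) / (2 * s2))
  Pex <- matrix(Pex, 100, 100)
  Pex <- Pex / (sum(Pex) * g$hx * g$hy)
  core <- Pex > 0.01 * max(Pex)
  expect_lt(max(abs(ls$P - Pex)[core] / Pex[core]), 0.02)
  expect_true(all(ls$P >= 0))
  expect_equal(sum(ls$P) * g$hx * g$hy, 1, tolerance = 1e-10)
  # equilibrium: flux negligible against the advective scale
  scale <- max(abs(k * 0.5) * max(Pex))
  expect_lt(max(sqrt(ls$Jx^2 + ls$Jy^2)), 1e-3 * scale)
})

test_that("stationary solver handles the anisotropic correlated tensor", {
  p <- baseline_params()
  Dt <- diffusion_tensor(p, D_NOISE, "gating")
  k <- 5; x0 <- c(0.5, 0.5)
  g <- grid2d(100)
  ls <- fpe_steady_state(g, function(x) -k * sweep(x, 2, x0), Dt)
  Sig <- Dt / k
  Si <- solve(Sig)
  pts <- grid_points(g)
  dx <- sweep(pts, 2, x0)
  q <- Si[1, 1] * dx[, 1]^2 + 2 * Si[1, 2] * dx[, 1] * dx[, 2] +
    Si[2, 2] * dx[, 2]^2
  Pex <- matrix(exp(-q / 2), 100, 100)
  Pex <- Pex / (sum(Pex) * g$hx * g$hy)
  core <- Pex > 0.01 * max(Pex)
  expect_lt(max(abs(ls$P - Pex)[core] / Pex[core]), 0.02)
  expect_true(all(ls$P >= 0))
})

test_that("potential transform obeys the uniform and rescaling identities", {
  P <- matrix(1 / 400, 20, 20)
  expect_equal(potential_from_density(P), matrix(log(400), 20, 20))
  set.seed(4)
  P2 <- matrix(rexp(400), 20, 20)
  dU <- potential_from_density(2 * P2) - potential_from_density(P2)
  expect_equal(max(dU) - min(dU), 0, tolerance = 1e-12)
  expect_error(potential_from_density(matrix(0, 5, 5)), "degenerate")
})

test_that("OU potential is quadratic over the central region", {
  k <- 1; D <- 2e-3
  g <- grid2d(100)
  ls <- fpe_steady_state(g, function(x) -k * sweep(x, 2, c(0.5, 0.5)),
                         D * diag(2))
  pts <- grid_points(g)
  r2 <- (pts[, 1] - 0.5)^2 + (pts[, 2] - 0.5)^2
  sel <- r2 < (3 * sqrt(D / k))^2 & !is.na(as.numeric(ls$U))
  y <- as.numeric(ls$U)[sel]
  fit <- stats::lm(y ~ r2[sel])
  rsq <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  expect_gt(rsq, 0.999)
  expect_equal(unname(stats::coef(fit)[2]), k / (2 * D), tolerance = 0.02)
})

test_that("baseline landscape is trimodal with peaks at the attractors", {
  p <- baseline_params()
  ls <- solve_steady_state(p, D_NOISE, grid2d(100))
  peaks <- landscape_maxima(ls, min_rel = 1e-4)
  expect_equal(nrow(peaks), 3)
  fps <- classify_attractors(find_fixed_points(p))
  st <- fps[fps$stable, ]
  for (k in seq_len(3)) {
    dmin <- min(sqrt((st$S1 - peaks$x[k])^2 + (st$S2 - peaks$y[k])^2))
    expect_lt(dmin, 0.05)
  }
})

test_that("a target stimulus removes the resting peak and m1 dominates", {
  p <- set_stimulus(baseline_params(), I_ext1 = 0.02)
  ls <- solve_steady_state(p, D_NOISE, grid2d(100))
  peaks <- landscape_maxima(ls, min_rel = 1e-3)
  # no peak left near the former resting state
  near_r <- sqrt((peaks$x - 0.05)^2 + (peaks$y - 0.05)^2) < 0.05
  expect_false(any(near_r))
  # the global maximum is the target-selective memory state
  expect_gt(peaks$x[1], 0.4)
  expect_lt(peaks$y[1], 0.2)
})

test_that("flux divergence vanishes at the discrete level for converged solves", {
  ls <- solve_steady_state(baseline_params(), D_NOISE, grid2d(80))
  area <- ls$grid$hx * ls$grid$hy
  expect_lt(sum(abs(ls$div_J)) * area, 1e-8)
})

test_that("transient evolution conserves mass and relaxes onto the steady state", {
  p <- baseline_params()
  g <- grid2d(60)
  Dt <- diffusion_tensor(p, D_NOISE, "gating")
  dfn <- wmflux:::circuit_drift_fn(p, "gating")
  ls <- fpe_steady_state(g, dfn, Dt)
  # stationarity: Pss is a fixed point of the evolution
  P1 <- evolve_density(ls$P, g, dfn, Dt, t = 1, dt = 0.25)
  expect_lt(0.5 * sum(abs(P1 - ls$P)) * g$hx * g$hy, 1e-6)
  # delta start near the resting state: mass conserved, L1 distance shrinks
  P0 <- matrix(0, 60, 60)
  P0[4, 4] <- 1
  out <- evolve_density(P0, g, dfn, Dt, t = 40, dt = 0.5,
                        save_times = c(2, 10, 40))
  expect_true(all(abs(out$mass - 1) < 1e-10))
  l1 <- vapply(out$densities, function(Pt)
    0.5 * sum(abs(Pt - ls$P)) * g$hx * g$hy, numeric(1))
  expect_true(all(diff(l1) < 0))
  expect_lt(l1[3], 0.02)
})

test_that("current-frame solve matches the gating frame after pullback", {
  p <- baseline_params()
  lg <- solve_steady_state(p, D_NOISE, grid2d(200))
  lc <- solve_steady_state(p, D_NOISE, current_grid(p, 200))
  lp <- landscape_to_gating(lc, grid2d(200))
  dU <- lp$U - lg$U
  core <- !is.na(dU) & lg$P > 1e-4 * max(lg$P)
  dev <- abs(dU[core] - stats::median(dU[core]))
  expect_lt(stats::quantile(dev, 0.99), 0.05)
})
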