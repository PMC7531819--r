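test_that("backward solver matches the 1-D quadrature formula", {
  # drift acts only along x, so the passage time into the strip x <= a
  # reduces to the classical double-integral expression
  k <- 4; D <- 0.02; xc <- 0.6; a <- 0.3
  g <- grid2d(200)
  drift <- function(x) cbind(-k * (x[, 1] - xc), 0)
  mask <- matrix(rep(g$xc <= a, times = g$ny), g$nx, g$ny)
  f <- mfpt_solve(g, drift, D * diag(2), mask)
  tau_pde <- mfpt_at(f, c(xc, 0.5))
  a_eff <- max(g$xc[g$xc <= a])   # discrete absorbing interface (tau = 0
  phi <- function(y) k * (y - xc)^2 / 2     # at the last absorbing center)
  inner <- function(y) vapply(y, function(yy)
    stats::integrate(function(z) exp(-phi(z) / D), yy, 1)$value, numeric(1))
  tau_exact <- stats::integrate(function(y)
    exp(phi(y) / D) / D * inner(y), a_eff, xc)$value
  expect_equal(tau_pde, tau_exact, tolerance = 0.02)
})

test_that("passage time vanishes on the absorbing set", {
  p <- baseline_params()
  fps <- classify_attractors(find_fixed_points(p))
  r <- attractor_location(fps, "r")
  f <- solve_mfpt(p, D_NOISE, grid2d(100), destination_disk(r))
  expect_equal(mfpt_at(f, r), 0, tolerance = 1e-10)
  expect_true(all(f$tau >= 0))
  expect_error(solve_mfpt(p, D_NOISE, grid2d(100), destination_disk(r),
                          start = r + c(0.005, 0)), "inside the absorbing")
})

test_that("PDE passage time agrees with seeded Monte-Carlo trials", {
  p <- baseline_params()
  fps <- classify_attractors(find_fixed_points(p))
  m1 <- attractor_location(fps, "m1")
  r <- attractor_location(fps, "r")
  f <- solve_mfpt(p, D_NOISE, grid2d(150), destination_disk(r), start = m1)
  mc <- first_passage_times(p, D_NOISE, start = "m1", destination = "r",
                            n_trials = 400, dt = 1e-4, seed = 101,
                            horizon = 200)
  expect_equal(mc$n_censored, 0)
  expect_lt(abs(mc$mean - f$tau_start), 3 * mc$se)
})

test_that("absorbing-disk radius is a weak lever in the small-noise regime", {
  p <- circuit_params(J_plus = 0.33)
  D <- 0.7e-2
  fps <- classify_attractors(find_fixed_points(p))
  m1 <- attractor_location(fps, "m1"); r <- attractor_location(fps, "r")
  g <- grid2d(100)
  t1 <- solve_mfpt(p, D, g, destination_disk(r, 0.02), start = m1)$tau_start
  t2 <- solve_mfpt(p, D, g, destination_disk(r, 0.01), start = m1)$tau_start
  expect_lt(abs(t2 - t1) / t1, 0.10)
})

test_that("escape slows as the noise is reduced", {
  p <- circuit_params(J_plus = 0.33)
  fps <- classify_attractors(find_fixed_points(p))
  m1 <- attractor_location(fps, "m1"); r <- attractor_location(fps, "r")
  g <- grid2d(100)
  taus <- vapply(c(2e-2, 1.4e-2, 1e-2), function(Dv)
    solve_mfpt(p, Dv, g, destination_disk(r), start = m1)$tau_start,
    numeric(1))
  expect_true(all(diff(taus) > 0))
})

test_that("robustness and flexibility pair follows the destination conventions", {
  pair <- robustness_flexibility_pair(baseline_params(), D_NOISE, grid2d(100))
  expect_equal(pair$tau_destination, "r")       # no m3 at baseline
  expect_equal(pair$tau_prime_destination, "m2")
  expect_lt(pair$tau_prime, pair$tau)           # the stimulus destabilizes m1
  pair36 <- robustness_flexibility_pair(circuit_params(J_plus = 0.36),
                                        D_NOISE, grid2d(100))
  expect_equal(pair36$tau_destination, "m3")    # switch at the emergence
})

test_that("log passage time tracks barrier height across the coupling sweep", {
  jps <- seq(0.30, 0.34, by = 0.01)
  rows <- vapply(jps, function(jp) {
    p <- circuit_params(J_plus = jp)
    fps <- classify_attractors(find_fixed_points(p))
    ls <- solve_steady_state(p, D_NOISE, grid2d(80))
    b <- barrier_height(ls$U, ls$grid, fps, "m1", "r")$height
    tau <- solve_mfpt(p, D_NOISE, grid2d(80),
                      destination_disk(attractor_location(fps, "r")),
                      start = attractor_location(fps, "m1"))$tau_start
    c(b, log(tau))
  }, numeric(2))
  expect_gt(stats::cor(rows[1, ], rows[2, ], method = "spearman"), 0.99)
})
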