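test_that("baseline circuit holds resting plus two mirror-image memory states", {
  fps <- classify_attractors(find_fixed_points(baseline_params()))
  st <- fps[fps$stable, ]
  expect_equal(nrow(st), 3)
  expect_setequal(st$label, c("r", "m1", "m2"))
  m1 <- attractor_location(fps, "m1")
  m2 <- attractor_location(fps, "m2")
  expect_equal(m1, rev(m2), tolerance = 1e-7)
  r <- attractor_location(fps, "r")
  expect_equal(r[1], r[2], tolerance = 1e-7)
  expect_true(all(r < 0.1))
})

test_that("strong self-excitation creates the both-active intermediate state", {
  fps <- classify_attractors(find_fixed_points(circuit_params(J_plus = 0.37)))
  expect_true("m3" %in% fps$label)
  m3 <- attractor_location(fps, "m3")
  expect_true(all(m3 > 0.35))
})

test_that("a target stimulus destroys the resting state", {
  p <- set_stimulus(baseline_params(), I_ext1 = 0.02)
  fps <- classify_attractors(find_fixed_points(p))
  expect_false("r" %in% fps$label[fps$stable])
  expect_true("m1" %in% fps$label)
})

test_that("duplicate labels raise an error instead of silent mislabeling", {
  fps <- find_fixed_points(baseline_params())
  expect_error(classify_attractors(fps, threshold = 0.9), "same label")
})

test_that("minimax barrier agrees with the exhaustive sublevel-set oracle", {
  set.seed(42)
  g <- grid2d(30)
  for (rep in 1:4) {
    # random smooth surface from a few Fourier modes
    pts <- grid_points(g)
    U <- matrix(0, 30, 30)
    for (k in 1:5) {
      fx <- sample(1:3, 1); fy <- sample(1:3, 1)
      U <- U + matrix(runif(1, -1, 1) *
        sin(2 * pi * fx * pts[, 1] + runif(1, 0, 2 * pi)) *
        sin(2 * pi * fy * pts[, 2] + runif(1, 0, 2 * pi)), 30, 30)
    }
    src <- c(sample(1:30, 1), sample(1:30, 1))
    tgt <- c(sample(1:30, 1), sample(1:30, 1))
    mm <- wmflux:::minimax_flood(U, 30, 30, src, tgt)
    expect_true(mm$connected)
    expect_equal(mm$value, brute_minimax(U, src, tgt), tolerance = 1e-12)
  }
})

test_that("symmetric landscapes give equal escape barriers for both memories", {
  p <- circuit_params(J_plus = 0.33)
  ls <- solve_steady_state(p, D_NOISE, grid2d(100))
  fps <- classify_attractors(find_fixed_points(p))
  b1 <- barrier_height(ls$U, ls$grid, fps, "m1", "r")
  b2 <- barrier_height(ls$U, ls$grid, fps, "m2", "r")
  expect_gt(b1$height, 0)
  expect_equal(b1$height, b2$height, tolerance = 0.05)
})

test_that("escape barriers deepen with self-excitation before m3 emerges", {
  heights <- vapply(c(0.30, 0.32, 0.34), function(jp) {
    p <- circuit_params(J_plus = jp)
    ls <- solve_steady_state(p, D_NOISE, grid2d(80))
    fps <- classify_attractors(find_fixed_points(p))
    barrier_height(ls$U, ls$grid, fps, "m1", "r")$height
  }, numeric(1))
  expect_true(all(diff(heights) > 0))
})

test_that("stable fixed points sit near potential minima at the working noise", {
  p <- baseline_params()
  ls <- solve_steady_state(p, D_NOISE, grid2d(100))
  fps <- classify_attractors(find_fixed_points(p))
  peaks <- landscape_maxima(ls, min_rel = 1e-4)
  st <- fps[fps$stable, ]
  for (k in seq_len(nrow(st))) {
    dmin <- min(sqrt((peaks$x - st$S1[k])^2 + (peaks$y - st$S2[k])^2))
    expect_lt(dmin, 0.05)
  }
})

test_that("intermediate-state scan finds the threshold and honors its range", {
  thr <- intermediate_state_threshold(baseline_params(), J_minus = 0.05,
                                      J_plus_range = c(0.34, 0.36),
                                      step = 0.005)
  expect_true(thr$found)
  expect_equal(thr$threshold, 0.35, tolerance = thr$step + 1e-12)
  none <- intermediate_state_threshold(baseline_params(), J_minus = 0.05,
                                       J_plus_range = c(0.30, 0.32),
                                       step = 0.005)
  expect_false(none$found)
  expect_true(is.na(none$threshold))
})

test_that("stronger mutual inhibition delays the emergence of m3", {
  t05 <- intermediate_state_threshold(baseline_params(), 0.05,
                                      c(0.34, 0.37), 0.005)
  t06 <- intermediate_state_threshold(baseline_params(), 0.06,
                                      c(0.34, 0.37), 0.005)
  expect_true(t05$found && t06$found)
  expect_gte(t06$threshold, t05$threshold)
})
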