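test_that("f-I curve evaluates correctly, including the removable singularity", {
  p <- baseline_params()
  # at aI = b the limit is 1/d
  expect_equal(fi_curve(p$b / p$a, p), 1 / p$d, tolerance = 1e-10)
  # frozen direct-evaluation oracles
  expect_equal(fi_curve(0.5, p), 27.4289560754, tolerance = 1e-9)
  expect_equal(fi_curve(0, p), 6.46008092563e-06, tolerance = 1e-6)
  expect_error(fi_curve(NaN, p), "non-finite")
})

test_that("f-I curve is strictly increasing and C1 across the singularity", {
  p <- baseline_params()
  I <- seq(0.2, 0.8, length.out = 4001)       # brackets b/a = 0.4
  r <- fi_curve(I, p)
  expect_true(all(diff(r) > 0))
  # finite-difference slope is continuous through I = b/a
  slope <- diff(r) / diff(I)
  i0 <- which.min(abs(I - p$b / p$a))
  local <- slope[(i0 - 20):(i0 + 20)]
  expect_lt(max(abs(diff(local))), 0.05 * max(local))
  # analytic derivative matches finite differences
  mid <- (I[-1] + I[-length(I)]) / 2
  expect_equal(wmflux:::fi_curve_deriv(mid, p), slope, tolerance = 1e-4)
})

test_that("gating<->current maps are mutually inverse and hit printed values", {
  p <- baseline_params()
  expect_equal(currents_from_gating(c(0, 0), p), c(0.31, 0.31))
  expect_equal(currents_from_gating(c(1, 0), p), c(0.61, 0.26))
  set.seed(1)
  S <- matrix(runif(200), ncol = 2)
  back <- gating_from_currents(currents_from_gating(S, p), p)
  expect_lt(max(abs(S - back)), 1e-12)
  expect_error(coupling_map(circuit_params(J11 = 0.1, J22 = 0.1,
                                           J12 = 0.1, J21 = 0.1)),
               "singular")
})

test_that("gating drift respects exchange symmetry and grows from silence", {
  p <- baseline_params()
  s <- seq(0.05, 0.95, by = 0.1)
  d <- drift_gating(cbind(s, s), p)
  expect_equal(d[, 1], d[, 2])
  d0 <- drift_gating(c(0, 0), p)
  expect_true(all(d0 > 0))  # background rate ~0.59 Hz drives gating up
  # zero drift at every fixed point
  fps <- find_fixed_points(p)
  for (k in seq_len(nrow(fps)))
    expect_lt(max(abs(drift_gating(c(fps$S1[k], fps$S2[k]), p))), 1e-8)
})

test_that("current-frame drift is the conjugate of the gating drift", {
  p <- baseline_params()
  cm <- coupling_map(p)
  set.seed(2)
  S <- matrix(runif(100), ncol = 2)
  I <- currents_from_gating(S, p)
  FI <- drift_current(I, p)
  FS <- drift_gating(S, p)
  expect_equal(FI, FS %*% t(cm$M), tolerance = 1e-12)
})

test_that("drift Jacobian matches finite differences", {
  p <- baseline_params()
  set.seed(3)
  for (k in 1:5) {
    S <- runif(2, 0.05, 0.95)
    J <- drift_jacobian(S, p)
    h <- 1e-6
    Jfd <- cbind((drift_gating(S + c(h, 0), p) - drift_gating(S - c(h, 0), p)) / (2 * h),
                 (drift_gating(S + c(0, h), p) - drift_gating(S - c(0, h), p)) / (2 * h))
    expect_equal(J, Jfd, tolerance = 1e-5)
  }
})

test_that("D1 modulation factor is calibrated, monotone and bounded", {
  expect_equal(d1_factor(1), 1, tolerance = 1e-12)
  expect_equal(d1_factor(0), 0.885621849362, tolerance = 1e-9)
  expect_equal(d1_factor(50), 1.0544862758, tolerance = 1e-6)  # saturation
  lv <- seq(0, 3, by = 0.05)
  expect_true(all(diff(d1_factor(lv)) > 0))
  Ce <- 1 / (1 + 0.2 / (1 + exp(-0.8)))
  expect_true(all(d1_factor(lv) > Ce & d1_factor(lv) < 1.2 * Ce))
  expect_error(d1_factor(-0.1), "non-negative")
  # common multiplicative factor preserves the J+/J- ratio
  pm <- modulate_params(baseline_params(), 1.4)
  expect_equal(pm$J11 / pm$J12, 0.30 / 0.05, tolerance = 1e-12)
})

test_that("stimulus protocol presets carry the standard amplitudes", {
  pr <- protocol_preset("loading")
  expect_equal(pr$I_ext1, 0.02)
  expect_equal(pr$I_ext2, 0)
  pr2 <- protocol_preset("distractor")
  expect_equal(pr2$I_ext2, 0.02)
  expect_error(stimulus_protocol(data.frame(duration = -1, I_ext1 = 0,
                                            I_ext2 = 0)), "positive")
  expect_error(stimulus_protocol(data.frame(duration = 1, I_ext1 = -0.1,
                                            I_ext2 = 0)), "non-negative")
})
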