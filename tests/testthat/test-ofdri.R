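fs <- 100

test_that("trapezoidal integration is exact for constant and linear inputs", {
  # constant acceleration, closed form
  a <- rep(1, 101)
  v <- integrate_forward(a, fs, v0 = 0)
  expect_equal(v[1], 0)
  expect_equal(v[101], 1.0, tolerance = 1e-12)

  # linear integrand: trapezoid exact
  t <- seq(0, 1, by = 1 / fs)
  v2 <- integrate_forward(2 * t, fs, v0 = 0)
  expect_equal(v2[101], 1.0, tolerance = 1e-4)

  # zero acceleration preserves the initial condition
  expect_equal(integrate_forward(rep(0, 50), fs, v0 = 0.5), rep(0.5, 50))

  expect_error(integrate_forward(1, fs), "too few")
})

test_that("reverse integration anchors the endpoint and mirrors forward", {
  expect_equal(integrate_reverse(rep(0, 50), fs, v_end = 0.8), rep(0.8, 50))

  a <- rep(1, 101)
  vr <- integrate_reverse(a, fs, v_end = 1.0)
  expect_equal(vr[1], 0.0, tolerance = 1e-12)
  expect_equal(vr[101], 1.0)

  # anchored at the forward end value, reverse equals forward exactly
  set.seed(1)
  a2 <- rnorm(200)
  vf <- integrate_forward(a2, fs, v0 = 0.3)
  vr2 <- integrate_reverse(a2, fs, v_end = vf[200])
  expect_equal(vr2 - vr2[1], vf - vf[1], tolerance = 1e-12)
  expect_equal(vr2, vf, tolerance = 1e-12)
})

test_that("blending is a pointwise convex combination", {
  vd <- c(0, 1); vi <- c(1, 0)
  expect_equal(blend_velocity(vd, vi, 1), vd)
  expect_equal(blend_velocity(vd, vi, 0), vi)
  expect_equal(blend_velocity(vd, vi, 0.5), c(0.5, 0.5))
  x <- rnorm(10)
  for (a in c(0, 0.3, 1)) expect_equal(blend_velocity(x, x, a), x)
  expect_error(blend_velocity(1:3, 1:4), "mismatch")
  expect_error(blend_velocity(vd, vi, 1.2), "alpha")
})

test_that("the velocity-error estimate is endpoint minus mean", {
  expect_equal(estimate_ev(rep(2.2, 30)), 0)
  expect_equal(estimate_ev(c(0, 1, 2)), 1)
  set.seed(2)
  v <- cumsum(rnorm(100))
  expect_equal(estimate_ev(v), v[100] - mean(v), tolerance = 1e-15)
})

test_that("linear drift correction matches the closed form", {
  t <- seq(0, 1, by = 0.01)
  v <- seq(0, 1, length.out = length(t))

  expect_equal(correct_drift(v, t, 0), v)

  # removing a full ramp zeroes the linear profile
  vc <- correct_drift(v, t, 1)
  expect_equal(vc, rep(0, length(t)), tolerance = 1e-12)

  # negative error raises the endpoint, start untouched
  vc2 <- correct_drift(v, t, -0.2)
  expect_equal(vc2[1], v[1])
  expect_equal(vc2[length(t)], v[length(t)] + 0.2, tolerance = 1e-12)

  # mean shifts by exactly -Ev/2 under uniform sampling
  set.seed(3)
  vr <- rnorm(101)
  ev <- 0.37
  expect_equal(mean(correct_drift(vr, t, ev)), mean(vr) - ev / 2,
               tolerance = 1e-12)

  expect_error(correct_drift(v, rep(0, length(t)), 1), "degenerate")
})

test_that("phase pipeline recovers constant speed and is alpha-invariant", {
  sc <- clean_trial(seed = 8L, speed_ripple = 0, impact_sharpness = 0.5,
                    yaw_amp_deg = 0)
  sim <- simulate_gait(sc)
  ev <- gait_events(sim$truth$ic_idx, sim$truth$ms_idx, sim$truth$side, fs)
  ph <- segment_phases(ev)
  vel <- phase_velocity_pipeline(sim$recording$acc_ap, ph, fs)
  steady <- vel[vel$step_index > 4 & vel$step_index <= max(vel$step_index) - 2, ]
  expect_true(all(abs(steady$v_mean - sc$mean_speed) / sc$mean_speed < 0.02))

  # drift-free signals: blending weight is immaterial
  for (a in c(0, 1)) {
    vel_a <- phase_velocity_pipeline(sim$recording$acc_ap, ph, fs, alpha = a)
    expect_equal(vel_a$v_mean, vel$v_mean, tolerance = 1e-9)
  }
})

test_that("drift correction removes most of an injected linear drift", {
  # one phase, fresh boundary condition, linearly growing spurious
  # acceleration (0.05 m/s^3): the linear ramp correction should cancel
  # most of its effect on the phase-mean velocity
  t <- seq(0, 0.5, by = 1 / fs)
  a_clean <- 1.5 * sin(2 * pi * 1.8 * t)
  one_phase <- function(acc, correct) {
    vd <- integrate_forward(acc, fs, v0 = 0)
    vi <- integrate_reverse(acc, fs, v_end = vd[length(vd)])
    vc <- blend_velocity(vd, vi, 0.5)
    if (correct) vc <- correct_drift(vc, t, estimate_ev(vc))
    mean(vc)
  }
  base <- one_phase(a_clean, TRUE)
  shift_cor <- abs(one_phase(a_clean + 0.05 * t, TRUE) - base)
  shift_unc <- abs(one_phase(a_clean + 0.05 * t, FALSE) -
                     one_phase(a_clean, FALSE))
  expect_lt(shift_cor, 0.25 * shift_unc + 1e-9)
})

test_that("the 3.5 Hz pre-filter passes gait and rejects impact-band noise", {
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  expect_equal(prefilter_acc(rep(2, 1000), fs), rep(2, 1000), tolerance = 1e-9)
  y1 <- prefilter_acc(sin(2 * pi * 1 * tt), fs)
  expect_gt(max(abs(y1[300:700])), 0.98)
  y10 <- prefilter_acc(sin(2 * pi * 10 * tt), fs)
  expect_lt(max(abs(y10[300:700])), 0.05)
})
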