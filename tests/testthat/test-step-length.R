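test_that("Froude number matches its closed form and dynamic similarity", {
  expect_equal(froude(0, 0.9), 0)
  expect_equal(froude(1.0, 1.0, 9.81), 0.1019368, tolerance = 1e-6)
  expect_equal(froude(sqrt(9.81), 1.0, 9.81), 1.0, tolerance = 1e-12)
  expect_error(froude(1, -0.5), "positive")

  # scaling lp by k and v by sqrt(k) leaves Fr unchanged
  set.seed(10)
  v <- runif(50, 0.3, 2); lp <- runif(50, 0.6, 1.1); k <- runif(50, 0.5, 2)
  expect_equal(froude(v * sqrt(k), lp * k), froude(v, lp), tolerance = 1e-14)
})

test_that("pendular length solves the inverted-pendulum relation (= v/C)", {
  expect_equal(pendular_length(0, 1, 2), 0)
  expect_equal(pendular_length(0.1019368, 1.0, 2.0, 9.81), 0.5,
               tolerance = 1e-6)
  set.seed(11)
  v <- runif(200, 0.1, 2.5); lp <- runif(200, 0.5, 1.2)
  C <- runif(200, 0.8, 5); g <- 9.81
  expect_equal(pendular_length(froude(v, lp, g), lp, C, g), v / C,
               tolerance = 1e-12)
  expect_error(pendular_length(0.1, 1, 0), "positive")
})

test_that("pelvic length is the signed tangent projection", {
  expect_equal(pelvic_length(0.15, 0), 0)
  expect_equal(pelvic_length(0.15, 20), 0.15 * tan(20 * pi / 180),
               tolerance = 1e-12)
  expect_equal(pelvic_length(0.15, 20), 0.0546, tolerance = 1e-4)
  # odd symmetry and strict monotonicity
  th <- seq(-89, 89, by = 0.5)
  L <- suppressWarnings(pelvic_length(0.15, th))
  expect_equal(suppressWarnings(pelvic_length(0.15, -th)), -L, tolerance = 1e-14)
  expect_true(all(diff(L) > 0))
  expect_error(pelvic_length(0.15, 90), "singularity")
  expect_warning(pelvic_length(0.15, 50), "45")
})

test_that("phase cadence is the reciprocal phase duration", {
  expect_equal(phase_cadence(0.5), 2.0)
  expect_equal(phase_cadence(1.0), 1.0)
  expect_error(phase_cadence(0), "positive")
  # consequence: the pendular term equals the phase displacement v * T
  v <- 1.2; Tp <- 0.31; lp <- 0.9
  expect_equal(pendular_length(froude(v, lp), lp, phase_cadence(Tp)),
               v * Tp, tolerance = 1e-12)
})

test_that("step length combines phases and conserves its decomposition", {
  anthro <- subject_anthro(0.9, 0.9, 0.15)
  e1 <- phase_kinematics(1.2, 0.25, 0, 0, 0.9)
  e2 <- phase_kinematics(1.2, 0.25, 0, 0, 0.9)
  est <- step_length(e1, e2, anthro, side = "left")
  expect_equal(est$L_total, 0.60, tolerance = 1e-9)
  expect_equal(est$L_pelvic_E1, 0)

  # with pelvic rotation the components still sum exactly
  e1y <- phase_kinematics(1.1, 0.28, -4, 4, 0.9)
  e2y <- phase_kinematics(1.3, 0.24, 4, -4, 0.9)
  esty <- step_length(e1y, e2y, anthro, side = "right")
  expect_equal(esty$L_total,
               esty$L_pendular_E1 + esty$L_pelvic_E1 +
                 esty$L_pendular_E2 + esty$L_pelvic_E2)
  # printed model form: pelvic term enters with a minus sign
  expect_equal(esty$L_pelvic_E1, -0.15 * tan(8 * pi / 180), tolerance = 1e-12)
  # stance side selects the leg length
  a2 <- subject_anthro(lp_right = 1.0, lp_left = 0.8, rp = 0.15)
  el <- step_length(e1, e2, a2, side = "left")
  er <- step_length(e1, e2, a2, side = "right")
  expect_equal(el$Fr_E1, froude(1.2, 0.8))
  expect_equal(er$Fr_E1, froude(1.2, 1.0))
})

test_that("zero-yaw constant-velocity step equals the velocity integral", {
  # isolate the integration + model stages with exact event times
  sc <- clean_trial(seed = 12L, speed_ripple = 0, impact_sharpness = 0.4,
                    yaw_amp_deg = 0, cadence_cv = 0)
  sim <- simulate_gait(sc)
  tr <- sim$truth
  ev <- gait_events(tr$ic_idx, tr$ms_idx, tr$side, sim$recording$fs)
  ph <- segment_phases(ev)
  vel <- phase_velocity_pipeline(sim$recording$acc_ap, ph, sim$recording$fs)
  steps <- estimate_steps(ph, vel, rep(0, sim$recording$n), sc$anthro,
                          sim$recording$fs)
  steps <- steps[!steps$trim, ]
  expect_gt(nrow(steps), 4)
  err <- steps$L_total - tr$step_lengths[steps$step_index]
  expect_lt(max(abs(err)), 2e-3)
})

test_that("estimation error grows with sensor noise", {
  # median absolute error versus truth across a noise ladder
  mdae <- vapply(c(0, 0.1, 0.3), function(na) {
    errs <- c()
    for (seed in 1:6) {
      sc <- gait_scenario(seed = seed, noise_acc = na)
      sim <- simulate_gait(sc)
      steps <- suppressWarnings(run_pipeline(sim$recording, sc$anthro))
      p <- pair_with_truth(steps, sim$truth)
      errs <- c(errs, abs(p$est - p$ref))
    }
    median(errs)
  }, numeric(1))
  expect_true(all(diff(mdae) > 0))
})
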