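test_that("imu_recording validates its invariants", {
  rec <- imu_recording(fs = 100, acc_ap = rnorm(200))
  expect_s3_class(rec, "imu_recording")
  expect_equal(rec$n, 200L)
  expect_equal(diff(rec$t), rep(0.01, 199), tolerance = 1e-12)

  expect_error(imu_recording(fs = 100, acc_ap = 1), "too short")
  expect_error(imu_recording(fs = -1, acc_ap = rnorm(10)), "fs")
  expect_error(imu_recording(t = c(0, 0.01, 0.5), fs = 100,
                             acc_ap = rnorm(3)), "non-uniform")
  expect_error(imu_recording(fs = 100, acc_ap = rnorm(10),
                             gyro_vert = rnorm(9)), "length")
  badq <- matrix(rep(c(2, 0, 0, 0), 10), ncol = 4, byrow = TRUE)
  expect_error(imu_recording(fs = 100, acc_ap = rnorm(10), quat = badq),
               "unit-norm")
})

test_that("subject anthropometrics guard plausibility", {
  a <- subject_anthro(0.9, 0.88, 0.15)
  expect_equal(a$g, 9.81)
  expect_error(subject_anthro(-1, 0.9, 0.1))
  expect_warning(subject_anthro(0.9, 0.9, 1.2), "rp")
})

test_that("recording CSV reader resolves dialects and rejects bad sampling", {
  t <- seq(0, 1.99, by = 0.01)
  df <- data.frame(t = t, ax = rnorm(200), ay = rnorm(200), az = rnorm(200),
                   gx = 0, gy = 0, gz = rnorm(200),
                   qw = 1, qx = 0, qy = 0, qz = 0)
  path <- write_fixture_csv(df)
  rec <- read_recording(path)
  expect_equal(rec$fs, 100)
  expect_equal(rec$acc_ap, df$az, tolerance = 1e-12)

  # unit conversion from g
  rec_g <- read_recording(path, imu_dialect(acc_unit = "g"))
  expect_equal(rec_g$acc_ap, df$az * 9.81, tolerance = 1e-12)

  # one-row file is degenerate
  p1 <- write_fixture_csv(df[1, ])
  expect_error(read_recording(p1), "too-short")

  # 0.5 s gap is non-uniform sampling
  dfg <- df; dfg$t[101:200] <- dfg$t[101:200] + 0.5
  pg <- write_fixture_csv(dfg)
  expect_error(read_recording(pg), "non-uniform")

  # missing channel column
  pm <- write_fixture_csv(df[setdiff(names(df), "az")])
  expect_error(read_recording(pm), "missing column")
})

test_that("recording write/read round-trips bit-for-float", {
  sim <- simulate_gait(clean_trial(seed = 4L, n_steps = 4L))
  path <- tempfile(fileext = ".csv")
  write_recording(sim$recording, path)
  back <- read_recording(path)
  expect_equal(back$acc_ap, sim$recording$acc_ap, tolerance = 1e-12)
  expect_equal(back$gyro_vert, sim$recording$gyro_vert, tolerance = 1e-12)
  expect_equal(unname(back$quat), unname(sim$recording$quat), tolerance = 1e-12)
})

test_that("step table writer round-trips and handles the empty table", {
  sim <- simulate_gait(gait_scenario(seed = 2L))
  steps <- suppressWarnings(run_pipeline(sim$recording, subject_anthro(0.88, 0.88, 0.15)))
  path <- tempfile(fileext = ".csv")
  write_steps(steps, path)
  back <- read_steps(path)
  expect_equal(nrow(back), nrow(steps))
  expect_equal(back$L_total, steps$L_total, tolerance = 1e-12)
  expect_equal(back$side, steps$side)

  expect_warning(write_steps(steps[0, ], path), "empty")
  expect_equal(nrow(read_steps(path)), 0L)
})

test_that("quaternion conversion follows the intrinsic Z-Y-X convention", {
  # identity
  e <- quat_to_euler(c(1, 0, 0, 0))
  expect_equal(unlist(e), c(roll = 0, pitch = 0, yaw = 0))

  # pure rotation about the vertical axis appears only in yaw
  for (ang in c(-60, -5, 12, 30, 85)) {
    q <- cbind(cos(ang * pi / 360), 0, 0, sin(ang * pi / 360))
    e <- quat_to_euler(q)
    expect_equal(e$yaw, ang, tolerance = 1e-9)
    expect_equal(e$roll, 0, tolerance = 1e-9)
    expect_equal(e$pitch, 0, tolerance = 1e-9)
  }

  # round trip euler -> quat -> euler
  ref <- data.frame(roll = c(5, -20, 7), pitch = c(0, 10, -45),
                    yaw = c(12, 170, -3))
  back <- quat_to_euler(euler_to_quat(ref$roll, ref$pitch, ref$yaw),
                        unwrap = FALSE)
  expect_equal(back$roll, ref$roll, tolerance = 1e-9)
  expect_equal(back$pitch, ref$pitch, tolerance = 1e-9)
  expect_equal(back$yaw, ref$yaw, tolerance = 1e-9)

  expect_error(quat_to_euler(c(0.9, 0, 0, 0)), "non-unit")
})

test_that("angle unwrapping removes wrap-around jumps", {
  ang <- seq(0, 4 * pi, by = 0.1)
  wrapped <- atan2(sin(ang), cos(ang))
  expect_equal(unwrap_angle(wrapped), ang, tolerance = 1e-12)
})
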