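#' Synthetic gait scenario
#'
#' Parameterizes the generator of lower-back IMU-like signals built on the
#' same double-inverted-pendulum kinematics the estimator assumes: forward
#' centre-of-mass velocity with per-step mean speeds (optionally
#' asymmetric), a smooth within-step braking/propulsion oscillation, an
#' impact transient locked to each initial contact, stride-frequency pelvic
#' yaw and roll, and vertical angular velocity as the yaw rate (so its sign
#' at contact encodes the stance limb). Exact ground-truth events and step
#' lengths are returned alongside the signals.
#'
#' @param n_steps number of complete steps (the recording holds
#'   `n_steps + 1` initial contacts).
#' @param cadence step rate, steps/s (physiologic range 0.5-4).
#' @param mean_speed mean forward speed, m/s.
#' @param speed_ripple within-step velocity oscillation amplitude as a
#'   fraction of `mean_speed`.
#' @param yaw_amp_deg transverse pelvic rotation amplitude, degrees
#'   (cohort observations stay within about +/-20).
#' @param roll_amp_deg frontal pelvic tilt amplitude, degrees.
#' @param asym_len left/right step-length ratio minus one.
#' @param asym_time left/right step-duration ratio minus one.
#' @param cadence_cv coefficient of variation of step duration (natural
#'   step-to-step timing variability; ~2% in steady adult gait). Set to 0
#'   for strictly periodic steps.
#' @param impact_sharpness scale of the initial-contact deceleration spike
#'   (1 = normal heel strike; small values emulate the soft heel strikes of
#'   shuffling gait that stress the detector).
#' @param noise_acc accelerometer white-noise sd, m/s^2.
#' @param noise_gyro gyroscope white-noise sd, rad/s.
#' @param noise_yaw_deg orientation (yaw/roll) white-noise sd, degrees.
#' @param fs sampling rate, Hz.
#' @param seed RNG seed.
#' @param anthro a [subject_anthro()].
#' @param startup if `TRUE` (default) the trial starts from standstill and
#'   the speed ramps up over the first two steps, so the first foot strike
#'   occurs at zero trunk velocity -- the condition under which the
#'   integration pipeline's zero initial velocity is exact. `FALSE` gives
#'   steady-state walking throughout (useful for isolated event-detection
#'   studies; note the trunk velocity at the first contact is then the
#'   walking speed, recorded in the ground truth as `v_ic0`).
#' @return object of class `gait_scenario`.
#' @export
gait_scenario <- function(n_steps = 12L, cadence = 1.8, mean_speed = 1.3,
                          speed_ripple = 0.08, yaw_amp_deg = 8,
                          roll_amp_deg = 4, asym_len = 0, asym_time = 0,
                          cadence_cv = 0.02,
                          impact_sharpness = 1, noise_acc = 0.1,
                          noise_gyro = 0.02, noise_yaw_deg = 0.3,
                          fs = 100, seed = 1L,
                          anthro = subject_anthro(0.88, 0.88, 0.15),
                          startup = TRUE) {
  if (cadence < 0.5 || cadence > 4) stop("cadence outside physiologic range [0.5, 4]")
  if (mean_speed <= 0) stop("mean_speed must be positive")
  if (abs(asym_len) >= 0.5 || abs(asym_time) >= 0.5) stop("|asym_*| must be < 0.5")
  if (yaw_amp_deg >= 90) stop("yaw amplitude must be < 90 degrees")
  if (n_steps < 1L) stop("need at least one step")
  structure(list(n_steps = as.integer(n_steps), cadence = cadence,
                 mean_speed = mean_speed, speed_ripple = speed_ripple,
                 yaw_amp_deg = yaw_amp_deg, roll_amp_deg = roll_amp_deg,
                 asym_len = asym_len, asym_time = asym_time,
                 cadence_cv = cadence_cv,
                 impact_sharpness = impact_sharpness, noise_acc = noise_acc,
                 noise_gyro = noise_gyro, noise_yaw_deg = noise_yaw_deg,
                 fs = fs, seed = as.integer(seed), anthro = anthro,
                 startup = startup),
            class = "gait_scenario")
}

# smootherstep ramp: 0 -> 1 with zero first and second derivatives at ends
.smootherstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^3 * (x * (6 * x - 15) + 10)
}

# piecewise-linear interpolation with linear extrapolation at both ends
.interp_extrap <- function(xk, yk, x) {
  y <- stats::approx(xk, yk, xout = x, rule = 2)$y
  m <- length(xk)
  lo <- x < xk[1]
  if (any(lo)) {
    s <- (yk[2] - yk[1]) / (xk[2] - xk[1])
    y[lo] <- yk[1] + s * (x[lo] - xk[1])
  }
  hi <- x > xk[m]
  if (any(hi)) {
    s <- (yk[m] - yk[m - 1]) / (xk[m] - xk[m - 1])
    y[hi] <- yk[m] + s * (x[hi] - xk[m])
  }
  y
}

#' Simulate a lower-back IMU gait recording with ground truth
#'
#' See [gait_scenario()] for the generative model. Event times are snapped
#' to the sample grid so ground-truth indices are exact. Ground-truth step
#' lengths follow the same geometric decomposition the estimator assumes:
#' the time integral of the generated forward velocity over the step plus
#' the pelvic tangent projection of the noise-free yaw change per phase
#' (printed model sign), so estimation error on clean signals isolates
#' pipeline error rather than model-versus-truth discrepancy.
#'
#' @param scenario a [gait_scenario()].
#' @return list with elements `recording` (an [imu_recording()]) and
#'   `truth` (class `gait_truth`): `ic_times`, `ic_idx`, `ms_times`,
#'   `ms_idx`, `side`, `step_lengths`, `step_sides`, `phase_velocities`
#'   (per-phase true mean velocities), `dyaw_E1`, `dyaw_E2`, `v`
#'   (true velocity series), `yaw_true`, `v_ic0`.
#' @export
simulate_gait <- function(scenario) {
  stopifnot(inherits(scenario, "gait_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  fs <- sc$fs
  n_ic <- sc$n_steps + 1L

  # --- event times -----------------------------------------------------
  # step k (k = 1..n_steps) runs from ic_k to ic_{k+1}; side of ic_k:
  # odd k -> left (vertical angular velocity positive just after contact)
  side_ic <- rep_len(c("left", "right"), n_ic)
  T0 <- 1 / sc$cadence
  dt_frac <- sc$asym_time / (2 + sc$asym_time)      # T_L/T_R = 1 + asym_time
  T_step <- ifelse(side_ic[-n_ic] == "left", T0 * (1 + dt_frac),
                   T0 * (1 - dt_frac))
  if (sc$cadence_cv > 0) {
    z <- pmin(pmax(stats::rnorm(sc$n_steps), -2.5), 2.5)
    T_step <- T_step * (1 + sc$cadence_cv * z)
  }
  lead <- if (sc$startup) 1.2 else 0.9 * T0
  # snap durations (not cumulative times) to the sample grid: cumulative
  # rounding would alternately stretch/shrink left and right steps
  T_step <- round(T_step * fs) / fs
  ic_t <- round(lead * fs) / fs + c(0, cumsum(T_step))
  ms_t <- round((ic_t[-n_ic] + T_step / 2) * fs) / fs
  # in steady mode end half a step after the last contact: the signal is
  # locally even about mid-step peaks, so reflective filter padding there
  # continues the gait waveform almost exactly
  tail <- (if (sc$startup) 0.9 else 0.5) * T_step[length(T_step)]
  n <- ceiling((ic_t[n_ic] + tail) * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  ic_idx <- round(ic_t * fs) + 1L
  ms_idx <- round(ms_t * fs) + 1L

  # --- gait phase theta(t): k*pi at ic_k, k*pi + pi/2 at ms_k ----------
  knots_t <- as.numeric(rbind(ic_t[-n_ic], ms_t))
  knots_th <- as.numeric(rbind((0:(sc$n_steps - 1)) * pi,
                               (0:(sc$n_steps - 1)) * pi + pi / 2))
  knots_t <- c(knots_t, ic_t[n_ic]); knots_th <- c(knots_th, sc$n_steps * pi)
  theta <- .interp_extrap(knots_t, knots_th, t)

  # --- forward velocity ------------------------------------------------
  ramp <- if (sc$startup) {
    ramp_end <- ic_t[min(3L, n_ic)]   # initiation ramp spans the two steps
    .smootherstep((t - ic_t[1]) / (ramp_end - ic_t[1]))   # the analysis trims
  } else rep(1, n)
  # braking/propulsion oscillation reaches full amplitude from the first
  # step; switched on smoothly just before the first contact
  rip_scale <- if (sc$startup) {
    .smootherstep((t - ic_t[1] + 0.15) / 0.15)
  } else rep(1, n)
  # per-side speed modulation at stride frequency; the mean of sin(theta)
  # over a step is +/- 2/pi, so solve the modulation depth for the target
  # length ratio after removing the share carried by duration asymmetry
  r_v <- (1 + sc$asym_len) / (1 + sc$asym_time)
  dv <- (pi / 2) * (r_v - 1) / (r_v + 1)
  v_env <- sc$mean_speed * (1 + dv * sin(theta)) * ramp
  v_rip <- -sc$speed_ripple * sc$mean_speed * rip_scale * sin(2 * theta)
  # impact: valley of depth impact_sharpness * 3 m/s^2 in acceleration at
  # each contact (Mexican-hat, zero net velocity change, ~60 ms FWHM)
  sig <- 0.060 / (2 * sqrt(2 * log(2)))
  A_imp <- sc$impact_sharpness * 3.0
  v_imp <- rep(0, n)
  for (k in seq_len(n_ic)) {
    u <- (t - ic_t[k]) / sig
    in_rng <- abs(u) < 8
    v_imp[in_rng] <- v_imp[in_rng] - A_imp * sig * u[in_rng] * exp(-u[in_rng]^2 / 2)
  }
  v <- v_env + v_rip + v_imp
  if (sc$startup) v <- v - v[1]        # quiet standing at the recording start

  # --- sensor channels -------------------------------------------------
  acc_true <- as.numeric(pracma::gradient(v, 1 / fs))
  # pelvic oscillation switches on with the first step (quiet standing before)
  ori_scale <- if (sc$startup)
    .smootherstep((t - ic_t[1]) / 0.25) else rep(1, n)
  yaw_true <- sc$yaw_amp_deg * sin(theta) * ori_scale
  roll_true <- sc$roll_amp_deg * sin(theta) * ori_scale
  gyro_true <- (pi / 180) * as.numeric(pracma::gradient(yaw_true, 1 / fs))

  acc <- acc_true + stats::rnorm(n, 0, sc$noise_acc)
  yaw <- yaw_true + stats::rnorm(n, 0, sc$noise_yaw_deg)
  roll <- roll_true + stats::rnorm(n, 0, sc$noise_yaw_deg)
  gyro <- gyro_true + stats::rnorm(n, 0, sc$noise_gyro)
  quat <- euler_to_quat(roll, 0, yaw)

  rec <- imu_recording(fs = fs, acc_ap = acc, gyro_vert = gyro, quat = quat,
                       roll_deg = roll, yaw_deg = yaw)

  # --- ground truth ----------------------------------------------------
  pend <- numeric(sc$n_steps)
  v_e1 <- numeric(sc$n_steps); v_e2 <- numeric(sc$n_steps)
  dy1 <- numeric(sc$n_steps); dy2 <- numeric(sc$n_steps)
  for (k in seq_len(sc$n_steps)) {
    i0 <- ic_idx[k]; im <- ms_idx[k]; i1 <- ic_idx[k + 1L]
    pend[k] <- pracma::trapz(t[i0:i1], v[i0:i1])
    v_e1[k] <- mean(v[i0:im]); v_e2[k] <- mean(v[im:i1])
    dy1[k] <- yaw_true[im] - yaw_true[i0]
    dy2[k] <- yaw_true[i1] - yaw_true[im]
  }
  rp <- sc$anthro$rp
  pelv <- -rp * tan(dy1 * pi / 180) - rp * tan(dy2 * pi / 180)
  truth <- structure(list(
    ic_times = ic_t, ic_idx = ic_idx, ms_times = ms_t, ms_idx = ms_idx,
    side = side_ic, step_sides = side_ic[-n_ic],
    step_lengths = pend + pelv, L_pendular = pend, L_pelvic = pelv,
    phase_velocities = data.frame(step_index = seq_len(sc$n_steps),
                                  v_E1 = v_e1, v_E2 = v_e2),
    dyaw_E1 = dy1, dyaw_E2 = dy2,
    v = v, yaw_true = yaw_true, v_ic0 = v[ic_idx[1]],
    scenario = sc), class = "gait_truth")
  list(recording = rec, truth = truth)
}

#' Named scenario presets
#'
#' Plausible synthetic gait phenotypes (amplitudes and rates are synthetic
#' defaults, not measured values): `healthy_adult`, `older_adult` (slower,
#' lower cadence), `asymmetric_mild` and `asymmetric_severe` (left/right
#' step-length and timing asymmetry with progressively softer heel
#' strikes), and `shuffling` (minimal impact transient -- the detector
#' stress case).
#'
#' @param seed seed stored into every preset.
#' @return named list of [gait_scenario()] objects.
#' @export
scenario_presets <- function(seed = 1L) {
  list(
    healthy_adult = gait_scenario(n_steps = 12L, cadence = 1.8,
                                  mean_speed = 1.3, yaw_amp_deg = 8,
                                  seed = seed),
    older_adult = gait_scenario(n_steps = 12L, cadence = 1.5,
                                mean_speed = 0.9, yaw_amp_deg = 6,
                                roll_amp_deg = 3, impact_sharpness = 0.8,
                                anthro = subject_anthro(0.84, 0.84, 0.14),
                                seed = seed),
    asymmetric_mild = gait_scenario(n_steps = 12L, cadence = 1.6,
                                    mean_speed = 1.0, asym_len = 0.10,
                                    asym_time = 0.05, impact_sharpness = 0.7,
                                    yaw_amp_deg = 12, seed = seed),
    asymmetric_severe = gait_scenario(n_steps = 12L, cadence = 1.3,
                                      mean_speed = 0.8, asym_len = 0.25,
                                      asym_time = 0.12, impact_sharpness = 0.4,
                                      yaw_amp_deg = 16, seed = seed),
    shuffling = gait_scenario(n_steps = 12L, cadence = 1.4, mean_speed = 0.7,
                              speed_ripple = 0.05, impact_sharpness = 0.15,
                              yaw_amp_deg = 5, roll_amp_deg = 2.5, seed = seed)
  )
}
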