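#' Froude number
#'
#' Dimensionless ratio of inertial to gravitational forces,
#' `Fr = V^2 / (g * Lp)`, which normalizes walking dynamics across body
#' sizes (dynamic similarity). Computed per sub-phase from that phase's
#' integrated average velocity, so braking and propulsion need not be
#' symmetric in time or speed.
#'
#' @param v phase-average forward velocity, m/s.
#' @param lp leg length, m.
#' @param g gravitational acceleration, m/s^2.
#' @return Froude number (>= 0).
#' @export
froude <- function(v, lp, g = 9.81) {
  if (any(lp <= 0) || any(g <= 0)) stop("lp and g must be positive")
  v^2 / (g * lp)
}

#' Pendular step-length component
#'
#' The inverted-pendulum relation `V = C * L` combined with the Froude
#' number `Fr = V^2/(g*Lp)` gives `L = sqrt(Fr * g * Lp) / C`, the
#' dimensionally consistent solution, algebraically equal to `V / C`.
#'
#' @param fr Froude number.
#' @param lp leg length, m.
#' @param C phase cadence, 1/s.
#' @param g gravitational acceleration, m/s^2.
#' @return pendular length, m.
#' @export
pendular_length <- function(fr, lp, C, g = 9.81) {
  if (any(C <= 0)) stop("cadence C must be positive")
  sqrt(pmax(fr, 0) * g * lp) / C
}

#' Pelvic step-length component
#'
#' Transverse pelvic rotation displaces the hip pivot forward (or backward)
#' by the tangent projection `rp * tan(yaw)`: seen from above, the pelvic
#' radius is the adjacent side and the longitudinal displacement the
#' opposite side of the rotation triangle. The full tangent (rather than a
#' small-angle form) keeps the projection valid at the larger compensatory
#' angles of impaired gait; cohort yaw ranges stay within about +/-20
#' degrees, far from the +/-90 degree singularities. Signed: negative yaw
#' change gives a negative contribution.
#'
#' @param rp pelvic radius, m.
#' @param yaw_deg pelvic rotation over the phase, degrees. Hard error at
#'   |yaw| >= 90 (tangent singularity); warning above 45.
#' @return signed length, m.
#' @export
pelvic_length <- function(rp, yaw_deg) {
  if (any(rp <= 0)) stop("rp must be positive")
  if (any(abs(yaw_deg) >= 90)) stop("|yaw| >= 90 degrees: tangent singularity")
  if (any(abs(yaw_deg) > 45)) warning("|yaw| > 45 degrees: implausible pelvic rotation")
  rp * tan(yaw_deg * pi / 180)
}

#' Phase cadence
#'
#' Cadence generalized to a sub-phase as the reciprocal of the phase
#' duration, `C = 1/T`. This is the unique choice under which the pendular
#' term `V/C` equals the kinematic displacement `V * T` of the phase.
#'
#' @param duration phase duration, s.
#' @return cadence, 1/s.
#' @export
phase_cadence <- function(duration) {
  if (any(duration <= 0)) stop("duration must be positive")
  1 / duration
}

#' Phase kinematics bundle
#'
#' @param v_mean phase-average forward velocity, m/s.
#' @param duration phase duration, s.
#' @param yaw_start,yaw_end filtered pelvic yaw at the phase boundaries,
#'   degrees.
#' @param lp stance-side leg length, m.
#' @return list of class `phase_kinematics`.
#' @export
phase_kinematics <- function(v_mean, duration, yaw_start, yaw_end, lp) {
  if (duration <= 0) stop("duration must be positive")
  if (lp <= 0) stop("lp must be positive")
  structure(list(v_mean = v_mean, duration = duration,
                 yaw_start = yaw_start, yaw_end = yaw_end, lp = lp),
            class = "phase_kinematics")
}

#' Step length from the double-inverted-pendulum model
#'
#' Combines the braking (E1) and propulsion (E2) phases of one step:
#' \deqn{L = \frac{\sqrt{Fr_{E1} g L_p}}{C_{E1}} - r_p\tan(\Delta yaw_{E1})
#'         + \frac{\sqrt{Fr_{E2} g L_p}}{C_{E2}} - r_p\tan(\Delta yaw_{E2})}
#' with phase-specific Froude numbers from the integrated phase-average
#' velocities, phase cadences `C = 1/T`, the stance side's leg length, and
#' the net change of the filtered yaw across each phase. `pelvic_sign`
#' flips the printed minus sign on the pelvic terms for sensors with the
#' opposite yaw convention; `yaw_stat` selects how the per-phase yaw is
#' summarized.
#'
#' @param e1,e2 [phase_kinematics()] for the braking and propulsion phase.
#' @param anthro a [subject_anthro()].
#' @param side stance side, `"left"` or `"right"` (selects `lp`; the `lp`
#'   stored in `e1`/`e2` is ignored when `anthro` is given).
#' @param pelvic_sign `-1` (printed model form) or `+1`.
#' @param yaw_stat `"delta"` (net change, default), `"end"`, or `"mean"`
#'   is expected to have been applied upstream when filling `yaw_start`,
#'   `yaw_end`; here `delta = yaw_end - yaw_start` is used.
#' @return one-row data.frame (class `step_estimate`) with the full
#'   decomposition: per-phase pendular and pelvic terms, Froude numbers,
#'   cadences, velocities, yaw changes, and `L_total`.
#' @export
step_length <- function(e1, e2, anthro, side = c("left", "right"),
                        pelvic_sign = -1, yaw_stat = "delta") {
  side <- match.arg(side)
  stopifnot(inherits(anthro, "subject_anthro"))
  lp <- if (side == "left") anthro$lp_left else anthro$lp_right
  g <- anthro$g
  comp <- function(e) {
    C <- phase_cadence(e$duration)
    fr <- froude(e$v_mean, lp, g)
    lpend <- sign(e$v_mean) * pendular_length(fr, lp, C, g)
    dyaw <- e$yaw_end - e$yaw_start
    lpelv <- pelvic_sign * pelvic_length(anthro$rp, dyaw)
    list(fr = fr, C = C, lpend = lpend, lpelv = lpelv, dyaw = dyaw)
  }
  c1 <- comp(e1); c2 <- comp(e2)
  out <- data.frame(side = side,
                    L_pendular_E1 = c1$lpend, L_pendular_E2 = c2$lpend,
                    L_pelvic_E1 = c1$lpelv, L_pelvic_E2 = c2$lpelv,
                    Fr_E1 = c1$fr, Fr_E2 = c2$fr,
                    C_E1 = c1$C, C_E2 = c2$C,
                    dyaw_E1 = c1$dyaw, dyaw_E2 = c2$dyaw,
                    v_E1 = e1$v_mean, v_E2 = e2$v_mean,
                    stringsAsFactors = FALSE)
  out$L_total <- out$L_pendular_E1 + out$L_pelvic_E1 +
    out$L_pendular_E2 + out$L_pelvic_E2
  class(out) <- c("step_estimate", "data.frame")
  out
}

#' Estimate all step lengths of a trial
#'
#' Joins segmented phases, OFDRI phase velocities and the filtered yaw
#' series into one step-length estimate per step.
#'
#' @param phases `step_phases` from [segment_phases()].
#' @param vel `phase_velocity` from [phase_velocity_pipeline()].
#' @param yaw_filt filtered yaw series, degrees (from [fft_bin_highpass()]).
#' @param anthro a [subject_anthro()].
#' @param fs sampling rate, Hz.
#' @param pelvic_sign pelvic term sign (default -1, the printed model form).
#' @return data.frame with one row per valid step: timing columns from
#'   `phases` plus the full decomposition and `L_total`.
#' @export
estimate_steps <- function(phases, vel, yaw_filt, anthro, fs,
                           pelvic_sign = -1) {
  rows <- list()
  for (k in seq_len(nrow(phases))) {
    ph <- phases[k, ]
    v1 <- vel[vel$step_index == ph$step_index & vel$phase == "E1", ]
    v2 <- vel[vel$step_index == ph$step_index & vel$phase == "E2", ]
    if (nrow(v1) != 1L || nrow(v2) != 1L || !v1$ok || !v2$ok) next
    e1 <- phase_kinematics(v1$v_mean, ph$T_E1,
                           yaw_start = yaw_filt[ph$ic_idx],
                           yaw_end = yaw_filt[ph$ms_idx], lp = 1)
    e2 <- phase_kinematics(v2$v_mean, ph$T_E2,
                           yaw_start = yaw_filt[ph$ms_idx],
                           yaw_end = yaw_filt[ph$ic_next_idx], lp = 1)
    est <- step_length(e1, e2, anthro, side = ph$side,
                       pelvic_sign = pelvic_sign)
    rows[[length(rows) + 1L]] <- cbind(
      ph[c("step_index", "side", "t_ic", "t_ms", "t_ic_next", "trim")],
      est[setdiff(names(est), "side")])
  }
  if (length(rows) == 0L) {
    warning("no steps could be estimated")
    return(data.frame())
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
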