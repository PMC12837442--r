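#' Pre-filter acceleration for integration
#'
#' Zero-phase 2nd-order Butterworth low-pass at 3.5 Hz, the band that keeps
#' the centre-of-mass kinematics (pelvic and trunk motion live below about
#' 4 Hz) while rejecting the impact and muscle-activity content that makes
#' drift worse under integration.
#'
#' @param acc_ap anteroposterior acceleration, m/s^2.
#' @param fs sampling rate, Hz.
#' @param cutoff_hz cutoff, Hz (default 3.5).
#' @param order filter order (default 2).
#' @return filtered acceleration.
#' @export
prefilter_acc <- function(acc_ap, fs, cutoff_hz = 3.5, order = 2L) {
  butterworth_filter(acc_ap, filter_spec("lowpass", order, cutoff_hz), fs)
}

#' Forward trapezoidal integration of acceleration
#'
#' Cumulative trapezoid with an explicit initial condition:
#' `v[1] = v0`.
#'
#' @param acc acceleration over one phase, m/s^2.
#' @param fs sampling rate, Hz.
#' @param v0 initial velocity, m/s.
#' @return velocity series, m/s, same length as `acc`.
#' @export
integrate_forward <- function(acc, fs, v0 = 0) {
  if (length(acc) < 2L) stop("too few samples to integrate (need >= 2)")
  t <- seq_along(acc) / fs
  v0 + as.numeric(pracma::cumtrapz(t, acc))
}

#' Reverse trapezoidal integration of acceleration
#'
#' Backward cumulative trapezoid anchored at the phase end:
#' `v[n] = v_end`, and `v[i] = v_end - integral from t_i to t_n of acc`.
#' Anchored at the forward end value this reproduces forward integration
#' exactly; the anchor is exposed so variants can re-anchor.
#'
#' @param acc acceleration over one phase, m/s^2.
#' @param fs sampling rate, Hz.
#' @param v_end final velocity, m/s.
#' @return velocity series, m/s.
#' @export
integrate_reverse <- function(acc, fs, v_end = 0) {
  if (length(acc) < 2L) stop("too few samples to integrate (need >= 2)")
  t <- seq_along(acc) / fs
  ct <- as.numeric(pracma::cumtrapz(t, acc))
  v_end - (ct[length(ct)] - ct)
}

#' Blend forward and reverse velocity estimates
#'
#' Pointwise convex combination
#' `v_combined = alpha * v_direct + (1 - alpha) * v_inverse`.
#'
#' @param v_direct forward-integrated velocity.
#' @param v_inverse reverse-integrated velocity.
#' @param alpha weighting factor in \[0, 1\] (default 0.5: both directions
#'   weighted equally).
#' @return blended velocity.
#' @export
blend_velocity <- function(v_direct, v_inverse, alpha = 0.5) {
  if (length(v_direct) != length(v_inverse)) stop("length mismatch")
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  alpha * v_direct + (1 - alpha) * v_inverse
}

#' Velocity error for boundary-condition correction
#'
#' With a lumbar sensor the end-of-phase velocity cannot be assumed zero
#' (the trunk keeps moving at foot contact), so the unknown boundary
#' velocity is approximated by the phase mean of the blended velocity:
#' `Ev = v[n] - mean(v)`. This is the unique reading under which the
#' corrected endpoint equals the blended-velocity mean, and it vanishes for
#' constant velocity.
#'
#' @param v_combined blended velocity over one phase.
#' @return scalar velocity error `Ev`, m/s.
#' @export
estimate_ev <- function(v_combined) {
  if (length(v_combined) == 0L) stop("empty velocity series")
  v_combined[length(v_combined)] - mean(v_combined)
}

#' Linear boundary-condition drift correction
#'
#' Subtracts a linear ramp that distributes the accumulated velocity error
#' evenly over the phase:
#' `v_corrected(t) = v_combined(t) - (t - t0)/(tf - t0) * Ev`,
#' leaving the start value unchanged and lowering the end value by `Ev`.
#'
#' @param v_combined blended velocity.
#' @param t sample times, s (same length).
#' @param ev velocity error, m/s.
#' @return corrected velocity.
#' @export
correct_drift <- function(v_combined, t, ev) {
  if (length(v_combined) != length(t)) stop("length mismatch")
  t0 <- t[1]; tf <- t[length(t)]
  if (tf <= t0) stop("degenerate interval: tf must exceed t0")
  v_combined - (t - t0) / (tf - t0) * ev
}

#' Phase-segmented OFDRI velocity pipeline
#'
#' Optimally Filtered Direct and Reverse Integration over the E1/E2 phases
#' of every step. The (pre-filtered) anteroposterior acceleration is
#' integrated forward with chained initial conditions -- the first E1 of the
#' trial starts from zero velocity (the trial begins from standstill, so the
#' first foot strike occurs at essentially zero trunk velocity); each E2
#' starts from the end of its E1; each subsequent E1 starts from the end of
#' the preceding stride -- and backward anchored at the forward end value.
#' The two are blended (weight `alpha`), the boundary-condition error
#' `Ev = v_end - mean(v)` is estimated per phase, and a linear ramp
#' correction is applied. A phase that produces non-finite values is
#' flagged and dropped rather than failing the trial.
#'
#' @param acc_ap anteroposterior acceleration, m/s^2 (raw; pre-filtering is
#'   applied here unless `prefilter = FALSE`).
#' @param phases a `step_phases` data.frame from [segment_phases()].
#' @param fs sampling rate, Hz.
#' @param alpha blending weight (default 0.5).
#' @param prefilter apply the 3.5 Hz low-pass first (default `TRUE`).
#' @param correct apply the linear drift correction (default `TRUE`;
#'   disabling it gives the uncorrected pipeline used as its own control).
#' @param anchor_idx sample index where the zero-velocity initial
#'   condition holds. Walk trials begin from quiet standing, so the default
#'   (`1`, the recording start) is where zero velocity is guaranteed; the
#'   velocity is integrated forward from there into the first phase. Pass
#'   the first initial-contact index to impose the boundary condition at
#'   the first foot strike instead. When steps are dropped between phases,
#'   the carried velocity is propagated by integrating across the gap, so
#'   a dropped step does not break the initial-condition chain.
#' @return data.frame (class `phase_velocity`), one row per phase:
#'   `step_index`, `phase` ("E1"/"E2"), `v0`, `v_end`, `ev`, `v_mean`
#'   (mean of the corrected velocity), `duration`, `ok`. The full per-phase
#'   velocity series are attached as attribute `series` (a list of lists
#'   with `t`, `v_direct`, `v_inverse`, `v_combined`, `v_corrected`).
#' @export
phase_velocity_pipeline <- function(acc_ap, phases, fs, alpha = 0.5,
                                    prefilter = TRUE, correct = TRUE,
                                    anchor_idx = 1L,
                                    prefilter_cutoff = 3.5,
                                    prefilter_order = 2L) {
  stopifnot(inherits(phases, "data.frame"))
  a <- if (prefilter)
    prefilter_acc(acc_ap, fs, prefilter_cutoff, prefilter_order) else acc_ap
  n <- length(a)
  rows <- list(); series <- list()
  v_carry <- 0   # velocity at `pos`: zero at the anchor
  pos <- if (is.null(anchor_idx)) NA_integer_ else as.integer(anchor_idx)
  for (k in seq_len(nrow(phases))) {
    ph <- phases[k, ]
    if (ph$ic_idx < 1L || ph$ic_next_idx > n) {
      rows[[length(rows) + 1L]] <- .phase_row(ph$step_index, NA, NA, NA, NA, NA, FALSE)
      next
    }
    if (is.na(pos)) pos <- ph$ic_idx
    if (ph$ic_idx > pos) {       # carry velocity across a gap (dropped steps)
      gap <- integrate_forward(a[pos:ph$ic_idx], fs, v0 = v_carry)
      v_carry <- gap[length(gap)]
    }
    pos <- ph$ic_idx
    for (phase in c("E1", "E2")) {
      idx <- if (phase == "E1") ph$ic_idx:ph$ms_idx else ph$ms_idx:ph$ic_next_idx
      seg <- a[idx]
      t <- (idx - 1L) / fs
      v0 <- v_carry
      vd <- integrate_forward(seg, fs, v0 = v0)
      vend <- vd[length(vd)]
      vi <- integrate_reverse(seg, fs, v_end = vend)
      vc <- blend_velocity(vd, vi, alpha)
      ev <- estimate_ev(vc)
      vcor <- if (correct) correct_drift(vc, t, ev) else vc
      ok <- all(is.finite(vcor))
      rows[[length(rows) + 1L]] <- .phase_row(ph$step_index, phase, v0, vend, ev,
                                              if (ok) mean(vcor) else NA_real_, ok,
                                              duration = t[length(t)] - t[1])
      series[[length(series) + 1L]] <- list(step_index = ph$step_index,
                                            phase = phase, t = t, v_direct = vd,
                                            v_inverse = vi, v_combined = vc,
                                            v_corrected = vcor)
      v_carry <- vend   # chain raw forward end value into the next phase
      pos <- idx[length(idx)]
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    .phase_row(integer(0), character(0), numeric(0), numeric(0),
               numeric(0), numeric(0), logical(0), numeric(0))
  attr(out, "series") <- series
  class(out) <- c("phase_velocity", "data.frame")
  out
}

.phase_row <- function(step_index, phase, v0, v_end, ev, v_mean, ok,
                       duration = NA_real_) {
  data.frame(step_index = step_index, phase = as.character(phase),
             v0 = v0, v_end = v_end, ev = ev, v_mean = v_mean,
             duration = duration, ok = ok, stringsAsFactors = FALSE)
}
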