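#' Detect initial contacts from anteroposterior acceleration
#'
#' At foot strike the pelvis decelerates sharply, which appears as a
#' characteristic valley in the anteroposterior acceleration. The signal is
#' band-limited to the locomotor fundamental (zero-phase 0.5 Hz high-pass
#' then 1.8 Hz low-pass, both order 4), candidate step peaks are found as
#' falling-edge zero-crossings of the time derivative, each paired with the
#' deceleration valley it reliably precedes (the next rising-edge
#' zero-crossing). Candidates are screened by an adaptive threshold on the
#' peak-to-valley swing -- a fraction of the median swing within a sliding
#' window -- which is scale-free and stays stable when band attenuation at
#' high cadence shrinks the absolute peak amplitudes. The local minimum of
#' the unfiltered acceleration within +/-4 samples of the accepted valley
#' pins the contact instant (the impact transient is sharp in the raw
#' channel but smeared by the band-pass). That refined index is the
#' initial contact. A refractory period suppresses double detections.
#'
#' @param acc_ap anteroposterior acceleration, m/s^2.
#' @param fs sampling rate, Hz.
#' @param hp,lp [filter_spec()]s for the high-pass and low-pass stages.
#' @param threshold_frac adaptive threshold as a fraction of the windowed
#'   median peak-to-valley swing of the candidates.
#' @param threshold_window_s sliding window for the adaptive threshold, s.
#' @param refine_window refinement half-window around the candidate valley,
#'   samples.
#' @param refractory_s minimum separation between initial contacts, s
#'   (cadence above 4 steps/s is non-physiologic).
#' @param min_swing_ms2 absolute floor on the peak-to-valley swing, m/s^2;
#'   guards the scale-free threshold against firing on numerically tiny
#'   residue when no gait is present.
#' @return integer vector of strictly increasing sample indices; empty, with
#'   a warning, when no events are found.
#' @export
detect_initial_contacts <- function(acc_ap, fs,
                                    hp = filter_spec("highpass", 4L, 0.5),
                                    lp = filter_spec("lowpass", 4L, 1.8),
                                    threshold_frac = 0.3,
                                    threshold_window_s = 5,
                                    refine_window = 4L,
                                    refractory_s = 0.25,
                                    min_swing_ms2 = 0.05) {
  n <- length(acc_ap)
  if (n < 3 * fs) stop("signal too short: need at least 3 s for event detection")
  y <- butterworth_filter(acc_ap, hp, fs)
  y <- butterworth_filter(y, lp, fs)
  dy <- diff(y)
  falling <- which(dy[-length(dy)] > 0 & dy[-1] <= 0) + 1L    # local maxima
  rising <- which(dy[-length(dy)] < 0 & dy[-1] >= 0) + 1L     # local minima
  if (length(falling) == 0L) {
    warning("no events found"); return(integer(0))
  }
  # pair every peak with the valley it precedes; screen by swing
  valley <- vapply(falling, function(p) {
    nxt <- rising[rising > p]
    if (length(nxt) == 0L) NA_integer_ else nxt[1]
  }, integer(1))
  ok <- !is.na(valley)
  falling <- falling[ok]; valley <- valley[ok]
  if (length(falling) == 0L) {
    warning("no events found"); return(integer(0))
  }
  swing <- y[falling] - y[valley]
  half <- threshold_window_s * fs / 2
  keep <- vapply(seq_along(falling), function(i) {
    w <- abs(falling - falling[i]) <= half
    med <- stats::median(swing[w])
    is.finite(med) && swing[i] > threshold_frac * med &&
      swing[i] > min_swing_ms2
  }, logical(1))
  if (!any(keep)) {
    warning("no events found"); return(integer(0))
  }
  ic <- vapply(valley[keep], function(v) {
    # recentre the +/-4-sample window until its minimum is interior: an
    # argmin on the window edge is not yet a local minimum
    for (iter in 1:5) {
      lo <- max(1L, v - refine_window); hi <- min(n, v + refine_window)
      m <- lo - 1L + which.min(acc_ap[lo:hi])
      if (m == v) break
      v <- m
    }
    v
  }, integer(1))
  ic <- sort(unique(ic))
  # refractory period: drop the later of any pair closer than refractory_s
  if (length(ic) > 1L) {
    keep <- rep(TRUE, length(ic)); last <- ic[1]
    for (i in seq_along(ic)[-1]) {
      if (ic[i] - last < refractory_s * fs) keep[i] <- FALSE else last <- ic[i]
    }
    ic <- ic[keep]
  }
  if (length(ic) == 0L) warning("no events found")
  ic
}

#' Detect mid-stance events from pelvic roll
#'
#' As load shifts between limbs the pelvis tilts toward the stance leg, so
#' mid-stance appears as alternating maxima/minima of the frontal-plane
#' rotation (roll). The roll series is centred with a zero-phase 0.5 Hz
#' high-pass (and smoothed with a 1.8 Hz low-pass so differentiation is not
#' noise-dominated), differentiated, and its zero-crossings of both
#' polarities are returned as mid-stance events, screened by an adaptive
#' amplitude threshold and a refractory period.
#'
#' @param roll_deg roll angle series, degrees.
#' @param fs sampling rate, Hz.
#' @param hp,lp [filter_spec()]s of the centring/smoothing stages.
#' @param threshold_frac fraction of the median absolute extremum amplitude
#'   below which an extremum is ignored.
#' @param refractory_s minimum separation between events, s.
#' @param min_amp_deg absolute floor on the extremum amplitude, degrees;
#'   pelvic tilt below it is not gait.
#' @return integer vector of sample indices (possibly empty, with warning).
#' @export
detect_midstance <- function(roll_deg, fs,
                             hp = filter_spec("highpass", 4L, 0.5),
                             lp = filter_spec("lowpass", 4L, 1.8),
                             threshold_frac = 0.3,
                             refractory_s = 0.25,
                             min_amp_deg = 0.05) {
  n <- length(roll_deg)
  if (n < 3 * fs) stop("signal too short: need at least 3 s for event detection")
  y <- butterworth_filter(roll_deg, hp, fs)
  y <- butterworth_filter(y, lp, fs)
  dy <- diff(y)
  ext <- which(dy[-length(dy)] * dy[-1] <= 0 & dy[-length(dy)] != 0) + 1L
  if (length(ext) == 0L) {
    warning("no mid-stance events found"); return(integer(0))
  }
  med <- stats::median(abs(y[ext]))
  ext <- ext[abs(y[ext]) > pmax(threshold_frac * med, min_amp_deg)]
  if (length(ext) > 1L) {
    keep <- rep(TRUE, length(ext)); last <- ext[1]
    for (i in seq_along(ext)[-1]) {
      if (ext[i] - last < refractory_s * fs) keep[i] <- FALSE else last <- ext[i]
    }
    ext <- ext[keep]
  }
  if (length(ext) == 0L) warning("no mid-stance events found")
  ext
}

#' Assign the stance limb at each initial contact
#'
#' Immediately after an initial contact, a positive vertical-axis angular
#' velocity means the centre of mass is moving to the right, implying the
#' left leg is in support; a negative value implies right-leg support. The
#' sign is taken from the mean over the 4 samples starting at the contact.
#' A zero mean yields "ambiguous", resolved by alternation with the
#' neighbouring labels (majority pattern at the trial boundary).
#'
#' @param gyro_vert vertical angular velocity, rad/s.
#' @param ic_idx initial-contact sample indices.
#' @param invert set `TRUE` for sensors mounted upside-down (flips the
#'   convention).
#' @return character vector, `"left"` or `"right"` per contact.
#' @export
assign_side <- function(gyro_vert, ic_idx, invert = FALSE) {
  n <- length(gyro_vert)
  if (length(ic_idx) == 0L) return(character(0))
  if (any(ic_idx < 1L | ic_idx > n)) stop("ic_idx outside signal bounds")
  s <- vapply(ic_idx, function(i) {
    m <- mean(gyro_vert[i:min(n, i + 3L)])
    if (m > 0) "left" else if (m < 0) "right" else "ambiguous"
  }, character(1))
  if (invert)
    s <- ifelse(s == "left", "right", ifelse(s == "right", "left", s))
  amb <- which(s == "ambiguous")
  if (length(amb)) {
    other <- function(x) if (x == "left") "right" else "left"
    for (i in amb) {
      if (i > 1L && s[i - 1L] != "ambiguous") s[i] <- other(s[i - 1L])
      else if (i < length(s) && s[i + 1L] != "ambiguous") s[i] <- other(s[i + 1L])
      else s[i] <- "left"
    }
  }
  s
}

#' Gait events container
#'
#' @param ic_idx initial-contact sample indices (strictly increasing).
#' @param ms_idx mid-stance sample indices.
#' @param side stance limb per initial contact (`"left"`/`"right"`).
#' @param fs sampling rate, Hz.
#' @return object of class `gait_events`. Non-alternating side sequences are
#'   flagged with a warning (not fatal: pathologic gait may violate strict
#'   alternation).
#' @export
gait_events <- function(ic_idx, ms_idx, side, fs) {
  ic_idx <- as.integer(ic_idx); ms_idx <- as.integer(ms_idx)
  if (is.unsorted(ic_idx, strictly = TRUE)) stop("ic_idx must be strictly increasing")
  if (length(side) != length(ic_idx)) stop("one side label per initial contact required")
  if (length(ic_idx) > 1L && any(side[-1] == side[-length(side)]))
    warning("non-alternating stance sides detected")
  structure(list(ic_idx = ic_idx, ms_idx = ms_idx, side = side, fs = fs),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d initial contacts, %d mid-stances @ %g Hz\n",
              length(x$ic_idx), length(x$ms_idx), x$fs))
  invisible(x)
}

#' Detect all gait events of a recording
#'
#' Convenience wrapper: initial contacts from `acc_ap`, mid-stances from
#' roll, stance sides from vertical angular velocity. Roll is taken from the
#' recording's `roll_deg` channel or derived from quaternions.
#'
#' @param rec an [imu_recording()].
#' @param config a [pipeline_config()] (cutoffs, thresholds, sign flags).
#' @return a [gait_events()] object.
#' @export
detect_events <- function(rec, config = pipeline_config()) {
  roll <- rec$roll_deg
  if (is.null(roll)) {
    if (is.null(rec$quat)) stop("recording has neither roll_deg nor quaternions")
    roll <- quat_to_euler(rec$quat)$roll
  }
  ic <- detect_initial_contacts(rec$acc_ap, rec$fs,
                                hp = filter_spec("highpass", config$hp_order, config$hp_cutoff),
                                lp = filter_spec("lowpass", config$lp_order, config$lp_cutoff),
                                threshold_frac = config$ic_threshold_frac,
                                refractory_s = config$refractory_s)
  ms <- detect_midstance(roll, rec$fs,
                         threshold_frac = config$ms_threshold_frac,
                         refractory_s = config$refractory_s)
  if (is.null(rec$gyro_vert)) stop("recording lacks gyro_vert; cannot assign sides")
  side <- assign_side(rec$gyro_vert, ic, invert = config$invert_vertical_gyro)
  gait_events(ic, ms, side, rec$fs)
}

#' Segment steps into phases E1 and E2
#'
#' A step runs from one initial contact to the next; mid-stance splits it
#' into E1 (braking: the body decelerates its forward fall from initial
#' contact until the pelvis is over the ankle) and E2 (propulsion: from
#' mid-stance to the next contact). Consecutive contact pairs with exactly
#' one interior mid-stance yield a step; pairs with none or several are
#' dropped and counted in the `dropped` attribute. The first and last two
#' steps of a trial are flagged (`trim`) as gait acceleration/deceleration
#' transients for downstream exclusion.
#'
#' @param events a [gait_events()].
#' @return data.frame (class `step_phases`): `step_index`, `side`, `t_ic`,
#'   `t_ms`, `t_ic_next`, `T_E1`, `T_E2`, `ic_idx`, `ms_idx`, `ic_next_idx`,
#'   `trim`.
#' @export
segment_phases <- function(events) {
  stopifnot(inherits(events, "gait_events"))
  ic <- events$ic_idx; ms <- events$ms_idx; fs <- events$fs
  if (length(ic) < 2L) stop("insufficient events: need at least 2 initial contacts")
  rows <- list(); dropped <- 0L
  for (k in seq_len(length(ic) - 1L)) {
    interior <- ms[ms > ic[k] & ms < ic[k + 1L]]
    if (length(interior) != 1L) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      side = events$side[k],
      t_ic = (ic[k] - 1L) / fs, t_ms = (interior - 1L) / fs,
      t_ic_next = (ic[k + 1L] - 1L) / fs,
      ic_idx = ic[k], ms_idx = interior, ic_next_idx = ic[k + 1L],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    warning("no valid steps after mid-stance interleaving check")
    out <- data.frame(step_index = integer(0), side = character(0),
                      t_ic = numeric(0), t_ms = numeric(0),
                      t_ic_next = numeric(0), T_E1 = numeric(0),
                      T_E2 = numeric(0), ic_idx = integer(0),
                      ms_idx = integer(0), ic_next_idx = integer(0),
                      trim = logical(0))
    attr(out, "dropped") <- dropped
    class(out) <- c("step_phases", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$step_index <- seq_len(nrow(out))
  out$T_E1 <- out$t_ms - out$t_ic
  out$T_E2 <- out$t_ic_next - out$t_ms
  m <- nrow(out)
  out$trim <- out$step_index <= 2L | out$step_index > m - 2L
  out <- out[c("step_index", "side", "t_ic", "t_ms", "t_ic_next",
               "T_E1", "T_E2", "ic_idx", "ms_idx", "ic_next_idx", "trim")]
  attr(out, "dropped") <- dropped
  class(out) <- c("step_phases", "data.frame")
  out
}
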