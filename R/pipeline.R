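#' Pipeline configuration
#'
#' Collects every tunable of the estimation pipeline with the reference
#' values as defaults. Unknown keys passed via `...` are an error, so
#' misspelt options are never silently accepted.
#'
#' @param hp_cutoff,hp_order event-detection high-pass (Hz / order).
#' @param lp_cutoff,lp_order event-detection low-pass (Hz / order).
#' @param yaw_cutoff FFT-bin high-pass cutoff for yaw, Hz.
#' @param yaw_bins optional fixed bin count for the yaw filter (overrides
#'   `yaw_cutoff`; the literal fixed-bin variant).
#' @param integration_lp_cutoff,integration_lp_order pre-integration
#'   low-pass (Hz / order).
#' @param alpha forward/reverse blending weight.
#' @param ic_threshold_frac,ms_threshold_frac adaptive-threshold fractions
#'   for initial-contact and mid-stance detection.
#' @param refractory_s event refractory period, s.
#' @param invert_vertical_gyro flip the stance-side sign convention.
#' @param pelvic_sign sign of the pelvic term (-1 = printed model form).
#' @param anchor where the zero-velocity boundary condition of the
#'   integration holds: `"trial_start"` (recording begins at quiet
#'   standing; default) or `"first_contact"` (zero trunk velocity imposed
#'   at the first detected initial contact).
#' @param pairing_tol step-pairing tolerance, s.
#' @param trim_steps exclude the first and last two steps of a trial
#'   (gait acceleration/deceleration transients).
#' @param ... guard against unknown keys.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(hp_cutoff = 0.5, hp_order = 4L,
                            lp_cutoff = 1.8, lp_order = 4L,
                            yaw_cutoff = 0.25, yaw_bins = NULL,
                            integration_lp_cutoff = 3.5,
                            integration_lp_order = 2L,
                            alpha = 0.5,
                            ic_threshold_frac = 0.3,
                            ms_threshold_frac = 0.3,
                            refractory_s = 0.25,
                            invert_vertical_gyro = FALSE,
                            pelvic_sign = -1,
                            anchor = c("trial_start", "first_contact"),
                            pairing_tol = 0.25,
                            trim_steps = TRUE, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration keys: ", paste(names(extra), collapse = ", "))
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (!pelvic_sign %in% c(-1, 1)) stop("pelvic_sign must be -1 or +1")
  anchor <- match.arg(anchor)
  structure(list(hp_cutoff = hp_cutoff, hp_order = as.integer(hp_order),
                 lp_cutoff = lp_cutoff, lp_order = as.integer(lp_order),
                 yaw_cutoff = yaw_cutoff, yaw_bins = yaw_bins,
                 integration_lp_cutoff = integration_lp_cutoff,
                 integration_lp_order = as.integer(integration_lp_order),
                 alpha = alpha, ic_threshold_frac = ic_threshold_frac,
                 ms_threshold_frac = ms_threshold_frac,
                 refractory_s = refractory_s,
                 invert_vertical_gyro = invert_vertical_gyro,
                 pelvic_sign = pelvic_sign, anchor = anchor,
                 pairing_tol = pairing_tol, trim_steps = trim_steps),
            class = "pipeline_config")
}

#' Run the full step-length estimation pipeline on one recording
#'
#' Preprocess, detect events, segment phases, integrate phase velocities
#' (OFDRI), and evaluate the double-inverted-pendulum model per step. When
#' trimming is enabled the first and last two steps (gait acceleration /
#' deceleration) are excluded from the returned table; set
#' `keep_trimmed = TRUE` to keep them flagged instead.
#'
#' @param rec an [imu_recording()].
#' @param anthro a [subject_anthro()].
#' @param config a [pipeline_config()].
#' @param keep_trimmed keep trimmed steps in the output (flagged in the
#'   `trim` column).
#' @return data.frame of step estimates (see [estimate_steps()]) with a
#'   `diagnostics` attribute: counts of events found, steps dropped at
#'   segmentation, and steps trimmed.
#' @export
run_pipeline <- function(rec, anthro, config = pipeline_config(),
                         keep_trimmed = FALSE) {
  if (!inherits(rec, "imu_recording")) stop("ingest: rec must be an imu_recording")
  if (rec$n < 3 * rec$fs) stop("ingest: recording shorter than 3 s")
  events <- detect_events(rec, config)
  phases <- segment_phases(events)
  vel <- phase_velocity_pipeline(rec$acc_ap, phases, rec$fs,
                                 alpha = config$alpha,
                                 anchor_idx = if (config$anchor == "first_contact")
                                   events$ic_idx[1] else 1L,
                                 prefilter_cutoff = config$integration_lp_cutoff,
                                 prefilter_order = config$integration_lp_order)
  yaw <- rec$yaw_deg
  if (is.null(yaw)) {
    if (is.null(rec$quat)) stop("recording has neither yaw_deg nor quaternions")
    yaw <- quat_to_euler(rec$quat)$yaw
  }
  yaw_f <- fft_bin_highpass(yaw, rec$fs, cutoff_hz = config$yaw_cutoff,
                            n_bins = config$yaw_bins)
  steps <- estimate_steps(phases, vel, yaw_f, anthro, rec$fs,
                          pelvic_sign = config$pelvic_sign)
  diag <- list(n_ic = length(events$ic_idx), n_ms = length(events$ms_idx),
               n_steps_segmented = nrow(phases),
               n_steps_dropped = attr(phases, "dropped"),
               n_steps_trimmed = if (nrow(steps)) sum(steps$trim) else 0L)
  if (config$trim_steps && !keep_trimmed && nrow(steps))
    steps <- steps[!steps$trim, , drop = FALSE]
  rownames(steps) <- NULL
  attr(steps, "diagnostics") <- diag
  steps
}

#' Pair pipeline output against generator ground truth
#'
#' Matches estimated steps of a synthetic trial to the true step sequence
#' (times are already on a common clock, so no re-alignment is applied) and
#' returns the paired table for agreement statistics.
#'
#' @param steps output of [run_pipeline()].
#' @param truth `gait_truth` from [simulate_gait()].
#' @param tol pairing tolerance, s.
#' @return a [pair_steps()] data.frame.
#' @export
pair_with_truth <- function(steps, truth, tol = 0.25) {
  if (nrow(steps) == 0L) stop("no estimated steps to pair")
  pair_steps(est_times = steps$t_ic, est_lengths = steps$L_total,
             ref_times = truth$ic_times[-length(truth$ic_times)],
             ref_lengths = truth$step_lengths,
             est_sides = steps$side, tol = tol, align = FALSE)
}

#' Simulate a cohort and validate the pipeline against ground truth
#'
#' Draws `n_subjects` subjects round-robin from the scenario presets (or a
#' supplied list), simulates `n_trials` walks each with subject- and
#' trial-specific seeds, runs the estimation pipeline, pairs each trial
#' against its generator truth, and aggregates pooled, per-group and
#' per-subject agreement statistics.
#'
#' @param n_subjects number of synthetic subjects.
#' @param n_trials trials per subject.
#' @param presets named list of [gait_scenario()]s to cycle through.
#' @param config a [pipeline_config()].
#' @param seed master seed; per-trial seeds are derived from it.
#' @param noise_acc optional override of the accelerometer noise sd for the
#'   whole cohort (used for noise-ladder studies).
#' @return list of class `validation_study`: `pooled`
#'   (an [agreement_report()]), `per_group` (list of reports by preset),
#'   `group_tables` (a [group_report()]), `pairs` (pooled paired steps with
#'   subject/group ids), `n_subjects`, `n_trials`.
#' @export
run_validation_study <- function(n_subjects = 20L, n_trials = 3L,
                                 presets = scenario_presets(),
                                 config = pipeline_config(), seed = 1L,
                                 noise_acc = NULL) {
  stopifnot(length(presets) >= 1L)
  all_pairs <- list(); by_subject <- list()
  for (s in seq_len(n_subjects)) {
    preset_name <- names(presets)[(s - 1L) %% length(presets) + 1L]
    sub_pairs <- list()
    for (tr in seq_len(n_trials)) {
      sc <- presets[[preset_name]]
      sc$seed <- (seed * 10007L + s * 101L + tr) %% .Machine$integer.max
      if (!is.null(noise_acc)) sc$noise_acc <- noise_acc
      sim <- simulate_gait(sc)
      steps <- run_pipeline(sim$recording, sc$anthro, config)
      if (nrow(steps) == 0L) next
      p <- pair_with_truth(steps, sim$truth, tol = config$pairing_tol)
      p$subject <- sprintf("S%02d", s); p$group <- preset_name; p$trial <- tr
      sub_pairs[[tr]] <- p
    }
    if (!length(sub_pairs)) next
    sp <- do.call(rbind, sub_pairs)
    by_subject[[sprintf("S%02d", s)]] <- sp
    all_pairs[[length(all_pairs) + 1L]] <- sp
  }
  pooled_pairs <- do.call(rbind, all_pairs)
  class(pooled_pairs) <- c("paired_steps", "data.frame")
  per_group <- lapply(split(pooled_pairs, pooled_pairs$group), function(g)
    agreement_report(g, tests = FALSE))
  structure(list(pooled = agreement_report(pooled_pairs),
                 per_group = per_group,
                 group_tables = group_report(by_subject),
                 pairs = pooled_pairs,
                 n_subjects = n_subjects, n_trials = n_trials),
            class = "validation_study")
}

#' @export
print.validation_study <- function(x, ...) {
  cat(sprintf("<validation_study> %d subjects x %d trials, %d paired steps\n",
              x$n_subjects, x$n_trials, x$pooled$n))
  print(x$pooled)
  invisible(x)
}
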