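---
title: "Step length from a single lumbar IMU: model, pipeline, and validation design"
author: "gaitdip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Step length from a single lumbar IMU: model, pipeline, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitdip)
```

## The model

Walking can be described as two inverted pendulums — the legs — coupled
through the pelvis. During each step the supporting leg pivots over the
foot while the pelvis, carrying the centre of mass, both translates
forward and rotates in the transverse plane. `gaitdip` estimates per-step
length from a single inertial sensor on the lower back by decomposing each
step into a pendular and a pelvic contribution:

$$L = \underbrace{\frac{\sqrt{Fr_{E1}\, g\, L_p}}{C_{E1}} +
      \frac{\sqrt{Fr_{E2}\, g\, L_p}}{C_{E2}}}_{\text{pendular}}
   \;-\; \underbrace{r_p \tan(\Delta\psi_{E1}) + r_p \tan(\Delta\psi_{E2})}_{\text{pelvic}}$$

Each step is split at mid-stance into a braking phase E1 (initial contact
until the pelvis passes over the ankle) and a propulsion phase E2
(mid-stance to the next contralateral contact). For each phase,

* $Fr = V^2/(g L_p)$ is the Froude number computed from that phase's
  integrated mean forward velocity $V$ and the stance leg's length $L_p$
  (trochanter to sole). Phase-specific Froude numbers let braking and
  propulsion differ in time and speed, which is exactly what asymmetric
  and pathological gait does;
* $C = 1/T$ is the cadence generalized to the phase (reciprocal phase
  duration). With this choice the pendular term reduces algebraically to
  $V/C = V\,T$, the kinematic displacement of the phase — the identity the
  test suite checks to $10^{-12}$;
* $\Delta\psi$ is the net change of the transverse pelvic rotation (yaw)
  over the phase and $r_p$ the pelvic radius (mid-sacrum to iliac crest).
  Seen from above, yaw rotation displaces the hip pivot forward by the
  tangent projection $r_p\tan\Delta\psi$. The full tangent is kept rather
  than a small-angle form so the projection stays valid at the larger
  compensatory rotations of impaired gait; observed cohort yaw stays
  within roughly $\pm 20^\circ$, far from the $\pm 90^\circ$
  singularities. The minus sign follows the model's printed form and the
  sensor's sign convention; `pipeline_config(pelvic_sign = +1)` flips it
  for sensors with the opposite convention.

A note on the pendular term: the dimensionally consistent solution of
$V = C\,L$ and $Fr = V^2/(gL_p)$ is $L = \sqrt{Fr\,g\,L_p}\,/\,C$; the
package implements this square-root form throughout.

## From raw signals to model inputs

**Event detection.** Initial contact (IC) appears as a sharp deceleration
valley in the anteroposterior acceleration. The detector band-limits the
signal to the locomotor fundamental (zero-phase Butterworth: 0.5 Hz
high-pass then 1.8 Hz low-pass, order 4), finds candidate step peaks as
falling-edge zero-crossings of the derivative, pairs each with the valley
it precedes (the next rising-edge zero-crossing), and screens candidates
with an adaptive threshold: a peak–valley *swing* must exceed 0.3 times
the median swing within a sliding 5 s window. We threshold the swing
rather than the peak amplitude because near and above the low-pass cutoff
the band-limited maxima shrink toward zero while genuine valleys persist;
the swing is scale-free and keeps full recall across the 1.2–2.2 steps/s
cadence range. The contact instant is then pinned on the *unfiltered*
acceleration: the ±4-sample window around the band-limited valley is
recentred on its own minimum until that minimum is interior. The impact
transient is sharp in the raw channel but smeared by the band-pass, so
this raw-signal descent removes the cadence-dependent timing bias a
filtered-signal refinement would introduce. A 0.25 s refractory period
(cadence < 4 steps/s) suppresses double detections, and an absolute swing
floor (0.05 m/s²) keeps the scale-free threshold from firing on numerical
residue when no gait is present.

**Mid-stance** is the extremum of the frontal-plane pelvic roll as load
shifts onto the stance leg: the roll series is centred (0.5 Hz high-pass),
smoothed (1.8 Hz low-pass — added so differentiation is not
noise-dominated), differentiated, and zero-crossings of both polarities
are taken, with the same adaptive screening.

**Stance side** comes from the vertical-axis angular velocity just after
each contact: positive means the centre of mass is moving right, hence
left-leg support; negative means right-leg support. Zero-velocity
ambiguity is resolved by alternation with neighbours;
`invert_vertical_gyro` accommodates upside-down mounting.

**Pelvic yaw** is extracted from the sensor's orientation quaternions
(intrinsic Z-Y-X decomposition, yaw about the gravity-aligned vertical,
unwrapped) and de-trended with an FFT-bin high-pass: all bins below
0.25 Hz including DC are zeroed, the signal reconstructed by inverse FFT,
and the output realigned by circular cross-correlation. The fixed-bin
variant (`yaw_bins = 8`) reproduces the constant-bin formulation, which
coincides with 0.25 Hz only for ~32 s records; the cutoff
parameterization is the default because it is record-length invariant.

## Velocity by drift-corrected integration (OFDRI)

The anteroposterior acceleration is low-pass filtered at 3.5 Hz (order 2,
zero-phase) — the band that keeps centre-of-mass kinematics while
rejecting impact content that aggravates drift — and integrated with the
trapezoidal rule per phase, forward and backward:

* the zero-velocity boundary condition is anchored at the **start of the
  recording** by default (`anchor = "trial_start"`): walk trials begin
  from quiet standing, where zero velocity is guaranteed, and the
  velocity is integrated forward into the first contact. The alternative
  `"first_contact"` imposes zero trunk velocity at the first detected
  contact — equivalent when the trial starts at rest, but fragile if the
  first contact is missed or mistimed during gait initiation;
* each E2 starts from the end of its E1; each subsequent E1 from the end
  of the preceding stride; if a step is dropped (e.g. ambiguous
  mid-stance), the carried velocity is propagated by integrating across
  the gap, so one bad step does not break the chain;
* reverse integration is anchored at the forward end value (the literal
  reading of the procedure; `blend_velocity()` then makes the α-weighting
  a no-op on clean signals — the acceptance suite verifies α ∈ {0, 0.5, 1}
  agree to 10⁻⁹ on drift-free input);
* the boundary-condition error is estimated as
  $E_v = v(t_f) - \overline{v}$ — the unique reading under which the
  corrected endpoint equals the blended-velocity mean, and zero for
  constant velocity — and distributed linearly:
  $v_{corr}(t) = v(t) - \frac{t - t_0}{t_f - t_0} E_v$. $E_v$ is
  estimated and applied per phase (not per stride), matching the
  phase-segmented description; per-phase application also makes the
  correction's clean-signal footprint cancel between E1 and E2.

The phase-mean of the corrected velocity feeds the Froude number; the
pendular term follows.

## What the synthetic generator emulates

`simulate_gait()` builds signals from the same kinematic skeleton the
estimator assumes, with exact ground truth:

* a gait phase function θ(t), linear between contacts (θ = kπ) and
  mid-stances (θ = kπ + π/2); all event times are snapped to the sample
  grid (durations are rounded, not cumulative times — cumulative rounding
  would systematically stretch left steps and shrink right ones);
* forward velocity = per-step mean speeds (left/right modulated at stride
  frequency to realize a configured step-length ratio) + a within-step
  braking/propulsion oscillation (−sin 2θ; `speed_ripple`, default 8% of
  speed) + a zero-net impact transient at each contact (Mexican-hat
  acceleration valley, ~60 ms FWHM, depth 3 m/s² × `impact_sharpness`);
* trials start from quiet standing with a two-step initiation ramp — the
  same two steps the analysis trims as acceleration transients — so the
  zero-velocity anchor is exact; `startup = FALSE` gives steady-state
  walking for isolated detection studies (the recording then ends half a
  step after the last contact, where the waveform's local even symmetry
  makes reflective filter padding continue it almost exactly);
* pelvic yaw and roll oscillate at *stride* frequency with extrema at
  mid-stance; the vertical angular velocity is the yaw rate, so its sign
  at contact encodes the stance limb by construction;
* step timing varies naturally (`cadence_cv`, default 2%): strictly
  periodic steps would phase-lock sample-grid rounding into a systematic
  bias no real cohort exhibits;
* white Gaussian noise on each channel (no noise model is prescribed for
  the reference hardware; accelerometer sd 0.1 m/s², gyroscope
  0.02 rad/s, orientation 0.3° by default).

Ground-truth step length uses the same geometric decomposition the model
assumes — the integral of the generated velocity over the step plus the
pelvic tangent projection of the noise-free yaw — so estimation error on
clean signals isolates *pipeline* error (filtering, detection,
integration, discretization) rather than model-versus-truth discrepancy.
Consequently, passing the closed-loop suite shows the chain recovers what
the model defines, under signals whose morphology mimics lumbar IMU data;
it does not validate the model against independent kinematics, soft-tissue
artifact, sensor misplacement, magnetic disturbance, or turning gait.
Preset amplitudes ("healthy_adult", "older_adult", "asymmetric_mild",
"asymmetric_severe", "shuffling") are synthetic, chosen as physiologically
plausible, not measured values.

## Numerical choices

* All Butterworth filtering is zero-phase (forward–backward), with
  reflective padding of at least 2 s, growing to eight cutoff periods at
  low cutoffs so start-up transients decay inside the pad. Stated filter
  orders are the single-pass design orders.
* The spectral QC (`locomotion_band()`) uses a small complex-Morlet
  continuous wavelet transform favouring frequency resolution; in steady
  adult gait the dominant band falls at 1.5–1.8 Hz. It is reporting-only:
  the 0.5/1.8 Hz detection cutoffs are fixed, not adapted.
* Degenerate inputs: flat signals yield empty event lists with warnings,
  not errors; a phase producing non-finite velocities flags and drops
  that step; consecutive contacts with zero or multiple interior
  mid-stances are dropped and counted in diagnostics.
* The first and last two steps of every trial are excluded by default as
  gait acceleration/deceleration transients (`trim_steps`).
* Validation studies in the test suite use 20 subjects × 3 trials of
  12 steps at 100 Hz, with detection sweeps over cadences 1.2–2.2 steps/s;
  these sizes give a few hundred analyzed steps per cohort, enough for
  stable medians while keeping the default suite under a minute.

## A worked example

```{r example}
sc <- scenario_presets(seed = 7L)$asymmetric_mild
sim <- simulate_gait(sc)
steps <- run_pipeline(sim$recording, sc$anthro)
steps[, c("step_index", "side", "t_ic", "L_pendular_E1", "L_pelvic_E1",
          "L_total")]

pairs <- pair_with_truth(steps, sim$truth)
agreement_report(pairs, tests = FALSE)
```

## Known limitations

* The tangent projection needs |Δψ| < 90°; the code errors at the
  singularity and warns above 45°.
* The zero-velocity anchor assumes the recording starts at rest (or, with
  `anchor = "first_contact"`, that the trunk is at rest at the first
  contact). Recordings clipped mid-walk violate both and will produce a
  uniform velocity offset.
* Event detection requires an identifiable deceleration valley; extremely
  soft heel strikes (severe shuffling) degrade recall — the
  `"shuffling"` preset exists precisely to exercise this failure mode.
* No explicit gravity compensation is applied to the anteroposterior
  channel; the sensor frame is assumed gravity-aligned by the onboard
  fusion. Misalignment couples vertical acceleration into the integrated
  channel.
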