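# gaitdip

Step-length estimation for (possibly asymmetric) human gait from a
**single inertial sensor on the lower back**, built on a
double-inverted-pendulum view of walking: each leg is an inverted pendulum
pivoting over the stance foot, coupled through the pelvis, whose
transverse rotation contributes its own share of forward displacement.

The package is for movement scientists and rehabilitation engineers who
want per-step spatial gait parameters outside a motion-capture lab — from
one belt-worn IMU sampling 3-axis acceleration, angular velocity and
orientation quaternions at 100 Hz — and who care about *asymmetric* gait,
where classical single-pendulum formulas that assume left/right symmetry
misread pelvic compensation as step length.

## The model

Each step (initial contact of one foot to initial contact of the other)
is split at mid-stance into a braking phase E1 and a propulsion phase E2.
Step length is

```
L = sqrt(Fr_E1 · g · Lp) / C_E1  −  rp · tan(Δψ_E1)
  + sqrt(Fr_E2 · g · Lp) / C_E2  −  rp · tan(Δψ_E2)
```

where, per phase, `Fr = V²/(g·Lp)` is the Froude number from the phase's
mean forward velocity, `C = 1/T` the phase cadence, `Lp` the stance leg's
length, `rp` the pelvic radius and `Δψ` the change of pelvic yaw. The
pendular terms reduce algebraically to `V·T` (phase displacement); the
pelvic terms are the tangent projection of transverse pelvic rotation.

The pipeline behind the formula:

* **gait events** — initial contacts from deceleration valleys of the
  anteroposterior acceleration (band-limited candidate search, raw-signal
  valley refinement); mid-stances from pelvic-roll extrema; stance side
  from the sign of the vertical angular velocity at contact;
* **phase velocity** — OFDRI: forward and reverse trapezoidal integration
  of the 3.5 Hz low-passed acceleration with chained initial conditions,
  α-blending, and a linear boundary-condition drift correction per phase;
* **pelvic yaw** — quaternion → Euler extraction and an FFT-bin high-pass
  (bins below 0.25 Hz zeroed) with cross-correlation realignment;
* **validation statistics** — step pairing against a reference sequence,
  median absolute error (MdAE) with IQR, percent error, Bland–Altman
  bias/limits of agreement, Pearson correlation and OLS regression,
  Shapiro–Wilk and Wilcoxon contracts;
* **synthetic gait generator** — IMU-like signals with exact ground-truth
  events and step lengths (configurable cadence, speed, asymmetry, heel
  strike sharpness, noise), enabling closed-loop validation of every
  stage. See the methods vignette (`vignettes/step-length-model.Rmd`).

## Worked example

Simulate a mildly asymmetric walker (10% longer left steps), run the full
pipeline, and compare with the generator's ground truth:

```r
library(gaitdip)
sc    <- scenario_presets(seed = 7L)$asymmetric_mild
sim   <- simulate_gait(sc)
steps <- run_pipeline(sim$recording, sc$anthro)
steps[, c("step_index","side","t_ic","L_pendular_E1","L_pelvic_E1","L_total")]
#>  step_index  side t_ic L_pendular_E1 L_pelvic_E1 L_total
#>           3  left 2.47        0.2988     -0.0337  0.6618
#>           4 right 3.10        0.2888      0.0308  0.5945
#>           5  left 3.70        0.2984     -0.0307  0.6608
#>           6 right 4.33        0.2783      0.0327  0.5945
#>           7  left 4.93        0.3164     -0.0321  0.6747
#>           8 right 5.58        0.2776      0.0320  0.6068
#>           9  left 6.19        0.3093     -0.0298  0.6691
#>          10 right 6.83        0.2965      0.0318  0.6353

agreement_report(pair_with_truth(steps, sim$truth), tests = FALSE)
#> <agreement_report> n = 8 steps
#>   MdAE 0.0103 m (IQR [0.0096-0.0148]), median % error +1.70%
#>   Bland-Altman bias +0.0119 m (95% CI [0.0095, 0.0143]), LoA [0.0051, 0.0186]
#>   R = 0.9970, R2 = 0.9941, slope 1.0698, intercept -0.0318
```

Reading the output: the trial's first and last two steps (gait
initiation/termination transients) are excluded, leaving steps 3–10; left
steps are ~0.66 m and right steps ~0.60 m, a median left/right ratio of
1.108 against the configured 1.10; the per-step decomposition shows the
pelvic term alternating sign with stance side. Against ground truth the
median absolute error is about 1 cm per step under the preset's sensor
noise.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/gaitdip.R simulate --preset asymmetric_mild --seed 7 \
    --out trial.csv --truth truth.json
Rscript inst/cli/gaitdip.R estimate --input trial.csv --out steps.csv
Rscript inst/cli/gaitdip.R detect   --input trial.csv --out events.json
Rscript inst/cli/gaitdip.R study    --subjects 20 --trials 3 --seed 1
```

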