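---
title: "Methods: synthetic validation of a myoelectric-wrist analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic validation of a myoelectric-wrist analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristcomp)
```

## Scope and design

`wristcomp` implements the computational analysis of a cross-over validation
study of a powered prosthetic wrist: transradial amputees perform a clothespin
relocation task (CRT) under four conditions — a commercial and a research
prosthesis configuration, each with the wrist enabled or disabled (C+W, C-W,
R+W, R-W) — while surface EMG drives a Kalman-filter decoder, chest-worn IMUs
measure compensatory trunk motion, and a secondary detection-response task
(DRT) plus NASA-TLX index cognitive load.

No subject-level data are deposited for such studies, so the package pairs
every analysis stage with a synthetic generator whose default parameters are
the study's published summary statistics. Acceptance is then *parameter
recovery*: the full pipeline (quaternion synthesis → angle extraction →
statistics; Bernoulli outcomes → GLM; DRT logs → matching and scoring) must
reproduce those calibrated values from raw synthetic inputs.

## EMG feature chain

Raw EMG is modelled as 32 channels at 1 kHz. The chain is:

1. **Band-pass**: sixth-order high-pass Butterworth at 15 Hz cascaded with a
   second-order low-pass at 375 Hz. Filtering is causal (single-pass), not
   zero-phase, because the decoder describes an online controller; a
   forward–backward filter would use future samples.
2. **Notches** at 60/120/180 Hz: second-order IIR biquads with quality factor
   Q = 30 (≈2 Hz bandwidth at 60 Hz). No notch design is canonical for this
   task; Q = 30 is standard power-line rejection and the tests only constrain
   the magnitude response (< 0.1 at the notch, within 5% of unity from 10 Hz
   away).
3. **Differential pairs**: all C(32, 2) = 496 ordered differences
   `channel_i − channel_j`, i < j, lexicographic. Because differencing and
   linear filtering commute, pairs are formed after filtering.
4. **Smoothed MAV**: per channel, the mean of |signal| over a trailing 300-ms
   window, evaluated at 30 Hz (frame k covers (k·Δ − 0.3 s, k·Δ], Δ = 1/30 s).
   Frames earlier than 300 ms use the partial window rather than being
   dropped, which keeps the stream aligned with kinematics from the first
   frame; whether the original system dropped start-up frames is unknowable
   from the outside, and this choice only affects the first nine frames.

The chain is positively homogeneous (doubling the input doubles every
feature), and the feature count is n + C(n, 2) for any n ≥ 2 — both are
property-tested.

## Synthetic EMG and the mixing model

The generator needs a forward model from 3-DOF kinematic intent (pinch,
pronation/supination, flexion/extension, each in [−1, 1]) to EMG. Each signed
DOF direction is an activation source (6 sources); a non-negative gain matrix
(default: one smooth Gaussian channel-tuning bump per source) maps activations
to per-channel envelopes; the raw signal is a band-limited (20–350 Hz)
unit-RMS Gaussian carrier amplitude-modulated by that envelope, plus optional
white noise. At `noise_sd = 0` the rectified signal is *exactly* linear in the
activations, giving the decoder a recoverable ground truth. This reproduces
the second-order statistics the feature chain consumes; it makes no attempt at
physiological realism beyond that (no motor-unit structure, no electrode
shift, no fatigue, no crosstalk physiology), so decoder tests certify the
algorithm, not clinical performance.

The training protocol mirrors prosthesis mimicry training: four repetitions
of each single-DOF motion (both directions, raised-cosine bumps, default 1 s
per bump with 0.25-s rests) and two repetitions of each ordered sequential
pair of one hand motion and one wrist motion (8 ordered pairs).

## Kalman decoder

The decoder is the linear-Gaussian state-space estimator standard in
myoelectric regression control: prior x_t = A x_{t−1} + w, w ~ N(0, W);
likelihood y_t = H x_t + q, q ~ N(0, Q), with y the 528-vector of MAV
features and x the 3-DOF intent. Training is least squares: A from successive
kinematic frames, H from regressing features on kinematics, W and Q as
residual covariances. Numerical choices:

- **Ridge on H** (`lambda`, default 1e-3, scaled by trace(X'X)/d): with 528
  features and a few thousand frames the regression is ill-conditioned; the
  penalty is a numerical necessity, not a modelling claim.
- **Diagonal loading on Q** (default 1e-6 of its mean diagonal) keeps the
  observation covariance invertible when frames barely exceed features.
- **Information-form update**: the posterior precision P⁻¹ + H'Q⁻¹H is 3×3,
  so each step costs O(d³ + dp) after caching H'Q⁻¹ — the natural route when
  p = 528 ≫ d = 3.
- **Alignment lag**: a trailing 300-ms MAV window summarizes activity centred
  150 ms in the past, so training kinematics are sampled at k/rate − 0.15 s
  (`kinematics_at_rate(..., lag = window/2)`). Without this the feature lag
  caps recovery correlations near 0.8; with it the full synthetic chain
  decodes at r > 0.98.
- **Initial state** 0 (rest posture) with covariance W; posterior means
  clipped to [−1, 1] each step.
- **DOF locking** zeroes the locked DOFs' posterior mean *and* covariance
  rows/columns every step, not merely the output, so locked-DOF dynamics
  cannot leak back through A. This matches disabling a wrist in software
  while leaving the control pipeline untouched.
- **Output shaping**: decoders of this family usually add post-hoc shaping;
  the exact modifications used in any given controller are rarely published.
  A per-DOF dead-zone (default 0.1) and gain (default 1.0) are provided as
  configurable stand-ins; `dead_zone = 0` recovers the pure linear-Gaussian
  filter, which is what the equivalence tests (single step ≡ closed-form
  Gaussian conditioning; stream ≡ batch joint-covariance conditioning to
  1e-6) exercise.
- **Degenerate inputs**: non-finite feature frames are skipped with the state
  held; rank-deficient kinematics trigger a ridge-regularized state model
  with a warning.

## IMU orientation and compensation angles

Axis conventions (fixed, since any consistent convention reproduces maxima of
isolated excursions): x anterior, y left, z up. Forward lean is intrinsic
pitch (body vertical tilting anteriorly), leftward bend intrinsic roll
(vertical tilting toward +y); both are read off the image of the vertical
unit vector under the relative rotation R_rel = R_ref⁻¹ R_sensor, i.e.
lean = atan2(v_x, v_z), bend = asin(v_y). The mean pose over the first 0.5 s
is subtracted (the study implies deviation from a neutral starting posture
but states no window; 0.5 s covers the pre-movement rest the generator
embeds). Compensation per attempt is max |angle| over the attempt window.
Poses with |lean| > 85° are gimbal-proximal and flagged.

Sensor fusion is a complementary filter: forward gyro integration with
error feedback toward the accelerometer gravity direction and the
magnetometer heading (blend weight 0.98 gyro / 0.02 correction per sample,
TRIAD initialization from the first sample). The firmware filter of any
particular IMU is unpublished; the complementary filter was chosen for
testability, and the pipeline equally accepts precomputed quaternions
(fusion bypass), which is how the study-scale recovery runs are done. The
zero-noise round trip (truth → accel/gyro/mag → fusion → angles) recovers
orientation to well under 1°.

Synthetic trials are 5 s at 64 Hz, embedding one forward-lean and one
leftward-bend raised-cosine excursion of 1.5 s (the study reports no
kinematic profile; a raised cosine is smooth, bounded and differentiable, so
the synthetic gyro stream is well-defined). Peak angles are Normal draws
truncated at 0° for physical validity; with condition SDs of 5–12° around
means of 12–24° the truncation shifts means by at most ≈0.2°, far inside the
Monte-Carlo tolerance at the study scale (n = 500 trials). The generated
accelerometer carries rotated gravity only — no linear acceleration — which
overstates how informative accelerometers are during brisk motion; the
fusion tests therefore certify geometry, not dynamic-motion robustness. The
bicep sensor of the physical setup is representable in the containers but no
arm-joint angles are derived; only the two reported trunk angles are.

## DRT generation and scoring

Stimuli arrive at inter-stimulus intervals uniform on [2, 4] s. (Descriptions
of such protocols sometimes also quote 5–8 stimuli per 30-s block, which a
2–4-s spacing contradicts — it yields 8–15; the interval rule is the
generative statement and is what the package honors.) Scoring follows the ISO
convention: each button press is matched to the most recent still-unanswered
stimulus preceding it (the pairing rule is not standardized in print;
most-recent-unanswered is the conventional choice), unmatched stimuli are
misses, and latencies strictly over 2.5 s are reclassified as misses and
excluded from response-time summaries (a latency of exactly 2.5 s is valid).

The condition parameters describe *scored* behaviour, because that is what a
study reports: `rt_mean`/`rt_sd` summarize valid (≤ 2.5 s) responses and
`drt_miss_prob` includes reclassified slow responses. The generator inverts
the scoring rule: latencies are log-normal with shape fixed by the
coefficient of variation `rt_sd/rt_mean` and scale solved (1-D monotone root)
so the mean latency *conditional on being scored valid* equals `rt_mean`;
the raw non-response probability is then lowered so the total scored miss
rate equals `drt_miss_prob`. Matching the truncated SD as well is ill-posed —
under a 2.5-s cutoff the reported SDs sit at the boundary of what a truncated
log-normal can express — so the SD enters only through the shape parameter.
Behaviourally, a participant attends one stimulus at a time: a response is
emitted only if it precedes the next stimulus onset. This keeps
response-to-stimulus matching exact and is folded into the calibration by
integrating over the U(2, 4) gap distribution. Slow (> 2.5 s) responses still
occur whenever the following gap is long, so the reclassification rule is
genuinely exercised.

NASA-TLX composites are Normal draws clipped to [0, 100]; aggregation flags
pairwise differences at or above the instrument's 15-point minimum detectable
change. Sub-scale weighting is out of scope (composites only).

## Statistical battery

Two within-configuration comparisons (C+W vs C-W, R+W vs R-W) over seven
outcomes, two-sided at α = 0.05:

- **Dichotomous** (task failure, DRT miss): binomial GLM with log link, so
  the exponentiated condition coefficient is a risk ratio. IRLS is capped at
  100 iterations with interior starting values (log link needs them);
  non-convergence and boundary fitted probabilities (separation) are
  reported as flags and warnings, never silently.
- **Continuous, many observations** (forward lean, leftward bend, response
  time): OLS point estimates with HC1 sandwich covariance — the
  small-sample-corrected flavour; the flavour is a convention choice since
  "robust or sandwich" does not pin one down — and Wald inference.
- **Small-n** (attempted movements, subjective workload): Monte Carlo
  permutation test (default 10,000 draws) of the condition coefficient from
  the covariate-adjusted linear regression, two-sided
  p = (1 + #{|b*| ≥ |b|}) / (n_perm + 1). Labels are shuffled *within
  participant*, respecting the repeated-measures design; unrestricted
  shuffling would test a different (and wrong) null here.
- **Adjusted means** by marginal standardization: the model's average
  prediction over the observed covariate pattern with condition forced to
  each level, delta-method 95% CIs. In the covariate-free case this
  reproduces raw proportions exactly, which is tested.

Covariates are participant (all outcomes) and block/cycle for per-attempt and
per-stimulus outcomes, both exposed as arguments since per-outcome covariate
coding conventions vary. Condition order in the generator is a seeded,
counterbalanced 4×4 Latin-square assignment per participant. Attempt counts
per 30-s block are Poisson (minimum 1) with condition means chosen so the
expected totals match the published per-condition attempt counts over three
participants and two blocks; `attempts_mean` exists because the battery
analyses attempted movements even though no dispersion for it is published.

## Problem sizes and tolerances

Stochastic recovery tests run at the scale the analysis targets: 500
orientation trials per arm (three standard errors of a 7.6°-SD peak
distribution at n = 500 is ≈1°), ≥ 2000 DRT stimuli (≈220 blocks), 200
attempts per arm for the GLM path, 200 null replicates for permutation size
and 500 for sandwich-CI coverage. Every stochastic assertion uses a ±3-SE
band computed from the generated sample, not a hand-picked constant; exact
algebraic checks (filter magnitudes, Kalman–Bayes equivalence, HC1 algebra,
rotation orthonormality) use tolerances of 1e-6 or tighter. All generators
take explicit seeds and are bit-reproducible.

## Known limitations

- The EMG forward model is statistical, not physiological; decoder results
  certify the estimator, not clinical controllability.
- Accelerometer synthesis omits linear acceleration; magnetometer
  calibration (hard/soft iron) is out of scope.
- The exact post-hoc modifications layered on deployed Kalman controllers
  (thresholding/gain shaping, channel selection) vary by system and are not
  reproduced beyond the configurable dead-zone/gain stand-ins.
- TLX is handled as a composite; preference rankings and embodiment measures
  are out of scope, as are prosthesis hardware, sockets and real-time
  actuation.
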