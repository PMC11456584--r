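# wristcomp

Analysis pipeline for validation studies of powered prosthetic wrists, for
researchers in myoelectric control and upper-limb rehabilitation. When a
multi-articulate prosthesis study asks *"does enabling the wrist improve
dexterity, reduce compensatory trunk motion, and leave cognitive load
unchanged?"*, this package provides every computational stage of the answer:

- **EMG feature chain** — 32-channel surface EMG at 1 kHz → causal Butterworth
  band-pass (15 Hz sixth-order high-pass, 375 Hz second-order low-pass) →
  60/120/180 Hz notches → all 496 differential channel pairs → 300-ms smoothed
  mean-absolute-value features on 528 channels at 30 Hz.
- **Kalman decoder** — the linear-Gaussian state-space estimator of
  proportional myoelectric control: prior `x_t = A x_{t-1} + w`, `w ~ N(0, W)`;
  likelihood `y_t = H x_t + q`, `q ~ N(0, Q)`; recursive predict/update with
  per-DOF software locking (posterior mean and covariance of locked DOFs
  zeroed each step), ridge-regularized system identification, outputs clipped
  to [-1, 1].
- **Trunk compensation** — IMU streams (64 Hz accel/gyro/mag) → complementary-
  filter quaternions (or precomputed quaternions) → relative rotation against
  a fixed reference → forward-lean / leftward-bend angle traces → per-attempt
  maximum absolute deviation in degrees.
- **Cognitive load** — detection-response-task scoring: responses matched to
  the most recent unanswered stimulus, latencies > 2.5 s reclassified as
  misses (ISO convention), miss rate and valid-response mean RT; NASA-TLX
  aggregation with the 15-point minimum-detectable-change flag.
- **Statistical battery** — per configuration comparison (wrist on vs off):
  log-link binomial GLM (risk ratios, marginally standardized proportions)
  for dichotomous outcomes; OLS with HC1 sandwich variance
  `(n/(n-k)) (X'X)^{-1} X' diag(e^2) X (X'X)^{-1}` for continuous outcomes;
  within-participant Monte Carlo permutation tests for small-n outcomes;
  adjusted means with delta-method 95% CIs; two-sided, alpha = 0.05.
- **Synthetic study generator** — every input above, with the statistical
  structure the analysis assumes, calibrated by default to the published
  summary statistics of a three-participant cross-over study (conditions
  C-W, C+W, R-W, R+W) so the whole pipeline can be exercised and checked by
  parameter recovery.

## Worked example

Generate a study-sized synthetic dataset (3 participants x 4 conditions x
two 30-s blocks) and run the full battery:

```r
library(wristcomp)

cfg <- sim_config(seed = 1)
ds  <- generate_condition_dataset(cfg)
ds
#> Synthetic study dataset: 3 participants x 4 conditions, 102 attempts, 232 DRT stimuli

report <- run_full_battery(ds, n_perm = 2000, seed = 1)
report
#> Statistical battery (alpha = 0.05)
#>   Failure Rate         commercial C-W 0.3 (SD 0.464) vs C+W 0.37 (SD 0.492): p = 0.5231
#>   Forward Lean         commercial C-W 24.5 (SD 7.22) vs C+W 14.1 (SD 7.02): p = 1.398e-07 *
#>   Leftward Bend        commercial C-W 24.3 (SD 8.22) vs C+W 12.8 (SD 4.73): p = 4.019e-10 *
#>   DRT Miss Rate        commercial C-W 0.407 (SD 0.495) vs C+W 0.327 (SD 0.474): p = 0.265
#>   Response Time        commercial C-W 1.25 (SD 0.45) vs C+W 1.05 (SD 0.386): p = 0.07079
#>   Attempted Movements  commercial C-W 6.67 (SD 2.34) vs C+W 4.5 (SD 2.59): p = 0.2324
#>   Subjective Workload  commercial C-W 62.2 (SD 1.54) vs C+W 48.8 (SD 5.93): p = 0.2584
#>   Failure Rate         research   R-W 0.714 (SD 0.463) vs R+W 0.5 (SD 0.519): p = 0.9872
#>   Forward Lean         research   R-W 24 (SD 10.9) vs R+W 9.36 (SD 3.1): p = 0.0001614 *
#>   Leftward Bend        research   R-W 15.3 (SD 5.82) vs R+W 15.3 (SD 7.5): p = 0.9406
#>   DRT Miss Rate        research   R-W 0.458 (SD 0.502) vs R+W 0.271 (SD 0.448): p = 0.04051 *
#>   Response Time        research   R-W 0.991 (SD 0.462) vs R+W 0.979 (SD 0.503): p = 0.8964
#>   Attempted Movements  research   R-W 3.5 (SD 2.81) vs R+W 2.33 (SD 1.37): p = 0.4398
#>   Subjective Workload  research   R-W 66 (SD 9.03) vs R+W 68.3 (SD 5.23): p = 0.7511
```

Each row reports raw mean (SD) per arm and the p-value of the condition
effect from the outcome's designated model (GLM / sandwich linear model /
permutation test). At this small study size the forward-lean reduction is
already unambiguous in both configurations; note also how the covariate-
adjusted research-arm Failure Rate p-value (0.99) disagrees with the raw
means (0.71 vs 0.50) — participant composition confounds the raw comparison,
which is exactly why the battery adjusts for participant.

Compensation angles recover their calibrated distribution through the full
quaternion → rotation-matrix → angle chain:

```r
cw     <- default_condition_params()[["C-W"]]
trials <- generate_orientation_trace(cw, 500, cfg, seed = 1)
m      <- sapply(trials, function(tr) compensation_maxima(tr$sensor, tr$reference))
sprintf("mean max forward lean: %.1f deg (SD %.1f)", mean(m[1, ]), sd(m[1, ]))
#> "mean max forward lean: 23.8 deg (SD 7.7)"
```

Decoder training and software wrist locking:

```r
mix  <- mixing_model(n_channels = 8, noise_sd = 0.02)
sess <- generate_training_session(sim_config(seed = 3), mix)
tf   <- training_frames(sess)            # 528-like feature/kinematics pairs
m    <- mkf(tf$features, tf$kinematics)  # Kalman system identification
dec  <- predict(m, tf$features, locked = c(FALSE, TRUE, TRUE))  # wrist locked
```

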