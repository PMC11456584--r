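# synthetic-study generator: protocol structure, calibration, determinism

test_that("training session follows the mimicry protocol", {
  cfg <- sim_config(seed = 2)
  mix <- mixing_model(n_channels = 4, noise_sd = 0)
  sess <- generate_training_session(cfg, mix, bump_duration = 0.4, gap = 0.1)
  ann <- sess$annotation
  # four repetitions of each of the three single-DOF motions
  expect_equal(sum(ann$type == "single"), 3 * 4)
  expect_equal(as.integer(table(ann$label[ann$type == "single"])), rep(4L, 3))
  # two repetitions of each ordered hand/wrist sequential pair
  expect_equal(sum(ann$type == "pair"), 2 * 8)
  expect_equal(length(unique(ann$label[ann$type == "pair"])), 8)
  expect_true(all(abs(sess$kinematics) <= 1))
  expect_equal(ncol(sess$kinematics), 3)
})

test_that("noiseless EMG envelope is exactly linear in the activations", {
  mix <- mixing_model(n_channels = 4, noise_sd = 0)
  kin <- cbind(seq(0, 1, length.out = 2000) * sin(seq(0, 6, length.out = 2000)),
               0.3, -0.5)
  half <- synthesize_emg(kin / 2, mix, fs = 1000, seed = 9)
  full <- synthesize_emg(kin, mix, fs = 1000, seed = 9)
  expect_equal(full$samples, 2 * half$samples, tolerance = 1e-12)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 4)
  mix <- mixing_model(n_channels = 3, noise_sd = 0.05)
  s1 <- generate_training_session(cfg, mix, bump_duration = 0.3, gap = 0.1)
  s2 <- generate_training_session(cfg, mix, bump_duration = 0.3, gap = 0.1)
  expect_identical(s1$emg$samples, s2$emg$samples)
  l1 <- generate_drt_log(default_params[["C-W"]], cfg, seed = 77)
  l2 <- generate_drt_log(default_params[["C-W"]], cfg, seed = 77)
  expect_identical(l1, l2)
  t1 <- generate_orientation_trace(default_params[["R+W"]], 3, cfg, seed = 5)
  t2 <- generate_orientation_trace(default_params[["R+W"]], 3, cfg, seed = 5)
  expect_identical(t1[[2]]$sensor$quaternions, t2[[2]]$sensor$quaternions)
})

test_that("orientation trials embed the requested excursions", {
  p0 <- condition_params("C-W", 20, 0, 12, 0, .3, .4, 1.2, .7, 60, 3)
  trials <- generate_orientation_trace(p0, 4, seed = 8)
  for (tr in trials) {
    expect_equal(tr$truth$peak_lean, 20)
    expect_equal(tr$truth$peak_bend, 12)
    expect_equal(max(tr$truth$lean), 20, tolerance = 1e-6)
    # quaternions unit-norm; reference constant
    expect_true(all(abs(sqrt(rowSums(tr$sensor$quaternions^2)) - 1) < 1e-9))
    expect_true(all(apply(tr$reference$quaternions, 2, function(col)
      all(col == col[1]))))
  }
  expect_error(generate_orientation_trace(p0, 0), "n_trials")
})

test_that("generated peak angles converge to the condition parameters", {
  cw <- default_params[["C-W"]]
  trials <- generate_orientation_trace(cw, 2000, seed = 123)
  peaks <- vapply(trials, function(tr) tr$truth$peak_lean, 0)
  se <- cw$lean_sd / sqrt(2000)
  expect_lt(abs(mean(peaks) - cw$lean_mean), 3 * se)
  bends <- vapply(trials, function(tr) tr$truth$peak_bend, 0)
  expect_lt(abs(mean(bends) - cw$bend_mean), 3 * cw$bend_sd / sqrt(2000))
})

test_that("DRT logs obey the stimulus schedule and miss calibration", {
  cfg <- sim_config()
  log <- generate_drt_log(default_params[["C+W"]], cfg, seed = 3)
  gaps <- diff(log$stimulus_times)
  expect_true(all(gaps >= 2 & gaps <= 4))
  expect_true(all(log$stimulus_times <= cfg$block_duration))
  # certain miss: stimuli present, no responses
  p_all_miss <- condition_params("C-W", 20, 5, 10, 3, .3, 1, 1.2, .7, 60, 3)
  log2 <- generate_drt_log(p_all_miss, cfg, seed = 3)
  expect_gt(length(log2$stimulus_times), 0)
  expect_length(log2$response_times, 0)
})

test_that("attempt outcomes and TLX respect their bounds and calibration", {
  cfg <- sim_config(seed = 6)
  p_never <- condition_params("C-W", 20, 5, 10, 3, 0, .4, 1.2, .7, 60, 3)
  att0 <- generate_attempt_outcomes(p_never, 50, cfg, seed = 2)
  expect_true(all(att0$failure == 0))
  rw <- default_params[["R-W"]]
  att <- generate_attempt_outcomes(rw, 1000, cfg, seed = 21)
  se <- sqrt(0.7 * 0.3 / 1000)
  expect_lt(abs(mean(att$failure) - rw$failure_prob), 3 * se)
  ds <- generate_condition_dataset(sim_config(seed = 11))
  expect_true(all(ds$tlx$tlx >= 0 & ds$tlx$tlx <= 100))
  # counterbalanced cross-over: every participant sees each condition once
  tab <- table(ds$order$participant, ds$order$condition)
  expect_true(all(tab == 1))
  ds2 <- generate_condition_dataset(sim_config(seed = 11))
  expect_identical(ds$attempts, ds2$attempts)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(block_duration = 0))
  expect_error(sim_config(imu_fs = -64))
  expect_error(condition_params("C-W", 20, -1, 10, 3, .3, .4, 1.2, .7, 60, 3))
  expect_error(condition_params("C-W", 20, 5, 10, 3, 1.4, .4, 1.2, .7, 60, 3))
  cfg <- sim_config()
  expect_error(generate_training_session(cfg, mixing_model(4),
                                         bump_duration = -1), "bump_duration")
})
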