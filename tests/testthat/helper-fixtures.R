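# small shared fixtures, built in code

default_params <- default_condition_params()

small_config <- function(seed = 1L) sim_config(seed = seed)

# steady-state amplitude of a filtered unit sinusoid: RMS over the last
# stretch of a long record, times sqrt(2)
steady_state_amplitude <- function(filter_fun, freq, fs = 1000,
                                   duration = 4) {
  t <- seq(0, duration, by = 1 / fs)
  rec <- emg_recording(matrix(sin(2 * pi * freq * t), ncol = 1), fs)
  out <- filter_fun(rec)$samples[, 1]
  tail_part <- out[(length(out) / 2):length(out)]
  sqrt(2) * sqrt(mean(tail_part^2))
}

# scored DRT aggregate over many blocks
score_blocks <- function(params, n_blocks, seed, config = sim_config()) {
  miss <- 0L; n <- 0L; rts <- numeric(0)
  for (b in seq_len(n_blocks)) {
    s <- score_drt(generate_drt_log(params, config, seed = seed + b))
    miss <- miss + (s$n_stimuli - s$n_valid)
    n <- n + s$n_stimuli
    rts <- c(rts, s$latency[!is.na(s$latency)])
  }
  list(n = n, miss_rate = miss / n, mean_rt = mean(rts), rts = rts)
}

# mean compensation maxima over generated trials, through the angle pipeline
compensation_means <- function(params, n_trials, seed,
                               config = sim_config()) {
  trials <- generate_orientation_trace(params, n_trials, config, seed = seed)
  m <- vapply(trials, function(tr) {
    compensation_maxima(tr$sensor, tr$reference)
  }, c(max_forward_lean = 0, max_leftward_bend = 0))
  list(lean = m["max_forward_lean", ], bend = m["max_leftward_bend", ])
}
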