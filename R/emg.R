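#' EMG containers and the 528-channel feature chain
#'
#' Raw 32-channel surface EMG sampled at 1 kHz is band-pass filtered (15 Hz
#' sixth-order high-pass, 375 Hz second-order low-pass Butterworth, applied
#' causally), notch filtered at 60/120/180 Hz, expanded with all C(n, 2)
#' differential channel pairs, and summarized as the mean absolute value (MAV)
#' over a trailing 300-ms window at 30 Hz. For 32 input channels this yields
#' 32 single-ended + 496 differential = 528 feature channels.
#'
#' @name emg
NULL

#' Construct an EMG recording
#'
#' @param samples numeric matrix, time x channels, signed amplitude
#' @param fs sampling rate, Hz
#' @param channel_labels optional channel names
#' @return object of class \code{"emg_recording"}
#' @export
emg_recording <- function(samples, fs, channel_labels = NULL) {
  samples <- as.matrix(samples)
  stopifnot(is.numeric(samples), nrow(samples) >= 1, fs > 0)
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(ncol(samples)))
  }
  stopifnot(length(channel_labels) == ncol(samples))
  structure(list(samples = samples, fs = fs, channel_labels = channel_labels),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("EMG recording: %d samples x %d channels at %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              nrow(x$samples) / x$fs))
  invisible(x)
}

#' Causal Butterworth band-pass for surface EMG
#'
#' Cascade of a sixth-order high-pass at 15 Hz and a second-order low-pass at
#' 375 Hz, run as single-pass (causal) IIR filters per channel, matching an
#' online controller.
#'
#' @param rec an [emg_recording()]
#' @param high_cut high-pass cutoff, Hz
#' @param low_cut low-pass cutoff, Hz
#' @return filtered [emg_recording()]
#' @export
bandpass_emg <- function(rec, high_cut = 15, low_cut = 375) {
  stopifnot(inherits(rec, "emg_recording"))
  nyq <- rec$fs / 2
  if (low_cut >= nyq) {
    stop("low-pass cutoff ", low_cut, " Hz is at or above Nyquist (", nyq,
         " Hz); need fs > ", 2 * low_cut, " Hz")
  }
  hp <- signal::butter(6, high_cut / nyq, type = "high")
  lp <- signal::butter(2, low_cut / nyq, type = "low")
  out <- apply(rec$samples, 2, function(x) {
    signal::filter(lp, signal::filter(hp, x))
  })
  emg_recording(out, rec$fs, rec$channel_labels)
}

# RBJ biquad notch coefficients at f0 with quality factor Q
notch_coefficients <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Power-line notch filters
#'
#' Second-order IIR notches (quality factor \code{Q}, default 30, i.e. about
#' 2 Hz bandwidth at 60 Hz) applied causally at each frequency in
#' \code{freqs}.
#'
#' @param rec an [emg_recording()]
#' @param freqs notch centre frequencies, Hz
#' @param Q notch quality factor
#' @return filtered [emg_recording()]
#' @export
notch_emg <- function(rec, freqs = c(60, 120, 180), Q = 30) {
  stopifnot(inherits(rec, "emg_recording"), all(freqs < rec$fs / 2))
  out <- rec$samples
  for (f0 in freqs) {
    co <- notch_coefficients(f0, rec$fs, Q)
    out <- apply(out, 2, function(x) {
      as.numeric(signal::filter(co$b, co$a, x))
    })
  }
  emg_recording(out, rec$fs, rec$channel_labels)
}

#' All differential channel pairs
#'
#' For n input channels, returns the C(n, 2) differences
#' \code{channel_i - channel_j} for all unordered pairs (i, j), i < j, in
#' lexicographic order; 32 channels yield 496 differential recordings.
#'
#' @param rec an [emg_recording()] with at least 2 channels
#' @return [emg_recording()] with \code{choose(n, 2)} channels
#' @export
differential_pairs <- function(rec) {
  stopifnot(inherits(rec, "emg_recording"))
  n <- ncol(rec$samples)
  if (n < 2) stop("need at least 2 channels to form differential pairs")
  pairs <- utils::combn(n, 2)
  out <- rec$samples[, pairs[1, ], drop = FALSE] -
    rec$samples[, pairs[2, ], drop = FALSE]
  labels <- paste0(rec$channel_labels[pairs[1, ]], "-",
                   rec$channel_labels[pairs[2, ]])
  emg_recording(out, rec$fs, labels)
}

#' Construct a feature stream
#'
#' @param frames numeric matrix, frames x channels, non-negative MAV values
#' @param rate frame rate, Hz
#' @param channel_labels feature channel names
#' @return object of class \code{"feature_stream"}
#' @export
feature_stream <- function(frames, rate, channel_labels = NULL) {
  frames <- as.matrix(frames)
  stopifnot(rate > 0, all(frames >= -1e-12))
  if (is.null(channel_labels)) {
    channel_labels <- paste0("f", seq_len(ncol(frames)))
  }
  structure(list(frames = frames, rate = rate,
                 channel_labels = channel_labels),
            class = "feature_stream")
}

#' @export
print.feature_stream <- function(x, ...) {
  cat(sprintf("Feature stream: %d frames x %d channels at %g Hz\n",
              nrow(x$frames), ncol(x$frames), x$rate))
  invisible(x)
}

#' Smoothed mean-absolute-value features
#'
#' Frame k (at time k/rate) carries, per channel, the mean of |signal| over
#' the trailing \code{window} seconds: the windows overlap because 300 ms
#' exceeds the 33.3-ms frame step. Frames earlier than one full window use
#' the partial data available so the stream stays aligned with kinematics
#' from the first frame.
#'
#' @param filtered an [emg_recording()] of single-ended channels
#' @param pairs optional [emg_recording()] of differential channels at the
#'   same rate (column-bound after the single-ended channels)
#' @param rate feature frame rate, Hz
#' @param window MAV window length, seconds
#' @return a [feature_stream()]
#' @export
mav_features <- function(filtered, pairs = NULL, rate = 30, window = 0.3) {
  stopifnot(inherits(filtered, "emg_recording"), rate > 0,
            window >= 1 / rate)
  x <- filtered$samples
  labels <- filtered$channel_labels
  if (!is.null(pairs)) {
    stopifnot(inherits(pairs, "emg_recording"),
              nrow(pairs$samples) == nrow(x), pairs$fs == filtered$fs)
    x <- cbind(x, pairs$samples)
    labels <- c(labels, pairs$channel_labels)
  }
  fs <- filtered$fs
  n <- nrow(x)
  if (n == 0) stop("empty input")
  n_frames <- floor(n / fs * rate + 1e-9)
  if (n_frames < 1) stop("input shorter than one feature frame")
  # cumulative sums of |x| let each trailing-window mean be a difference
  cs <- apply(abs(x), 2, cumsum)
  cs <- rbind(0, cs)
  k <- seq_len(n_frames)
  hi <- pmin(floor(k / rate * fs + 1e-9), n)
  lo <- pmax(floor((k / rate - window) * fs + 1e-9), 0)
  frames <- (cs[hi + 1, , drop = FALSE] - cs[lo + 1, , drop = FALSE]) /
    (hi - lo)
  feature_stream(frames, rate, labels)
}

#' Full EMG feature chain
#'
#' Composition band-pass -> notch -> \{identity, differential pairs\} -> MAV.
#' MAV is computed on the already-filtered signals for both single-ended and
#' differential channels (differencing and linear filtering commute). A
#' 32-channel recording yields a 528-channel stream.
#'
#' @param raw an [emg_recording()]
#' @inheritParams mav_features
#' @return a [feature_stream()] with \code{n + choose(n, 2)} channels
#' @examples
#' rec <- emg_recording(matrix(rnorm(4000 * 4), ncol = 4), fs = 1000)
#' fs <- extract_features(rec)
#' dim(fs$frames)  # 120 frames x 10 channels
#' @export
extract_features <- function(raw, rate = 30, window = 0.3) {
  filt <- notch_emg(bandpass_emg(raw))
  mav_features(filt, differential_pairs(filt), rate = rate, window = window)
}
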