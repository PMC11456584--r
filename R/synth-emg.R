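#' Synthetic surface EMG driven by kinematic intent
#'
#' A forward mixing model stands in for muscle physiology so the decoder has a
#' recoverable ground truth: each of the 6 activation sources (the positive
#' and negative directions of the 3 DOFs: pinch, pronation/supination,
#' flexion/extension) projects onto the recording channels through a
#' non-negative gain matrix. The raw EMG is a band-limited Gaussian carrier
#' amplitude-modulated by the summed activation envelope, plus additive
#' white noise. With \code{noise_sd = 0} the rectified envelope of the
#' generated EMG is exactly linear in the activation vector.
#'
#' @name synth_emg
NULL

# smooth non-negative default gains: one Gaussian bump of channels per source
default_gain_matrix <- function(n_channels, n_sources = 6) {
  centers <- (seq_len(n_sources) - 0.5) * n_channels / n_sources
  width <- n_channels / (2 * n_sources)
  g <- outer(seq_len(n_channels), centers,
             function(c, mu) exp(-((c - mu) / width)^2))
  g / max(g)
}

#' Construct an EMG mixing model
#'
#' @param n_channels number of recording channels (study: 32)
#' @param gain_matrix optional \code{n_channels x 6} non-negative gain matrix;
#'   defaults to smooth per-source channel tuning
#' @param noise_sd additive white-noise SD per channel
#' @param carrier_band band limits of the Gaussian carrier, Hz
#' @param carrier_order Butterworth order of the carrier band-pass
#' @return object of class \code{"mixing_model"}
#' @export
mixing_model <- function(n_channels = 32, gain_matrix = NULL,
                         noise_sd = 0.05, carrier_band = c(20, 350),
                         carrier_order = 4) {
  if (is.null(gain_matrix)) gain_matrix <- default_gain_matrix(n_channels)
  gain_matrix <- as.matrix(gain_matrix)
  stopifnot(nrow(gain_matrix) == n_channels, ncol(gain_matrix) == 6,
            all(gain_matrix >= 0), noise_sd >= 0,
            length(carrier_band) == 2, carrier_band[1] > 0,
            carrier_band[1] < carrier_band[2])
  structure(list(n_channels = as.integer(n_channels),
                 gain_matrix = gain_matrix, noise_sd = noise_sd,
                 carrier_band = carrier_band, carrier_order = carrier_order),
            class = "mixing_model")
}

# signed 3-DOF kinematics -> 6 non-negative activation sources
kinematics_to_activation <- function(kin) {
  kin <- as.matrix(kin)
  stopifnot(ncol(kin) == 3)
  cbind(pmax(kin[, 1], 0), pmax(-kin[, 1], 0),
        pmax(kin[, 2], 0), pmax(-kin[, 2], 0),
        pmax(kin[, 3], 0), pmax(-kin[, 3], 0))
}

# band-limited unit-RMS Gaussian carrier, one column per channel
emg_carrier <- function(n, n_channels, fs, band, order) {
  bp <- signal::butter(order, band / (fs / 2), type = "pass")
  x <- matrix(stats::rnorm(n * n_channels), n, n_channels)
  x <- apply(x, 2, function(col) as.numeric(signal::filter(bp, col)))
  x <- matrix(x, n, n_channels)
  sweep(x, 2, pmax(sqrt(colMeans(x^2)), 1e-12), "/")
}

#' Synthesize EMG from a kinematic trace
#'
#' @param kin n x 3 kinematic trace, each DOF in \[-1, 1\]
#' @param mix a [mixing_model()]
#' @param fs sampling rate, Hz
#' @param seed integer seed (carrier and noise)
#' @return an [emg_recording()]
#' @export
synthesize_emg <- function(kin, mix, fs = 1000, seed = 1L) {
  stopifnot(inherits(mix, "mixing_model"))
  kin <- as.matrix(kin)
  if (max(abs(kin)) > 1 + 1e-9) stop("kinematics must lie in [-1, 1]")
  n <- nrow(kin)
  envelope <- kinematics_to_activation(kin) %*% t(mix$gain_matrix)
  with_local_seed(seed, {
    carrier <- emg_carrier(n, mix$n_channels, fs, mix$carrier_band,
                           mix$carrier_order)
    x <- carrier * envelope
    if (mix$noise_sd > 0) {
      x <- x + matrix(stats::rnorm(n * mix$n_channels, 0, mix$noise_sd),
                      n, mix$n_channels)
    }
    emg_recording(x, fs)
  })
}

# one raised-cosine kinematic bump on a DOF; amplitude +/- 1
kin_bump_segment <- function(n_dof, dof, sign, n_samples) {
  u <- seq(0, 1, length.out = n_samples)
  seg <- matrix(0, n_samples, n_dof)
  seg[, dof] <- sign * 0.5 * (1 - cos(2 * pi * u))
  seg
}

# training protocol: returns kinematics matrix + segment annotation
training_protocol <- function(fs, bump_duration, gap, reps_single = 4,
                              reps_pair = 2) {
  nb <- round(bump_duration * fs)
  ng <- round(gap * fs)
  n_dof <- 3
  motions <- list(  # signed single-direction bumps
    pinch_close = c(1, 1), pinch_open = c(1, -1),
    pronate = c(2, 1), supinate = c(2, -1),
    flex = c(3, 1), extend = c(3, -1)
  )
  segs <- list()
  ann <- list()
  add_segment <- function(kin, type, label) {
    segs[[length(segs) + 1]] <<- rbind(kin, matrix(0, ng, n_dof))
    ann[[length(ann) + 1]] <<- data.frame(type = type, label = label)
  }
  # four repetitions of each full motion (both directions of each DOF)
  single_labels <- c("pinch open/close", "pronate/supinate", "flex/extend")
  for (rep in seq_len(reps_single)) {
    for (dof in 1:3) {
      kin <- rbind(kin_bump_segment(n_dof, dof, 1, nb),
                   kin_bump_segment(n_dof, dof, -1, nb))
      add_segment(kin, "single", single_labels[dof])
    }
  }
  # two repetitions of each ordered hand/wrist sequential pair
  hand <- "pinch_close"
  wrist <- c("pronate", "supinate", "flex", "extend")
  pairs <- c(lapply(wrist, function(w) c(hand, w)),
             lapply(wrist, function(w) c(w, hand)))
  for (rep in seq_len(reps_pair)) {
    for (p in pairs) {
      kin <- do.call(rbind, lapply(p, function(m) {
        kin_bump_segment(n_dof, motions[[m]][1], motions[[m]][2], nb)
      }))
      add_segment(kin, "pair", paste(p, collapse = " then "))
    }
  }
  kin <- do.call(rbind, c(list(matrix(0, ng, n_dof)), segs))
  ann <- do.call(rbind, ann)
  ann$segment <- seq_len(nrow(ann))
  lens <- vapply(segs, nrow, 0L)
  ann$t_start <- (ng + c(0, cumsum(lens))[seq_along(lens)]) / fs
  ann$t_end <- (ng + cumsum(lens) - ng) / fs
  list(kinematics = kin, annotation = ann)
}

#' Generate a decoder-training session
#'
#' Builds the mimicry protocol -- four repetitions of each single-DOF motion
#' (pinch open/close, pronate/supinate, flex/extend) plus two repetitions of
#' each ordered sequential pair of one hand motion and one wrist motion -- as
#' a raised-cosine kinematic trace in \[-1, 1\], and synthesizes EMG from it
#' through the mixing model.
#'
#' @param config a [sim_config()] (supplies the EMG sampling rate and seed)
#' @param mix a [mixing_model()]
#' @param seed integer seed
#' @param bump_duration duration of one movement bump, seconds
#' @param gap rest between segments, seconds
#' @return object of class \code{"training_session"}: list with \code{emg}
#'   (an [emg_recording()]), \code{kinematics} (n x 3 matrix at the EMG rate),
#'   \code{annotation} (per-segment type/label/times) and \code{fs}
#' @export
generate_training_session <- function(config = sim_config(),
                                      mix = mixing_model(),
                                      seed = config$seed,
                                      bump_duration = 1, gap = 0.25) {
  stopifnot(inherits(config, "sim_config"), inherits(mix, "mixing_model"))
  if (bump_duration <= 0) stop("bump_duration must be positive")
  if (gap < 0) stop("gap must be non-negative")
  proto <- training_protocol(config$emg_fs, bump_duration, gap)
  emg <- synthesize_emg(proto$kinematics, mix, config$emg_fs, seed)
  structure(list(emg = emg, kinematics = proto$kinematics,
                 annotation = proto$annotation, fs = config$emg_fs),
            class = "training_session")
}

#' @export
print.training_session <- function(x, ...) {
  cat(sprintf(
    "Training session: %.1f s at %g Hz, %d channels, %d segments (%d single, %d paired)\n",
    nrow(x$kinematics) / x$fs, x$fs, ncol(x$emg$samples),
    nrow(x$annotation), sum(x$annotation$type == "single"),
    sum(x$annotation$type == "pair")))
  invisible(x)
}

#' Resample a kinematic trace to the feature frame rate
#'
#' Takes the kinematic sample at each feature frame time k/rate - lag so
#' decoder training sees features and kinematics on a common clock. The
#' default \code{lag} of 0.15 s is half the 300-ms MAV window: a trailing
#' window summarizes activity centred that far in the past, so shifting the
#' kinematics by the window's group delay aligns intent with the features.
#'
#' @param kin n x d kinematic matrix sampled at \code{fs}
#' @param fs kinematic sampling rate, Hz
#' @param rate target frame rate, Hz
#' @param n_frames number of frames (default: as many as fit)
#' @param lag alignment lag, seconds
#' @return n_frames x d matrix
#' @export
kinematics_at_rate <- function(kin, fs, rate = 30, n_frames = NULL,
                               lag = 0.15) {
  kin <- as.matrix(kin)
  if (is.null(n_frames)) n_frames <- floor(nrow(kin) / fs * rate + 1e-9)
  idx <- pmin(pmax(round((seq_len(n_frames) / rate - lag) * fs), 1),
              nrow(kin))
  kin[idx, , drop = FALSE]
}

#' Feature/kinematics training pairs from a session
#'
#' Runs the full EMG feature chain on the session's recording and aligns the
#' kinematic trace to the feature frames (see [kinematics_at_rate()]).
#'
#' @param session a [generate_training_session()] result
#' @param rate feature frame rate, Hz
#' @param window MAV window, seconds
#' @return list with \code{features} (a [feature_stream()]) and
#'   \code{kinematics} (aligned frames x 3 matrix)
#' @export
training_frames <- function(session, rate = 30, window = 0.3) {
  stopifnot(inherits(session, "training_session"))
  feats <- extract_features(session$emg, rate = rate, window = window)
  kin <- kinematics_at_rate(session$kinematics, session$fs, rate,
                            nrow(feats$frames), lag = window / 2)
  list(features = feats, kinematics = kin)
}
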