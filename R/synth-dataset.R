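#' Synthetic study datasets
#'
#' Bundles everything the statistical battery consumes: per-attempt clothespin
#' outcomes with compensation maxima run through the quaternion -> rotation
#' matrix -> angle pipeline, per-stimulus DRT scoring rows, per-condition
#' NASA-TLX composites, and the counterbalanced condition order.
#'
#' @name synth_dataset
NULL

#' Generate Bernoulli attempt outcomes for one condition
#'
#' @param params a [condition_params()]
#' @param n_attempts total attempts to draw across participants
#' @param config a [sim_config()] (supplies the participant count)
#' @param seed integer seed
#' @return data frame with columns \code{participant}, \code{condition},
#'   \code{attempt}, \code{success}, \code{failure}
#' @export
generate_attempt_outcomes <- function(params, n_attempts,
                                      config = sim_config(),
                                      seed = config$seed) {
  stopifnot(inherits(params, "condition_params"), n_attempts >= 1)
  with_local_seed(seed, {
    participant <- sort(rep_len(seq_len(config$n_participants), n_attempts))
    failure <- stats::rbinom(n_attempts, 1, params$failure_prob)
    data.frame(participant = factor(participant),
               condition = params$label,
               attempt = seq_len(n_attempts),
               success = 1L - failure,
               failure = failure)
  })
}

# counterbalanced condition order: participants cycle through the rows of a
# balanced 4 x 4 latin square, with the row assignment seeded-shuffled
counterbalanced_order <- function(n_participants, labels, seed) {
  square <- rbind(c(1, 2, 4, 3), c(2, 3, 1, 4), c(3, 4, 2, 1), c(4, 1, 3, 2))
  with_local_seed(seed, {
    rows <- rep_len(sample(4), n_participants)
    do.call(rbind, lapply(seq_len(n_participants), function(p) {
      data.frame(participant = factor(p, levels = seq_len(n_participants)),
                 period = seq_along(labels),
                 condition = labels[square[rows[p], ]])
    }))
  })
}

#' Generate a full synthetic study dataset
#'
#' For every participant x condition x block: attempt counts are Poisson
#' (mean \code{attempts_mean}, at least 1); each attempt gets a Bernoulli
#' failure outcome and an orientation trial whose compensation maxima are
#' measured through the angle-extraction pipeline; each block gets a DRT log
#' scored with the 2.5-s rule; each participant x condition gets a NASA-TLX
#' composite (Normal, clipped to \[0, 100\]). Condition order is
#' pseudo-randomized and counterbalanced across participants.
#'
#' @param config a [sim_config()]
#' @param trial_duration per-attempt duration for orientation trials, seconds
#' @return object of class \code{"condition_dataset"}: list of data frames
#'   \code{attempts} (participant, condition, block, attempt, success,
#'   failure, max_lean, max_bend), \code{drt} (one row per stimulus: miss
#'   flag, latency of valid responses), \code{tlx}, \code{order}, plus the
#'   generating \code{config}
#' @export
generate_condition_dataset <- function(config = sim_config(),
                                       trial_duration = 5) {
  stopifnot(inherits(config, "sim_config"))
  labels <- names(config$condition_params)
  order <- counterbalanced_order(config$n_participants, labels,
                                 derive_seed(config$seed, 1))
  attempts <- list()
  drt <- list()
  tlx <- list()
  for (p in seq_len(config$n_participants)) {
    for (ci in seq_along(labels)) {
      cond <- labels[ci]
      par <- config$condition_params[[cond]]
      tlx_seed <- derive_seed(config$seed, p, ci, 0)
      tlx[[length(tlx) + 1]] <- data.frame(
        participant = factor(p, levels = seq_len(config$n_participants)),
        condition = cond,
        tlx = with_local_seed(tlx_seed,
          min(100, max(0, stats::rnorm(1, par$tlx_mean, par$tlx_sd))))
      )
      for (b in seq_len(config$n_blocks_per_condition)) {
        bseed <- derive_seed(config$seed, p, ci, b)
        n_att <- with_local_seed(bseed,
                                 max(1L, stats::rpois(1, par$attempts_mean)))
        fail <- with_local_seed(derive_seed(bseed, 2),
                                stats::rbinom(n_att, 1, par$failure_prob))
        trials <- generate_orientation_trace(par, n_att, config,
                                             seed = derive_seed(bseed, 3),
                                             trial_duration = trial_duration)
        comp <- t(vapply(trials, function(tr) {
          compensation_maxima(tr$sensor, tr$reference)
        }, c(max_forward_lean = 0, max_leftward_bend = 0)))
        attempts[[length(attempts) + 1]] <- data.frame(
          participant = factor(p, levels = seq_len(config$n_participants)),
          condition = cond, block = b, attempt = seq_len(n_att),
          success = 1L - fail, failure = fail,
          max_lean = comp[, "max_forward_lean"],
          max_bend = comp[, "max_leftward_bend"])
        log <- generate_drt_log(par, config, seed = derive_seed(bseed, 4))
        sc <- score_drt(log)
        drt[[length(drt) + 1]] <- data.frame(
          participant = factor(p, levels = seq_len(config$n_participants)),
          condition = cond, block = b,
          stimulus = seq_len(sc$n_stimuli),
          miss = as.integer(is.na(sc$latency)),
          latency = sc$latency)
      }
    }
  }
  structure(
    list(attempts = do.call(rbind, attempts),
         drt = do.call(rbind, drt),
         tlx = do.call(rbind, tlx),
         order = order,
         config = config),
    class = "condition_dataset"
  )
}

#' @export
print.condition_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic study dataset: %d participants x %d conditions, %d attempts, %d DRT stimuli\n",
    nlevels(x$attempts$participant),
    length(unique(x$attempts$condition)),
    nrow(x$attempts), nrow(x$drt)))
  invisible(x)
}
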