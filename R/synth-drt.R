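#' Synthetic detection-response-task logs
#'
#' Stimuli arrive with inter-stimulus intervals uniform on \[2, 4\] s. A
#' participant attends one stimulus at a time: a response is emitted only if
#' its latency is shorter than the wait to the next stimulus (the pending
#' stimulus is abandoned once a new one arrives). Responses may still exceed
#' the 2.5-s scoring cutoff (when the following gap is longer), so the
#' reclassification rule is exercised.
#'
#' The condition parameters describe the SCORED behaviour (what [score_drt()]
#' reports): \code{rt_mean}/\code{rt_sd} are the mean/SD of latencies over
#' valid (<= 2.5 s) responses and \code{drt_miss_prob} is the scored miss rate
#' including non-responses, abandoned stimuli and reclassified slow responses.
#' The generator calibrates itself against those targets: latencies are
#' log-normal with shape set by the coefficient of variation
#' \code{rt_sd / rt_mean} and scale solved so the mean latency conditional on
#' being scored valid equals \code{rt_mean}; the raw non-response probability
#' is then lowered so the total scored miss rate equals \code{drt_miss_prob}.
#'
#' @name synth_drt
NULL

# E[X 1{X <= u}] for X ~ lognormal(mu, sigma)
lnorm_partial_mean <- function(u, mu, sigma) {
  exp(mu + sigma^2 / 2) * stats::pnorm((log(u) - mu - sigma^2) / sigma)
}

# moments of the scored-valid latency X | X <= min(G, cutoff), G ~ U(gap),
# and the probability of the complement (abandoned or reclassified)
valid_latency_stats <- function(mu, sigma, cutoff = 2.5, gap = c(2, 4)) {
  thr_cdf_mean <- function(f) {
    # E_G[ f(min(G, cutoff)) ] for G ~ U(gap[1], gap[2])
    if (cutoff <= gap[1]) return(f(cutoff))
    hi <- min(cutoff, gap[2])
    w_tail <- (gap[2] - hi) / (gap[2] - gap[1])
    int <- stats::integrate(function(u) vapply(u, f, 0), gap[1], hi,
                            rel.tol = 1e-10)$value / (gap[2] - gap[1])
    int + w_tail * f(cutoff)
  }
  p_valid <- thr_cdf_mean(function(u) stats::pnorm((log(u) - mu) / sigma))
  m_valid <- thr_cdf_mean(function(u) lnorm_partial_mean(u, mu, sigma))
  list(p_over = 1 - p_valid, mean_valid = m_valid / p_valid)
}

.calibration_cache <- new.env(parent = emptyenv())

# calibrate the latency log-normal and raw non-response probability against
# the scored targets; cached per parameter tuple
calibrate_drt <- function(rt_mean, rt_sd, miss_prob, cutoff = 2.5,
                          gap = c(2, 4)) {
  key <- paste(rt_mean, rt_sd, miss_prob, cutoff, gap[1], gap[2], sep = "|")
  if (!is.null(.calibration_cache[[key]])) return(.calibration_cache[[key]])
  stopifnot(rt_mean > 0, rt_mean < cutoff)
  if (rt_sd == 0) {
    # degenerate latency: abandoned only if the gap is shorter than rt_mean
    p_over <- if (rt_mean <= gap[1]) 0
              else (min(rt_mean, min(cutoff, gap[2])) - gap[1]) /
                     (gap[2] - gap[1])
    out <- list(mu = log(rt_mean), sigma = 0, p_over = p_over,
                p0 = min(1, max(0, (miss_prob - p_over) / (1 - p_over))))
    .calibration_cache[[key]] <- out
    return(out)
  }
  sigma <- sqrt(log(1 + (rt_sd / rt_mean)^2))
  root <- stats::uniroot(
    function(mu) {
      valid_latency_stats(mu, sigma, cutoff, gap)$mean_valid - rt_mean
    },
    lower = log(rt_mean) - 3 * sigma^2 - 2, upper = log(cutoff) + 5 * sigma,
    tol = 1e-12
  )
  mu <- root$root
  p_over <- valid_latency_stats(mu, sigma, cutoff, gap)$p_over
  out <- list(mu = mu, sigma = sigma, p_over = p_over,
              p0 = min(1, max(0, (miss_prob - p_over) / (1 - p_over))))
  .calibration_cache[[key]] <- out
  out
}

#' Generate a synthetic DRT log for one task block
#'
#' @param params a [condition_params()] object
#' @param config a [sim_config()]; supplies the block duration
#' @param seed integer seed
#' @param cutoff scoring cutoff the calibration targets, seconds
#' @return a [drt_log()] covering one block: stimuli at cumulative U(2, 4)-s
#'   intervals within the block; each answered with the calibrated raw
#'   response probability at a calibrated log-normal latency, the response
#'   being emitted only when it precedes the next stimulus onset
#' @export
generate_drt_log <- function(params, config = sim_config(),
                             seed = config$seed, cutoff = 2.5) {
  stopifnot(inherits(params, "condition_params"),
            inherits(config, "sim_config"))
  dur <- config$block_duration
  if (dur <= 0) stop("block_duration must be positive")
  cal <- calibrate_drt(params$rt_mean, params$rt_sd, params$drt_miss_prob,
                       cutoff)
  with_local_seed(seed, {
    # one interval beyond the block so the last stimulus has a next onset
    n_max <- ceiling(dur / 2) + 1
    onsets <- cumsum(stats::runif(n_max, 2, 4))
    keep <- onsets <= dur
    if (!any(keep)) keep[1] <- TRUE
    stim <- onsets[keep]
    gap_next <- onsets[which(keep) + 1] - stim
    attended <- stats::runif(length(stim)) >= cal$p0
    lat <- if (cal$sigma == 0) rep(exp(cal$mu), length(stim))
           else stats::rlnorm(length(stim), cal$mu, cal$sigma)
    emitted <- attended & lat < gap_next
    drt_log(stim, stim[emitted] + lat[emitted])
  })
}
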