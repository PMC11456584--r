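#' Detection-response-task scoring
#'
#' During each task block the participant answers vibrotactile stimuli by
#' button press. Cognitive load is indexed by the miss rate and the response
#' time; following the ISO convention, latencies over 2.5 s are reclassified
#' as misses and excluded from the response-time analysis.
#'
#' @name drt
NULL

#' Construct a DRT log
#'
#' @param stimulus_times stimulus onset times, seconds, strictly increasing
#' @param response_times button-press times, seconds (absolute, same clock)
#' @return object of class \code{"drt_log"}
#' @export
drt_log <- function(stimulus_times, response_times = numeric(0)) {
  stopifnot(is.numeric(stimulus_times), length(stimulus_times) >= 1,
            !is.unsorted(stimulus_times, strictly = TRUE),
            is.numeric(response_times))
  structure(list(stimulus_times = as.numeric(stimulus_times),
                 response_times = sort(as.numeric(response_times))),
            class = "drt_log")
}

#' @export
print.drt_log <- function(x, ...) {
  cat(sprintf("DRT log: %d stimuli, %d responses\n",
              length(x$stimulus_times), length(x$response_times)))
  invisible(x)
}

#' Match button presses to stimuli
#'
#' Each response is assigned to the most recent still-unanswered stimulus
#' preceding it; stimuli left without a response are misses. Responses with no
#' preceding unanswered stimulus are discarded (their count is returned).
#'
#' @param log a [drt_log()]
#' @return list with \code{latency} (per-stimulus latency in seconds, NA for
#'   misses) and \code{n_discarded} (orphan responses dropped)
#' @export
match_responses <- function(log) {
  stopifnot(inherits(log, "drt_log"))
  stim <- log$stimulus_times
  lat <- rep(NA_real_, length(stim))
  discarded <- 0L
  for (r in log$response_times) {
    cand <- which(stim <= r & is.na(lat))
    if (length(cand) == 0) {
      discarded <- discarded + 1L
    } else {
      i <- cand[length(cand)]
      lat[i] <- r - stim[i]
    }
  }
  list(latency = lat, n_discarded = discarded)
}

#' Score a DRT log
#'
#' Applies [match_responses()], reclassifies latencies strictly greater than
#' \code{cutoff} (default 2.5 s) as misses, and summarizes. A latency of
#' exactly 2.5 s counts as a valid response. \code{mean_rt} is computed over
#' valid responses only and is \code{NA} when every stimulus was missed.
#'
#' @param log a [drt_log()]
#' @param cutoff reclassification latency, seconds
#' @param tlx optional NASA-TLX composite (0-100) to attach
#' @return object of class \code{"cognitive_load_summary"}: list with
#'   \code{miss_rate}, \code{mean_rt}, \code{n_stimuli}, \code{n_valid},
#'   \code{latency} (post-reclassification, NA for misses) and \code{tlx}
#' @export
score_drt <- function(log, cutoff = 2.5, tlx = NULL) {
  stopifnot(inherits(log, "drt_log"), cutoff > 0)
  if (!is.null(tlx)) stopifnot(tlx >= 0, tlx <= 100)
  m <- match_responses(log)
  lat <- m$latency
  lat[!is.na(lat) & lat > cutoff] <- NA_real_
  n <- length(lat)
  n_valid <- sum(!is.na(lat))
  structure(
    list(miss_rate = (n - n_valid) / n,
         mean_rt = if (n_valid > 0) mean(lat, na.rm = TRUE) else NA_real_,
         n_stimuli = n, n_valid = n_valid,
         latency = lat, tlx = tlx),
    class = "cognitive_load_summary"
  )
}

#' @export
print.cognitive_load_summary <- function(x, ...) {
  cat(sprintf("DRT summary: %d stimuli, miss rate %.1f%%, mean RT %s\n",
              x$n_stimuli, 100 * x$miss_rate,
              if (is.na(x$mean_rt)) "undefined"
              else sprintf("%.3f s", x$mean_rt)))
  if (!is.null(x$tlx)) cat(sprintf("  NASA-TLX: %.1f\n", x$tlx))
  invisible(x)
}

#' Aggregate NASA-TLX scores across conditions
#'
#' Computes per-condition mean and SD of the 0-100 composite and annotates
#' each pairwise difference with whether its magnitude meets the 15-point
#' minimum detectable change (differences below 15 points lie within the
#' instrument's measurement error).
#'
#' @param scores named list (or data frame with columns \code{condition},
#'   \code{tlx}) of composite scores per condition, each in \[0, 100\]
#' @param threshold minimum change attributable to true change, points
#' @return list with \code{summary} (condition, mean, sd, n) and \code{pairs}
#'   (condition_a, condition_b, difference, exceeds_threshold); difference is
#'   mean_a - mean_b and \code{exceeds_threshold} is |difference| >= threshold
#' @export
aggregate_tlx <- function(scores, threshold = 15) {
  if (is.data.frame(scores)) {
    scores <- split(scores$tlx, scores$condition)
  }
  vals <- unlist(scores)
  if (any(vals < 0 | vals > 100)) stop("TLX scores must lie in [0, 100]")
  summ <- data.frame(
    condition = names(scores),
    mean = vapply(scores, mean, 0),
    sd = vapply(scores, stats::sd, 0),
    n = vapply(scores, length, 0L),
    row.names = NULL
  )
  pairs <- NULL
  if (nrow(summ) >= 2) {
    idx <- utils::combn(nrow(summ), 2)
    d <- summ$mean[idx[1, ]] - summ$mean[idx[2, ]]
    pairs <- data.frame(
      condition_a = summ$condition[idx[1, ]],
      condition_b = summ$condition[idx[2, ]],
      difference = d,
      exceeds_threshold = abs(d) >= threshold
    )
  }
  list(summary = summ, pairs = pairs, threshold = threshold)
}
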