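#' Kalman-filter decoding of kinematic intent from EMG features
#'
#' The decoder is the standard linear-Gaussian state-space model used in
#' neural decoding: kinematics x_t follow a first-order linear prior
#' x_t = A x_{t-1} + w, w ~ N(0, W), and features y_t arise from the linear
#' likelihood y_t = H x_t + q, q ~ N(0, Q). \code{mkf()} identifies (A, W)
#' from successive kinematic frames and (H, Q) by (ridge-regularized) least
#' squares of features on kinematics; decoding is the recursive Kalman
#' predict/update cycle. DOFs can be locked in software: their posterior mean
#' and covariance rows/columns are zeroed every step, so a physical joint
#' stays immobile while the control pipeline is unchanged.
#'
#' @name decoder
NULL

#' Train a Kalman decoder
#'
#' @param features a [feature_stream()] or frames x p numeric matrix
#' @param kinematics frames x d matrix of intent (each DOF in \[-1, 1\]),
#'   time-aligned with the feature frames
#' @param lambda ridge penalty for the observation model, as a fraction of
#'   \code{trace(X'X)/d}; regularizes the p >> frames regime
#' @param q_ridge diagonal loading added to the observation-noise covariance,
#'   as a fraction of its mean diagonal (keeps Q invertible when the feature
#'   count approaches the frame count)
#' @return an object of class \code{"mkf"} with elements \code{A}, \code{W}
#'   (state model), \code{H}, \code{Q} (observation model) and cached
#'   quantities for fast filtering
#' @examples
#' x <- matrix(sin(seq(0, 20, length.out = 400)), ncol = 1)
#' kin <- cbind(x, 0, 0)
#' feats <- kin %*% matrix(rnorm(30), 3, 10) + rnorm(4000, sd = 0.01)
#' m <- mkf(feats, kin)
#' dec <- predict(m, feats)
#' @export
mkf <- function(features, kinematics, lambda = 1e-3, q_ridge = 1e-6) {
  Y <- if (inherits(features, "feature_stream")) features$frames
       else as.matrix(features)
  X <- as.matrix(kinematics)
  n <- nrow(Y)
  d <- ncol(X)
  stopifnot(nrow(X) == n, lambda >= 0, q_ridge >= 0)
  if (n < d + 2) stop("need at least state_dim + 2 aligned frames")

  # state model: A from successive kinematic frames, W from its residuals
  X1 <- X[-n, , drop = FALSE]
  X2 <- X[-1, , drop = FALSE]
  G <- crossprod(X1)
  if (rcond(G) < 1e-10) {
    warning("rank-deficient kinematics; using ridge-regularized state model")
    G <- G + diag(lambda * (sum(diag(G)) / d + 1), d)
  }
  A <- t(solve(G, crossprod(X1, X2)))
  rw <- X2 - X1 %*% t(A)
  W <- crossprod(rw) / max(1, n - 1 - d)
  W <- (W + t(W)) / 2 + diag(1e-10, d)

  # observation model: ridge regression of features on kinematics
  Gx <- crossprod(X)
  ridge <- diag(lambda * (sum(diag(Gx)) / d + 1e-12), d)
  H <- t(solve(Gx + ridge, crossprod(X, Y)))
  rq <- Y - X %*% t(H)
  Q <- crossprod(rq) / max(1, n - d)
  diag(Q) <- diag(Q) + q_ridge * mean(diag(Q)) + 1e-12
  Q <- (Q + t(Q)) / 2

  # cache H' Q^-1 and H' Q^-1 H for the information-form update
  QiH <- solve(Q, H)
  structure(
    list(A = A, W = W, H = H, Q = Q,
         HtQi = t(QiH), HtQiH = crossprod(H, QiH),
         state_dim = d, feature_dim = ncol(Y), n_train = n,
         lambda = lambda),
    class = "mkf"
  )
}

#' @export
print.mkf <- function(x, ...) {
  cat(sprintf("Kalman decoder: %d features -> %d DOFs (trained on %d frames)\n",
              x$feature_dim, x$state_dim, x$n_train))
  invisible(x)
}

#' @export
coef.mkf <- function(object, ...) {
  list(A = object$A, W = object$W, H = object$H, Q = object$Q)
}

# zero the locked DOFs in mean and covariance
apply_lock <- function(state, cov, locked) {
  if (any(locked)) {
    state[locked] <- 0
    cov[locked, ] <- 0
    cov[, locked] <- 0
  }
  list(state = state, cov = cov)
}

#' One Kalman predict/update step
#'
#' Runs the prediction x_pred = A x, P_pred = A P A' + W and the measurement
#' update in information form (the state dimension is small, so the posterior
#' precision P_pred^-1 + H'Q^-1 H is the cheap route for 528-dimensional
#' observations). Locked DOFs are zeroed in the posterior mean and their
#' covariance rows/columns cleared; the posterior mean is clipped to
#' \[-1, 1\]. A frame with any non-finite feature is skipped: the previous
#' state and covariance are returned unchanged, with attribute
#' \code{skipped = TRUE}.
#'
#' @param model an [mkf()] decoder
#' @param y feature frame (length \code{feature_dim})
#' @param state previous posterior mean (length \code{state_dim})
#' @param cov previous posterior covariance
#' @param locked logical vector of software-locked DOFs
#' @return list with updated \code{state} and \code{cov}
#' @export
decode_step <- function(model, y, state, cov,
                        locked = rep(FALSE, model$state_dim)) {
  stopifnot(inherits(model, "mkf"), length(locked) == model$state_dim)
  if (any(!is.finite(y))) {
    out <- list(state = state, cov = cov)
    attr(out, "skipped") <- TRUE
    return(out)
  }
  x_pred <- drop(model$A %*% state)
  P_pred <- model$A %*% cov %*% t(model$A) + model$W
  P_pred <- (P_pred + t(P_pred)) / 2
  Pi <- solve(P_pred)
  P_post <- solve(Pi + model$HtQiH)
  P_post <- (P_post + t(P_post)) / 2
  x_post <- drop(P_post %*% (Pi %*% x_pred + model$HtQi %*% y))
  x_post <- pmin(1, pmax(-1, x_post))
  apply_lock(x_post, P_post, locked)
}

# per-DOF output shaping: dead-zone then gain, rescaled to keep +/-1 reach
shape_output <- function(x, dead_zone, gain) {
  if (dead_zone > 0) {
    x <- sign(x) * pmax(abs(x) - dead_zone, 0) / (1 - dead_zone)
  }
  pmin(pmax(gain * x, -1), 1)  # matrix first: pmax/pmin keep its dims
}

#' Decode a feature stream
#'
#' Folds [decode_step()] over the frames from initial state 0 (rest posture)
#' and initial covariance W. The filtered trace is optionally passed through a
#' per-DOF output dead-zone and gain (the post-hoc output shaping commonly
#' layered on Kalman decoders; set \code{dead_zone = 0, gain = 1} for the pure
#' linear-Gaussian filter).
#'
#' @param model an [mkf()] decoder
#' @param features a [feature_stream()] or frames x p matrix
#' @param locked logical vector of software-locked DOFs (e.g.
#'   \code{c(FALSE, TRUE, TRUE)} to lock the two wrist DOFs)
#' @param dead_zone per-DOF output dead-zone in \[0, 1)
#' @param gain per-DOF output gain
#' @return frames x d matrix of decoded kinematics in \[-1, 1\]; the
#'   unshaped filter output is attached as attribute \code{"raw"} and the
#'   number of skipped frames as \code{"n_skipped"}
#' @export
decode_stream <- function(model, features,
                          locked = rep(FALSE, model$state_dim),
                          dead_zone = 0.1, gain = 1) {
  stopifnot(inherits(model, "mkf"), dead_zone >= 0, dead_zone < 1)
  Y <- if (inherits(features, "feature_stream")) features$frames
       else as.matrix(features)
  d <- model$state_dim
  state <- rep(0, d)
  cov <- model$W
  out <- matrix(0, nrow(Y), d)
  n_skipped <- 0L
  for (k in seq_len(nrow(Y))) {
    step <- decode_step(model, Y[k, ], state, cov, locked)
    if (isTRUE(attr(step, "skipped"))) n_skipped <- n_skipped + 1L
    state <- step$state
    cov <- step$cov
    out[k, ] <- state
  }
  shaped <- shape_output(out, dead_zone, gain)
  shaped[, locked] <- 0
  attr(shaped, "raw") <- out
  attr(shaped, "n_skipped") <- n_skipped
  shaped
}

#' @describeIn mkf decode new features with a fitted decoder (see
#'   [decode_stream()] for the arguments)
#' @param object an \code{"mkf"} model
#' @param ... passed to [decode_stream()]
#' @export
predict.mkf <- function(object, features, ...) {
  decode_stream(object, features, ...)
}
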