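# Kalman decoder: system identification, filter correctness, locking

# simulate a known linear-Gaussian system
simulate_lds <- function(n, A, H, w_sd, q_sd, seed = 1) {
  set.seed(seed)
  d <- nrow(A); p <- nrow(H)
  x <- matrix(0, n, d)
  for (k in 2:n) x[k, ] <- A %*% x[k - 1, ] + rnorm(d, 0, w_sd)
  y <- x %*% t(H) + matrix(rnorm(n * p, 0, q_sd), n, p)
  list(x = x, y = y)
}

A2 <- matrix(c(0.9, 0.05, -0.03, 0.85), 2, 2)
H2 <- matrix(c(1.2, -0.4, 0.3, 0.9, -0.7, 0.5, 0.2, -1.1), 4, 2)

test_that("training recovers the generating A and H on synthetic data", {
  sim <- simulate_lds(10000, A2, H2, w_sd = sqrt(0.02), q_sd = sqrt(0.05),
                      seed = 42)
  m <- mkf(sim$y, sim$x, lambda = 1e-8)
  expect_lt(norm(coef(m)$A - A2, "F") / norm(A2, "F"), 0.05)
  expect_lt(norm(coef(m)$H - H2, "F") / norm(H2, "F"), 0.05)
  # determinism: refitting the same data gives the identical model
  m2 <- mkf(sim$y, sim$x, lambda = 1e-8)
  expect_identical(coef(m), coef(m2))
})

test_that("constant-zero kinematics with noise features give a null model", {
  set.seed(3)
  y <- matrix(rnorm(500 * 6), 500, 6)
  x <- matrix(0, 500, 2)
  expect_warning(m <- mkf(y, x), "rank-deficient")
  expect_true(all(abs(coef(m)$H) < 1e-10))
})

test_that("one decode step equals direct Gaussian conditioning", {
  sim <- simulate_lds(400, A2, H2, sqrt(0.05), sqrt(0.1), seed = 7)
  m <- mkf(sim$y, sim$x, lambda = 1e-8)
  x0 <- c(0.02, -0.01)
  P0 <- diag(c(0.03, 0.02))
  yobs <- sim$y[100, ] / 10          # small values: clipping never binds
  step <- decode_step(m, yobs, x0, P0)
  # closed-form Bayes: condition the joint prior-observation Gaussian
  A <- m$A; W <- m$W; H <- m$H; Q <- m$Q
  x_pred <- A %*% x0
  P_pred <- A %*% P0 %*% t(A) + W
  S <- H %*% P_pred %*% t(H) + Q
  K <- P_pred %*% t(H) %*% solve(S)
  mu <- drop(x_pred + K %*% (yobs - H %*% x_pred))
  P <- P_pred - K %*% H %*% P_pred
  expect_lt(max(abs(step$state - mu)), 1e-8)
  expect_lt(max(abs(step$cov - P)), 1e-8)
})

test_that("the filter matches batch Gaussian conditioning on short sequences", {
  sim <- simulate_lds(300, A2, H2, sqrt(0.05), sqrt(0.1), seed = 11)
  m <- mkf(sim$y, sim$x, lambda = 1e-8)
  A <- m$A; W <- m$W; H <- m$H; Q <- m$Q
  d <- 2
  for (T in c(1, 3, 5)) {
    yobs <- sim$y[seq_len(T), , drop = FALSE] / 10
    dec <- decode_stream(m, yobs, dead_zone = 0)
    # batch oracle: joint covariance of stacked states (x_0 ~ N(0, W)) and
    # observations, conditioned by brute force
    # x_t = A^t x_0 + sum_{j=1}^t A^(t-j) w_j, stacked into M (x_0, w_1..w_T)
    M <- matrix(0, T * d, (T + 1) * d)
    Apows <- list(diag(d))
    for (k in seq_len(T)) Apows[[k + 1]] <- A %*% Apows[[k]]
    for (t in seq_len(T)) {
      rows <- (t - 1) * d + seq_len(d)
      M[rows, seq_len(d)] <- Apows[[t + 1]]
      for (j in seq_len(t)) {
        M[rows, j * d + seq_len(d)] <- Apows[[t - j + 1]]
      }
    }
    Sz <- kronecker(diag(T + 1), W)
    Sxx <- M %*% Sz %*% t(M)
    Hb <- kronecker(diag(T), H)
    Syy <- Hb %*% Sxx %*% t(Hb) + kronecker(diag(T), Q)
    Sxy <- Sxx %*% t(Hb)
    mu_all <- Sxy %*% solve(Syy, as.vector(t(yobs)))
    mu_T <- mu_all[(T - 1) * d + seq_len(d)]
    expect_lt(max(abs(dec[T, ] - mu_T)), 1e-6)
  }
})

test_that("software locking forces DOFs to zero without disturbing the rest", {
  sim <- simulate_lds(500, A2, H2, sqrt(0.05), sqrt(0.1), seed = 5)
  m <- mkf(sim$y, sim$x, lambda = 1e-8)
  dec <- decode_stream(m, sim$y, locked = c(FALSE, TRUE))
  expect_true(all(dec[, 2] == 0))
  expect_gt(stats::cor(dec[, 1], sim$x[, 1]), 0.8)
  dec_all <- decode_stream(m, sim$y, locked = c(TRUE, TRUE))
  expect_true(all(dec_all == 0))
})

test_that("an uninformative observation model reduces to the prior prediction", {
  sim <- simulate_lds(300, A2, H2, sqrt(0.05), sqrt(0.1), seed = 13)
  m <- mkf(sim$y, sim$x, lambda = 1e-8)
  m$HtQi <- m$HtQi * 1e-6      # Q scaled by 1e6
  m$HtQiH <- m$HtQiH * 1e-6
  x0 <- c(0.3, -0.2); P0 <- diag(0.01, 2)
  step <- decode_step(m, sim$y[50, ], x0, P0)
  expect_equal(step$state, drop(m$A %*% x0), tolerance = 1e-3)
})

test_that("non-finite feature frames are skipped and the state held", {
  sim <- simulate_lds(300, A2, H2, sqrt(0.05), sqrt(0.1), seed = 17)
  m <- mkf(sim$y, sim$x, lambda = 1e-8)
  x0 <- c(0.1, 0.1); P0 <- diag(0.02, 2)
  bad <- sim$y[10, ]; bad[2] <- NaN
  step <- decode_step(m, bad, x0, P0)
  expect_true(attr(step, "skipped"))
  expect_identical(step$state, x0)
  y <- sim$y[1:50, ]; y[25, 1] <- Inf
  dec <- decode_stream(m, y, dead_zone = 0)
  expect_equal(attr(dec, "n_skipped"), 1L)
})

test_that("state covariance stays symmetric PSD over long runs", {
  sim <- simulate_lds(600, A2, H2, sqrt(0.05), sqrt(0.1), seed = 19)
  m <- mkf(sim$y, sim$x, lambda = 1e-8)
  state <- c(0, 0); cov <- m$W
  set.seed(23)
  for (k in seq_len(10000)) {
    step <- decode_step(m, sim$y[(k - 1) %% 600 + 1, ], state, cov)
    state <- step$state; cov <- step$cov
    if (k %% 500 == 0) {
      expect_lt(max(abs(cov - t(cov))), 1e-8)
      expect_gt(min(eigen(cov, symmetric = TRUE)$values), -1e-8)
    }
  }
})

test_that("filtering smooths harder than frame-wise inverse regression", {
  sim <- simulate_lds(2000, A2, H2, sqrt(0.02), sqrt(0.5), seed = 29)
  m <- mkf(sim$y, sim$x, lambda = 1e-8)
  dec <- decode_stream(m, sim$y, dead_zone = 0)
  # naive per-frame pseudo-inverse oracle on the same noisy stream
  naive <- sim$y %*% t(solve(crossprod(m$H), t(m$H)))
  err_kf <- colMeans((dec - sim$x)^2)
  err_naive <- colMeans((naive - sim$x)^2)
  expect_true(all(apply(dec, 2, var) <= apply(naive, 2, var)))
  expect_true(all(err_kf <= err_naive))
})

test_that("the full synthetic chain is decoded with high fidelity", {
  mix <- mixing_model(n_channels = 8, noise_sd = 0.02)  # SNR well above 10
  cfg <- sim_config(seed = 3)
  sess <- generate_training_session(cfg, mix, bump_duration = 1, gap = 0.25)
  tf <- training_frames(sess)
  m <- mkf(tf$features, tf$kinematics)
  dec <- decode_stream(m, tf$features, dead_zone = 0)
  r <- diag(stats::cor(dec, tf$kinematics))
  expect_gt(mean(r), 0.9)
  expect_gt(min(r), 0.9)
  # wrist lock: hand decoding survives, wrist outputs are identically zero
  dec_lock <- decode_stream(m, tf$features, locked = c(FALSE, TRUE, TRUE))
  expect_true(all(dec_lock[, 2:3] == 0))
})
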