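# statistical battery: GLM risk ratios, sandwich variance, permutation tests

test_that("the log-link GLM reproduces the closed-form risk ratio", {
  d <- data.frame(condition = rep(c("b", "a"), each = 10),
                  failure = c(rep(1, 6), rep(0, 4), rep(1, 3), rep(0, 7)))
  r <- glm_binomial_log(d, "failure", covariates = character(0), ref = "a")
  expect_equal(r$risk_ratio, 2, tolerance = 1e-6)
  expect_equal(r$estimate, log(2), tolerance = 1e-6)
  # covariate-free adjusted proportions equal the raw proportions exactly
  expect_equal(r$adjusted$mean[r$adjusted$condition == "a"], 0.3,
               tolerance = 1e-8)
  expect_equal(r$adjusted$mean[r$adjusted$condition == "b"], 0.6,
               tolerance = 1e-8)
})

test_that("identical groups give a null condition effect", {
  d <- data.frame(condition = rep(c("a", "b"), each = 8),
                  failure = rep(c(1, 1, 0, 0), 4))
  r <- glm_binomial_log(d, "failure", covariates = character(0), ref = "a")
  expect_equal(r$estimate, 0, tolerance = 1e-8)
  expect_gt(r$p_value, 0.99)
})

test_that("HC1 sandwich SE equals the hand-computed value on a toy design", {
  toy <- data.frame(condition = c("a", "a", "b", "b"), y = c(1, 2, 4, 7))
  r <- robust_linear(toy, "y", covariates = character(0), ref = "a")
  # brute-force HC1: (n/(n-k)) (X'X)^-1 X' diag(e^2) X (X'X)^-1
  X <- cbind(1, c(0, 0, 1, 1))
  b <- solve(crossprod(X), crossprod(X, toy$y))
  e <- drop(toy$y - X %*% b)
  XtXi <- solve(crossprod(X))
  V <- 4 / (4 - 2) * XtXi %*% t(X) %*% diag(e^2) %*% X %*% XtXi
  expect_equal(r$se, sqrt(V[2, 2]), tolerance = 1e-10)
  expect_equal(r$estimate, 4)
})

test_that("sandwich and classical SEs agree on large homoskedastic samples", {
  set.seed(8)
  n <- 10000
  d <- data.frame(condition = rep(c("a", "b"), n / 2),
                  y = rnorm(n) + 0.2 * rep(c(0, 1), n / 2))
  r <- robust_linear(d, "y", covariates = character(0), ref = "a")
  classical <- summary(lm(y ~ condition, d))$coefficients["conditionb",
                                                          "Std. Error"]
  expect_lt(abs(r$se - classical) / classical, 0.03)
})

test_that("adjusted means bracket the estimate and carry 95% CIs", {
  set.seed(12)
  d <- data.frame(condition = rep(c("a", "b"), each = 30),
                  participant = rep(rep(1:3, each = 10), 2),
                  y = rnorm(60, rep(c(10, 7), each = 30), 2))
  r <- robust_linear(d, "y", ref = "a")
  adj <- r$adjusted
  expect_equal(adj$mean[adj$condition == "b"] -
                 adj$mean[adj$condition == "a"], r$estimate,
               tolerance = 1e-8)
  expect_true(all(adj$lower <= adj$mean & adj$mean <= adj$upper))
})

test_that("robust-linear CI covers the true condition effect at ~95%", {
  set.seed(33)
  true_eff <- -2
  hits <- 0
  n_rep <- 500
  for (i in seq_len(n_rep)) {
    d <- data.frame(condition = rep(c("a", "b"), each = 20),
                    y = c(rnorm(20, 10, 3), rnorm(20, 10 + true_eff, 1.5)))
    r <- robust_linear(d, "y", covariates = character(0), ref = "a")
    ci <- r$estimate + c(-1, 1) * qnorm(0.975) * r$se
    if (ci[1] <= true_eff && true_eff <= ci[2]) hits <- hits + 1
  }
  expect_lt(abs(hits / n_rep - 0.95), 0.03)
})

test_that("permutation p-values obey the add-one bound and degenerate cases", {
  d <- data.frame(participant = rep(1:3, each = 4),
                  condition = rep(c("a", "a", "b", "b"), 3),
                  y = c(1, 2, 9, 10, 2, 1, 8, 11, 0, 3, 10, 9))
  r <- permutation_test(d, "y", ref = "a", n_perm = 200, seed = 3)
  expect_gte(r$p_value, 1 / 201)
  expect_lte(r$p_value, 1)
  dc <- d; dc$y <- 5
  r0 <- permutation_test(dc, "y", ref = "a", n_perm = 50, seed = 3)
  expect_equal(r0$p_value, 1)
  # determinism under a fixed seed
  r2 <- permutation_test(d, "y", ref = "a", n_perm = 200, seed = 3)
  expect_identical(r$p_value, r2$p_value)
})

test_that("the permutation test holds its size under the null", {
  set.seed(71)
  n_rep <- 200
  pvals <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    d <- data.frame(participant = rep(1:3, each = 8),
                    condition = rep(c("a", "b"), 12),
                    y = rnorm(24, 50, 5))
    pvals[i] <- permutation_test(d, "y", ref = "a", n_perm = 500,
                                 seed = 1000 + i)$p_value
  }
  # not significant in at least 95% of replicates; p-values near-uniform
  expect_gte(mean(pvals > 0.05), 0.95)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.12)
})

test_that("the full battery is deterministic and structurally complete", {
  ds <- generate_condition_dataset(sim_config(seed = 7))
  rep1 <- suppressWarnings(run_full_battery(ds, n_perm = 300, seed = 2))
  rep2 <- suppressWarnings(run_full_battery(ds, n_perm = 300, seed = 2))
  expect_identical(rep1$table, rep2$table)
  expect_equal(nrow(rep1$table), 14)      # 7 outcomes x 2 comparisons
  expect_setequal(unique(rep1$table$comparison), c("commercial", "research"))
  expect_true(all(rep1$table$p_value >= 0 & rep1$table$p_value <= 1))
  # dropping an outcome column skips that row with a warning
  ds2 <- ds
  ds2$tlx$tlx <- NULL
  w <- capture_warnings(rep3 <- run_full_battery(ds2, n_perm = 50, seed = 2))
  expect_true(any(grepl("missing", w)))
  expect_equal(nrow(rep3$table), 12)
})
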