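#' Statistical battery for condition comparisons
#'
#' The study compares wrist-enabled vs wrist-disabled arms within each
#' prosthesis configuration (C+W vs C-W and R+W vs R-W) for seven outcomes.
#' Dichotomous outcomes (task failure, DRT miss) use a binomial GLM with log
#' link, so the exponentiated condition coefficient is a risk ratio;
#' continuous outcomes with many observations (lean, bend, response time) use
#' OLS point estimates with the HC1 heteroskedasticity-consistent sandwich
#' variance; small-n outcomes (attempted movements, subjective workload) use a
#' Monte Carlo permutation test of the covariate-adjusted regression
#' coefficient, shuffling condition labels within participant to respect the
#' repeated-measures structure. Adjusted means are obtained by marginal
#' standardization (average model prediction over the observed covariate
#' pattern) with delta-method 95\% confidence intervals. Two-sided tests at
#' alpha = 0.05 throughout.
#'
#' @name stats_battery
NULL

# validate + order the condition factor so `ref` is the reference level
prep_condition <- function(data, ref) {
  cond <- as.character(data$condition)
  levels <- unique(cond)
  if (length(levels) != 2) stop("exactly two condition levels required")
  if (is.null(ref)) ref <- sort(levels)[1]
  if (!ref %in% levels) stop("ref level '", ref, "' not present")
  factor(cond, levels = c(ref, setdiff(levels, ref)))
}

# marginal standardization: average prediction with condition forced to each
# level; delta-method variance from the coefficient covariance
adjusted_means <- function(fit, data, vcov_mat, response = identity,
                           dresponse = function(eta) rep(1, length(eta))) {
  tt <- stats::terms(fit)
  b <- stats::coef(fit)
  keep <- !is.na(b)
  out <- lapply(levels(data$condition), function(lv) {
    d <- data
    d$condition <- factor(lv, levels = levels(data$condition))
    X <- stats::model.matrix(stats::delete.response(tt), d)
    X <- X[, names(b)[keep], drop = FALSE]
    eta <- drop(X %*% b[keep])
    mu <- response(eta)
    grad <- colMeans(dresponse(eta) * X)
    se <- sqrt(drop(t(grad) %*% vcov_mat %*% grad))
    c(mean = mean(mu), se = se)
  })
  m <- do.call(rbind, out)
  data.frame(condition = levels(data$condition),
             mean = m[, "mean"], se = m[, "se"],
             lower = m[, "mean"] - stats::qnorm(0.975) * m[, "se"],
             upper = m[, "mean"] + stats::qnorm(0.975) * m[, "se"],
             row.names = NULL)
}

stats_result <- function(estimate, se, p_value, adjusted, method, n_obs,
                         extra = list()) {
  structure(c(list(estimate = estimate, se = se, p_value = p_value,
                   adjusted = adjusted, method = method, n_obs = n_obs),
              extra),
            class = "stats_result")
}

#' @export
print.stats_result <- function(x, ...) {
  cat(sprintf("%s (n = %d)\n", x$method, x$n_obs))
  cat(sprintf("  condition effect: %.4g (SE %.4g), p = %.4g\n",
              x$estimate, x$se, x$p_value))
  if (!is.null(x$risk_ratio)) {
    cat(sprintf("  risk ratio: %.3f\n", x$risk_ratio))
  }
  if (!is.null(x$adjusted)) {
    cat("  adjusted means (95% CI):\n")
    for (i in seq_len(nrow(x$adjusted))) {
      cat(sprintf("    %s: %.4g [%.4g, %.4g]\n", x$adjusted$condition[i],
                  x$adjusted$mean[i], x$adjusted$lower[i],
                  x$adjusted$upper[i]))
    }
  }
  invisible(x)
}

#' Log-link binomial GLM for dichotomous outcomes
#'
#' Fits \code{outcome ~ condition + covariates} by IRLS with
#' \code{binomial(link = "log")}, so \code{exp(coef)} is a risk ratio.
#' Adjusted per-condition proportions come from marginal standardization.
#' Non-convergence within \code{maxit} iterations and (quasi-)separation
#' (fitted probabilities at the boundary) are reported via flags and warnings
#' rather than errors.
#'
#' @param data data frame with a two-level \code{condition} column
#' @param outcome name of the 0/1 outcome column
#' @param covariates character vector of covariate column names (coerced to
#'   factors); default \code{"participant"}
#' @param ref reference condition level (the "without wrist" arm)
#' @param maxit IRLS iteration cap
#' @return a \code{"stats_result"} with the condition coefficient (log risk
#'   ratio), its SE, Wald p-value, \code{risk_ratio}, and adjusted proportions
#' @export
glm_binomial_log <- function(data, outcome, covariates = "participant",
                             ref = NULL, maxit = 100) {
  data <- as.data.frame(data)
  y <- data[[outcome]]
  stopifnot(all(y %in% 0:1))
  data$condition <- prep_condition(data, ref)
  data$.y <- y
  for (cv in covariates) data[[cv]] <- factor(data[[cv]])
  rhs <- paste(c("condition", covariates), collapse = " + ")
  f <- stats::as.formula(paste(".y ~", rhs))
  # log-link binomial needs interior starting values
  X <- stats::model.matrix(f, data)
  start <- c(log(max(mean(y), 1e-3)), rep(0, ncol(X) - 1))
  fit <- suppressWarnings(
    stats::glm(f, data = data, family = stats::binomial(link = "log"),
               start = start, control = stats::glm.control(maxit = maxit))
  )
  if (!fit$converged) {
    warning("log-link binomial GLM did not converge in ", maxit,
            " IRLS iterations")
  }
  separated <- any(stats::fitted(fit) > 1 - 1e-8 |
                     stats::fitted(fit) < 1e-8)
  if (separated) warning("fitted probabilities at the boundary; possible separation")
  sm <- summary(fit)
  co <- sm$coefficients
  cname <- paste0("condition", levels(data$condition)[2])
  adj <- adjusted_means(fit, data, stats::vcov(fit), response = exp,
                        dresponse = exp)
  adj$mean <- pmin(adj$mean, 1)
  adj$upper <- pmin(adj$upper, 1)
  adj$lower <- pmax(adj$lower, 0)
  stats_result(
    estimate = co[cname, "Estimate"], se = co[cname, "Std. Error"],
    p_value = co[cname, "Pr(>|z|)"], adjusted = adj,
    method = "binomial GLM (log link)", n_obs = nrow(data),
    extra = list(risk_ratio = exp(co[cname, "Estimate"]),
                 converged = fit$converged, separated = separated,
                 fit = fit)
  )
}

#' Linear model with HC1 sandwich variance
#'
#' OLS point estimates with heteroskedasticity-consistent (HC1,
#' small-sample-corrected) sandwich standard errors and Wald inference,
#' robust to the non-normal residual distributions of bounded angle and
#' response-time outcomes. Collinear columns are dropped with a warning.
#'
#' @inheritParams glm_binomial_log
#' @param outcome name of the continuous outcome column
#' @return a \code{"stats_result"} with the condition coefficient (adjusted
#'   mean difference), HC1 SE, Wald p-value and adjusted means
#' @export
robust_linear <- function(data, outcome, covariates = "participant",
                          ref = NULL) {
  data <- as.data.frame(data)
  data$condition <- prep_condition(data, ref)
  for (cv in covariates) data[[cv]] <- factor(data[[cv]])
  if (any(table(data$condition) < 2)) {
    stop("need at least 2 observations per condition")
  }
  data$.y <- data[[outcome]]
  rhs <- paste(c("condition", covariates), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = data)
  if (any(is.na(stats::coef(fit)))) {
    warning("collinear design; dropped column(s): ",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                  collapse = ", "))
  }
  V <- sandwich::vcovHC(fit, type = "HC1")
  ct <- lmtest::coeftest(fit, vcov. = V)
  cname <- paste0("condition", levels(data$condition)[2])
  adj <- adjusted_means(fit, data, V)
  stats_result(
    estimate = ct[cname, "Estimate"], se = ct[cname, "Std. Error"],
    p_value = ct[cname, "Pr(>|t|)"], adjusted = adj,
    method = "linear model, HC1 sandwich variance", n_obs = nrow(data),
    extra = list(fit = fit, vcov = V)
  )
}

#' Monte Carlo permutation test of a regression coefficient
#'
#' The observed statistic is the condition coefficient from the
#' covariate-adjusted linear regression. The null distribution is built by
#' shuffling condition labels within participant (respecting the
#' repeated-measures design) \code{n_perm} times; the two-sided p-value is
#' \code{(1 + #\{|b*| >= |b|\}) / (n_perm + 1)}. A constant outcome returns
#' p = 1.
#'
#' @inheritParams robust_linear
#' @param n_perm number of Monte Carlo permutations
#' @param seed integer seed for the permutation draws
#' @return a \code{"stats_result"} with the observed coefficient and the
#'   permutation p-value (SE is the permutation-null SD of the coefficient)
#' @export
permutation_test <- function(data, outcome, covariates = "participant",
                             ref = NULL, n_perm = 10000, seed = 1L) {
  stopifnot(n_perm >= 1)
  data <- as.data.frame(data)
  data$condition <- prep_condition(data, ref)
  for (cv in covariates) data[[cv]] <- factor(data[[cv]])
  y <- data[[outcome]]
  n <- length(y)
  adj <- data.frame(condition = levels(data$condition),
                    mean = tapply(y, data$condition, mean),
                    se = NA_real_, lower = NA_real_, upper = NA_real_,
                    row.names = NULL)
  if (stats::var(y) == 0) {
    return(stats_result(0, 0, 1, adj, "permutation test (degenerate outcome)",
                        n, extra = list(n_perm = n_perm)))
  }
  covf <- stats::as.formula(
    paste("~", paste(c(covariates, "1"), collapse = " + ")))
  Xcov <- stats::model.matrix(covf, data)
  z <- as.numeric(data$condition == levels(data$condition)[2])
  coef_for <- function(zz) {
    fit <- stats::.lm.fit(cbind(Xcov, zz), y)
    fit$coefficients[ncol(Xcov) + 1]
  }
  b_obs <- coef_for(z)
  part <- data[[covariates[1]]]
  idx_by_part <- split(seq_len(n), part)
  b_null <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      zz <- z
      for (ix in idx_by_part) zz[ix] <- zz[ix][sample.int(length(ix))]
      coef_for(zz)
    }, 0)
  })
  p <- (1 + sum(abs(b_null) >= abs(b_obs) - 1e-12)) / (n_perm + 1)
  stats_result(
    estimate = b_obs, se = stats::sd(b_null), p_value = p, adjusted = adj,
    method = sprintf("permutation test (%d Monte Carlo draws)", n_perm),
    n_obs = n, extra = list(n_perm = n_perm)
  )
}

#' Run the full statistical battery on a synthetic study dataset
#'
#' Applies, per configuration comparison (C+W vs C-W and R+W vs R-W): the
#' log-link binomial GLM to task failure and DRT miss; the HC1 sandwich
#' linear model to forward lean, leftward bend and DRT response time; and the
#' within-participant permutation test to attempted movements and NASA-TLX.
#' Covariates: participant (all outcomes) and block/cycle for the per-attempt
#' and per-stimulus outcomes.
#'
#' @param dataset a [generate_condition_dataset()] result (or a list with
#'   compatible \code{attempts}, \code{drt}, \code{tlx} data frames)
#' @param n_perm Monte Carlo permutations for the permutation tests
#' @param seed integer seed for the permutation draws
#' @param include_cycle include the block/cycle covariate where applicable
#' @return object of class \code{"battery_report"}: a summary data frame
#'   (\code{$table}) with raw mean (SD), adjusted mean (95\% CI) and p-value
#'   per outcome x comparison, plus the full \code{"stats_result"} objects in
#'   \code{$results}
#' @export
run_full_battery <- function(dataset, n_perm = 10000, seed = 1L,
                             include_cycle = TRUE) {
  comparisons <- list(
    commercial = c(ref = "C-W", alt = "C+W"),
    research = c(ref = "R-W", alt = "R+W")
  )
  att_cov <- c("participant", if (include_cycle) "block")
  outcomes <- list(
    list(name = "Failure Rate", data = "attempts", col = "failure",
         fun = "glm", cov = att_cov),
    list(name = "Forward Lean", data = "attempts", col = "max_lean",
         fun = "lm", cov = att_cov),
    list(name = "Leftward Bend", data = "attempts", col = "max_bend",
         fun = "lm", cov = att_cov),
    list(name = "DRT Miss Rate", data = "drt", col = "miss",
         fun = "glm", cov = att_cov),
    list(name = "Response Time", data = "drt_valid", col = "latency",
         fun = "lm", cov = att_cov),
    list(name = "Attempted Movements", data = "counts", col = "n_attempts",
         fun = "perm", cov = "participant"),
    list(name = "Subjective Workload", data = "tlx", col = "tlx",
         fun = "perm", cov = "participant")
  )
  counts <- stats::aggregate(attempt ~ participant + condition + block,
                             dataset$attempts, length)
  names(counts)[names(counts) == "attempt"] <- "n_attempts"
  tables <- list(
    attempts = dataset$attempts,
    drt = dataset$drt,
    drt_valid = dataset$drt[!is.na(dataset$drt$latency), , drop = FALSE],
    counts = counts,
    tlx = dataset$tlx
  )
  results <- list()
  rows <- list()
  for (cmp_name in names(comparisons)) {
    cmp <- comparisons[[cmp_name]]
    for (oc in outcomes) {
      df <- tables[[oc$data]]
      if (is.null(df) || !oc$col %in% names(df)) {
        warning("outcome column '", oc$col, "' missing; skipped")
        next
      }
      sub <- df[df$condition %in% cmp, , drop = FALSE]
      if (nrow(sub) == 0 || length(unique(sub$condition)) < 2) next
      cov <- intersect(oc$cov, names(sub))
      res <- switch(oc$fun,
        glm = glm_binomial_log(sub, oc$col, covariates = cov,
                               ref = cmp[["ref"]]),
        lm = robust_linear(sub, oc$col, covariates = cov,
                           ref = cmp[["ref"]]),
        perm = permutation_test(sub, oc$col, covariates = cov,
                                ref = cmp[["ref"]], n_perm = n_perm,
                                seed = derive_seed(seed, length(results)))
      )
      results[[paste(cmp_name, oc$name, sep = ": ")]] <- res
      raw <- vapply(cmp, function(lv) {
        v <- sub[[oc$col]][sub$condition == lv]
        c(mean(v), stats::sd(v))
      }, c(0, 0))
      adj <- res$adjusted
      rows[[length(rows) + 1]] <- data.frame(
        outcome = oc$name, comparison = cmp_name,
        ref = cmp[["ref"]], alt = cmp[["alt"]],
        raw_mean_ref = raw[1, "ref"], raw_sd_ref = raw[2, "ref"],
        raw_mean_alt = raw[1, "alt"], raw_sd_alt = raw[2, "alt"],
        adj_ref = adj$mean[adj$condition == cmp[["ref"]]],
        adj_alt = adj$mean[adj$condition == cmp[["alt"]]],
        estimate = res$estimate, p_value = res$p_value,
        significant = res$p_value < 0.05,
        method = res$method, n_obs = res$n_obs,
        flag = if (isFALSE(res$converged)) "non-convergence"
               else if (isTRUE(res$separated)) "separation" else ""
      )
    }
  }
  structure(list(table = do.call(rbind, rows), results = results,
                 alpha = 0.05),
            class = "battery_report")
}

#' @export
print.battery_report <- function(x, ...) {
  cat("Statistical battery (alpha = 0.05)\n")
  t <- x$table
  for (i in seq_len(nrow(t))) {
    cat(sprintf(
      "  %-20s %-10s %s %.3g (SD %.3g) vs %s %.3g (SD %.3g): p = %.4g%s\n",
      t$outcome[i], t$comparison[i],
      t$ref[i], t$raw_mean_ref[i], t$raw_sd_ref[i],
      t$alt[i], t$raw_mean_alt[i], t$raw_sd_alt[i],
      t$p_value[i], paste0(ifelse(t$significant[i], " *", ""),
                           ifelse(nzchar(t$flag[i]),
                                  paste0(" [", t$flag[i], "]"), ""))))
  }
  invisible(x)
}
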