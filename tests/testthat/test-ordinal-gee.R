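test_that("cumulative expansion encodes and recovers ordinal scores", {
  expect_equal(expand_cumulative(0), rep(1L, 20))
  expect_equal(expand_cumulative(20), rep(0L, 20))
  expect_equal(expand_cumulative(7), c(rep(0L, 7), rep(1L, 13)))
  # bijection: the number of zeros recovers x
  for (x in 0:20) expect_equal(sum(expand_cumulative(x) == 0), x)
  expect_error(expand_cumulative(21), "0..20")
  expect_error(expand_cumulative(3.5), "0..20")
})

test_that("binary-collapse slopes match an independent logistic GLM oracle", {
  # with scores in {0, 20} every informative threshold carries the same
  # indicator, so the independence GEE must reproduce the plain GLM fit
  d <- generate_trial(trial_config(n_per_sequence = 6), seed = 65)
  d$value <- ifelse(d$value > 4, 20, 0)
  f <- fit_ordinal_gee(d, "vas")
  slope_names <- c("G", "P", "T2", "T3", "T4", "G:P", "G:T2", "G:T3", "G:T4",
                   "P:T2", "P:T3", "P:T4")
  covs <- with(d, cbind(
    G = as.numeric(treatment == "active"), P = as.numeric(period == 2),
    T2 = as.numeric(time == 2), T3 = as.numeric(time == 3),
    T4 = as.numeric(time == 4)))
  covs <- cbind(covs, covs[, "G"] * covs[, c("P", "T2", "T3", "T4")],
                covs[, "P"] * covs[, c("T2", "T3", "T4")])
  oracle <- glm((d$value <= 10) ~ covs, family = binomial)
  rel <- abs(f$coefficients[slope_names] - coef(oracle)[-1]) /
    pmax(abs(coef(oracle)[-1]), 1e-8)
  expect_lt(max(rel), 1e-5)
  expect_lt(f$score_norm, 1e-6)
})

test_that("the estimating equations are solved to high precision (tiny trial)", {
  d <- generate_trial(trial_config(n_per_sequence = 2), seed = 51)
  f <- fit_ordinal_gee(d, "vas")
  expect_lt(f$score_norm, 1e-6)
  # independent re-evaluation: under the independence working structure the
  # estimating function reduces to X'(y - mu) summed over clusters
  kept <- f$kept_thresholds
  score <- 0
  for (k in seq_len(nrow(d) / 8)) {
    id <- unique(d$subject_id)[k]
    sub <- d[d$subject_id == id, ]
    sub <- sub[order(sub$period, sub$time), ]
    y <- as.numeric(t(outer(sub$value, kept - 1, "<=")))
    covs <- cbind(
      G = as.numeric(sub$treatment == "active"), P = as.numeric(sub$period == 2),
      T2 = as.numeric(sub$time == 2), T3 = as.numeric(sub$time == 3),
      T4 = as.numeric(sub$time == 4))
    covs <- cbind(covs, covs[, "G"] * covs[, c("P", "T2", "T3", "T4")],
                  covs[, "P"] * covs[, c("T2", "T3", "T4")])
    X <- cbind(kronecker(rep(1, 8), diag(length(kept))),
               covs[rep(1:8, each = length(kept)), ])
    eta <- drop(X %*% f$coefficients[f$estimable])
    score <- score + drop(crossprod(X, y - plogis(eta)))
  }
  expect_lt(sqrt(sum(score^2)), 1e-6)
})

test_that("reversing the category order flips the slope signs", {
  d <- generate_trial(trial_config(n_per_sequence = 5), seed = 52)
  f1 <- fit_ordinal_gee(d, "vas")
  d2 <- d
  d2$value <- 20 - d$value
  f2 <- fit_ordinal_gee(d2, "vas")
  slope_names <- c("G", "P", "T2", "T3", "T4", "G:P", "G:T2", "G:T3", "G:T4",
                   "P:T2", "P:T3", "P:T4")
  expect_equal(unname(f2$coefficients[slope_names]),
               unname(-f1$coefficients[slope_names]), tolerance = 1e-6)
})

test_that("the independence fit ignores within-subject row order", {
  d <- generate_trial(trial_config(n_per_sequence = 3), seed = 53)
  set.seed(54)
  d2 <- as_long_trial(d[sample(nrow(d)), ])
  f1 <- fit_ordinal_gee(d, "vas")
  f2 <- fit_ordinal_gee(d2, "vas")
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
})

test_that("the sandwich covariance is symmetric positive semi-definite", {
  for (s in 55:57) {
    d <- generate_trial(trial_config(n_per_sequence = 4), seed = s)
    f <- fit_ordinal_gee(d, "vas")
    expect_equal(f$vcov, t(f$vcov))
    ev <- eigen(f$vcov, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10 * max(ev))
  }
})

test_that("degenerate thresholds are profiled out with infinite intercepts", {
  d <- generate_trial(trial_config(n_per_sequence = 4), seed = 58)
  d$value <- pmin(d$value, 10)  # nothing above 10: thresholds 10..20 all-one
  f <- suppressWarnings(fit_ordinal_gee(d, "vas"))
  expect_true(all(f$degenerate_thresholds >= 10))
  expect_true(all(f$coefficients[paste0("cut_", f$degenerate_thresholds)] == Inf))
  expect_true(all(is.finite(f$coefficients[f$estimable])))
})

test_that("hetero-AR(1) working association is estimated and valid", {
  d <- generate_trial(trial_config(), seed = 59)
  f <- suppressWarnings(fit_ordinal_gee(d, "vas", working = "hetero_ar1"))
  expect_true(f$converged)
  expect_gte(f$working$rho, 0); expect_lt(f$working$rho, 1)
  expect_true(all(f$working$phi > 0))
  expect_lt(f$score_norm, 1e-4)
  ev <- eigen(f$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10 * max(ev))
})

test_that("Wald treatment tests are definitional and guarded", {
  d <- generate_trial(trial_config(n_per_sequence = 5), seed = 60)
  f <- fit_ordinal_gee(d, "vas")
  w1 <- wald_treatment_test(f, "G")
  expect_equal(w1$statistic,
               unname((f$coefficients["G"] / sqrt(f$vcov["G", "G"]))^2))
  expect_equal(w1$df, 1)
  w5 <- wald_treatment_test(f)
  expect_equal(w5$df, 5)
  expect_error(wald_treatment_test(f, "nonexistent"), "not estimable")

  # exactly-zero tested coefficients give statistic 0, p = 1
  f0 <- f
  f0$coefficients[c("G", "G:P", "G:T2", "G:T3", "G:T4")] <- 0
  w0 <- wald_treatment_test(f0)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)
})

test_that("small-sample corrections inflate the sandwich", {
  d <- generate_trial(trial_config(n_per_sequence = 5), seed = 61)
  f <- fit_ordinal_gee(d, "vas")
  expect_identical(small_sample_correction(f, "none"), f$vcov)
  vmd <- small_sample_correction(f, "mancl_derouen")
  expect_true(all(diag(vmd) >= diag(f$vcov) - 1e-12))
  vkc <- small_sample_correction(f, "kauermann_carroll")
  # KC inflates less than MD
  expect_true(all(diag(vkc) <= diag(vmd) + 1e-8))
  ev <- eigen(vkc, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))

  f1 <- f
  f1$n_clusters <- 1L
  expect_error(small_sample_correction(f1, "mancl_derouen"), "2 clusters")
})

test_that("non-convergence raises a typed error carrying the last iterate", {
  d <- generate_trial(trial_config(n_per_sequence = 4), seed = 62)
  cnd <- tryCatch(fit_ordinal_gee(d, "vas", max_iter = 1),
                  rarecross_gee_nonconvergence = function(c) c)
  expect_s3_class(cnd, "rarecross_gee_nonconvergence")
  expect_true(is.numeric(cnd$last_estimate))
})

test_that("validation rejects incomplete or off-scale data", {
  d <- generate_trial(trial_config(n_per_sequence = 2), seed = 63)
  d_bad <- d; d_bad$value[1] <- NA
  expect_error(fit_ordinal_gee(d_bad, "vas"), "complete")
  d_bad <- d; d_bad$value[1] <- 21
  expect_error(fit_ordinal_gee(d_bad, "vas"), "0..20")
  d_miss <- as_long_trial(d[d$time != 4, ])
  expect_error(fit_ordinal_gee(d_miss, "vas"), "8 occasions")
})

test_that("tidy and glance summarize a GEE fit", {
  d <- generate_trial(trial_config(n_per_sequence = 4), seed = 64)
  f <- fit_ordinal_gee(d, "vas")
  td <- tidy(f)
  expect_equal(nrow(td), 12)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in% names(td)))
  gl <- glance(f)
  expect_true(gl$converged)
  expect_equal(gl$n_clusters, 8)
})
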