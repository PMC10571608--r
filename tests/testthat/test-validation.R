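test_that("mse averages squared residuals over complete pairs", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(1, 2, 3), c(2, 2, 2)), 2 / 3)
  expect_equal(mse(c(1, 2, NA, 3), c(2, 2, 5, 2)), (1 + 0 + 1) / 3)
  expect_error(mse(c(NA, NA), c(1, 2)), "no complete")
})

test_that("relative MSE difference reproduces printed model-vs-null improvements", {
  # printed MSE pairs and their printed relative differences (percent)
  expect_equal(round(100 * mse_relative_difference(136.78, 119.52), 2), 12.62)
  expect_equal(round(100 * mse_relative_difference(187.16, 164.23), 2), 12.25)
  expect_equal(round(100 * mse_relative_difference(247.90, 172.59), 2), 30.38)
  expect_equal(round(100 * mse_relative_difference(202.27, 177.53), 2), 12.23)
  expect_equal(round(100 * mse_relative_difference(172.15, 164.34), 2), 4.54)
  # pairs limited by the rounding of the printed MSEs themselves
  expect_equal(100 * mse_relative_difference(172.15, 152.60), 11.35,
               tolerance = 0.05 / 11.35)
  expect_equal(100 * mse_relative_difference(13.82, 11.72), 15.17,
               tolerance = 0.05 / 15.17)
  expect_equal(100 * mse_relative_difference(0.785, 0.708), 9.82,
               tolerance = 0.05 / 9.82)
  expect_equal(mse_relative_difference(5, 5), 0)
  expect_error(mse_relative_difference(0, 1), "positive")
})

test_that("pearson_prediction_r matches hand-computed values", {
  expect_equal(pearson_prediction_r(1:4, 1:4), 1)
  expect_equal(pearson_prediction_r(1:4, -(1:4)), -1)
  expect_equal(pearson_prediction_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_prediction_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_prediction_r(1:2, 1:2), "3 complete")
})

test_that("corrected CV t-test handles degenerate and limiting cases", {
  # identical models
  res0 <- corrected_cv_ttest(rep(0, 20), n_train = 72, n_test = 8)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  # zero variance, nonzero mean
  res1 <- corrected_cv_ttest(rep(0.3, 20), n_train = 72, n_test = 8)
  expect_true(res1$degenerate)
  expect_lt(res1$p, 1e-300)
  # as n_test/n_train -> 0 the statistic approaches the classical paired t
  set.seed(30)
  d <- rnorm(100, 0.2)
  res2 <- corrected_cv_ttest(d, n_train = 1e9, n_test = 1)
  classical <- t.test(d)
  expect_equal(res2$t, unname(classical$statistic), tolerance = 1e-6)
  expect_equal(res2$p, classical$p.value, tolerance = 1e-6)
  expect_error(corrected_cv_ttest(0.5, 10, 2), "at least 2")
})

test_that("corrected test is calibrated under the null; the naive test is not", {
  # two equally good linear models compared over 10x10-fold CV on null
  # cohorts: rejection at alpha = .05 should be near nominal for the
  # corrected statistic and inflated for the uncorrected one
  set.seed(500)
  k <- 10; reps <- 10; n <- 40
  n_cohorts <- 500
  rej_corr <- rej_naive <- logical(n_cohorts)
  for (cix in seq_len(n_cohorts)) {
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- x1 + x2 + rnorm(n)
    d <- numeric(k * reps)
    pos <- 0
    for (r in seq_len(reps)) {
      fold <- sample(rep_len(1:k, n))
      for (f in 1:k) {
        te <- fold == f; tr <- !te
        p1 <- cbind(1, x1[te]) %*% .lm.fit(cbind(1, x1[tr]), y[tr])$coefficients
        p2 <- cbind(1, x2[te]) %*% .lm.fit(cbind(1, x2[tr]), y[tr])$coefficients
        pos <- pos + 1
        d[pos] <- mean((y[te] - p1)^2) - mean((y[te] - p2)^2)
      }
    }
    n_te <- n / k
    rej_corr[cix] <- corrected_cv_ttest(d, n - n_te, n_te)$p < 0.05
    rej_naive[cix] <- corrected_cv_ttest(d, n - n_te, n_te, corrected = FALSE)$p < 0.05
  }
  rate <- mean(rej_corr)
  expect_gte(rate, 0.033)
  expect_lte(rate, 0.071)
  expect_gt(mean(rej_naive), 0.071)
})

test_that("compare_models pairs fold losses of model and null on identical folds", {
  tab <- planted_table(n = 60, p_noise = 6, beta = 1, noise_sd = 0.5, seed = 18)
  cmp <- compare_models(tab$features, tab$cohort, baseline_spec(states = "task"),
                        scheme = cv_kfold(10, 5, seed = 3))
  expect_equal(nrow(cmp$fold_diffs), 50)
  expect_gt(cmp$mse_diff, 0)    # planted effect: GPM beats null
  expect_lt(cmp$t, 0)           # lower loss for the model
  expect_lt(cmp$p, 0.05)
  expect_equal(cmp$mse_diff,
               (cmp$mse_null - cmp$mse_model) / cmp$mse_null)
})

test_that("permutation p follows the add-one rule and detects real signal", {
  tab <- planted_table(n = 50, p_noise = 4, beta = 1.5, noise_sd = 0.3, seed = 25)
  pt <- permutation_test(tab$features, tab$cohort, baseline_spec(states = "task"),
                         scheme = cv_kfold(5, 1, seed = 2), n_perm = 199, seed = 11)
  # strong planted signal: observed r should beat every permutation
  expect_equal(pt$p, 1 / 200)
  expect_gt(pt$r_obs, 0.8)
  expect_length(pt$r_null, 199)
  expect_warning(
    permutation_test(tab$features, tab$cohort, baseline_spec(states = "task"),
                     scheme = cv_kfold(5, 1, seed = 2), n_perm = 50, seed = 1),
    "coarse")
})

test_that("permutation p is invariant to affine rescaling of the target", {
  tab <- planted_table(n = 40, p_noise = 4, beta = 1, noise_sd = 0.6, seed = 26)
  spec <- baseline_spec(states = "task")
  p1 <- permutation_test(tab$features, tab$cohort, spec,
                         scheme = cv_kfold(5, 1, seed = 2), n_perm = 100,
                         seed = 7)$p
  coh2 <- tab$cohort
  coh2$anhedonia_baseline <- 10 + 3 * coh2$anhedonia_baseline
  p2 <- permutation_test(tab$features, coh2, spec,
                         scheme = cv_kfold(5, 1, seed = 2), n_perm = 100,
                         seed = 7)$p
  expect_equal(p1, p2)
})

test_that("permutation p-values are uniform under the null", {
  # no-signal cohorts: p should be approximately Uniform(0, 1)
  set.seed(60)
  n <- 40
  spec <- baseline_spec(states = "task")
  ps <- vapply(1:60, function(s) {
    tab <- planted_table(n = n, p_noise = 4, beta = 0, noise_sd = 1,
                         seed = 7000 + s)
    permutation_test(tab$features, tab$cohort, spec,
                     scheme = cv_kfold(5, 1, seed = s), n_perm = 100,
                     seed = s)$p
  }, 0)
  # permutation p-values are discrete (multiples of 1/101), so ties are
  # expected; the KS approximation is still adequate at this alpha
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})
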