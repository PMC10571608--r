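test_that("fit_gpm recovers exact coefficients and flags collinearity", {
  x <- c(1, 2, 3, 4, 5)
  y <- 2 * x + 3
  fit <- fit_gpm(x, y)
  expect_equal(unname(fit$coefficients), c(3, 2), tolerance = 1e-10)

  # brain coefficient near 0 when target is independent of the feature
  set.seed(3)
  n <- 200
  xf <- rnorm(n); cv <- rnorm(n)
  yy <- 0.5 * cv + rnorm(n)
  fit2 <- fit_gpm(xf, yy, covariates = cbind(c1 = cv))
  se <- sqrt(sum(fit2$residuals^2) / (n - 3)) / sqrt(sum((xf - mean(xf))^2))
  expect_lt(abs(fit2$coefficients[["brain"]]), 2.5 * se)

  # duplicated covariate: rank-deficiency error naming the column
  expect_error(fit_gpm(xf, yy, covariates = cbind(c1 = cv, c2 = cv)),
               "collinear.*c2")
})

test_that("noiseless planted effect is predicted exactly under LOOCV", {
  tab <- planted_table(n = 40, p_noise = 5, beta = 2, noise_sd = 0, seed = 9)
  res <- cross_validate_gpm(tab$features, tab$cohort, baseline_spec(states = "task"),
                            cv_loocv())
  expect_lt(res$mse, 1e-8)
  expect_equal(res$pearson_r, 1, tolerance = 1e-6)
  expect_true(all(res$fold_summary$selected_feature == "task:planted_metric"))
  expect_equal(res$n_used, 40)
})

test_that("feature selection and fitting never leak held-out information", {
  # canary: a feature equal to the target for the held-out subject only
  # (noise for all training subjects) must not improve CV error -- a leaky
  # pipeline would latch onto it and predict the held-out subject perfectly
  tab <- planted_table(n = 40, p_noise = 6, beta = 0.8, noise_sd = 0.7, seed = 31)
  spec <- baseline_spec(states = "task")
  res_honest <- cross_validate_gpm(tab$features, tab$cohort, spec, cv_loocv())
  n <- nrow(tab$features)
  set.seed(21)
  canary_noise <- rnorm(n)
  preds <- vapply(seq_len(n), function(i) {
    f2 <- tab$features
    f2[["task:canary"]] <- canary_noise
    f2[["task:canary"]][i] <- tab$target[i] # informative only when held out
    res <- cross_validate_gpm(f2, tab$cohort, spec, cv_loocv())
    res$predictions$predicted[res$predictions$subject_id ==
                                tab$features$subject_id[i]]
  }, 0)
  mse_canary <- mean((tab$target - preds)^2)
  expect_gte(mse_canary, res_honest$mse * 0.98)
})

test_that("permuted targets give chance-level prediction", {
  tab <- planted_table(n = 50, p_noise = 8, beta = 1, noise_sd = 0.5, seed = 77)
  rs <- vapply(1:50, function(s) {
    set.seed(s)
    coh <- tab$cohort
    coh$anhedonia_baseline <- sample(coh$anhedonia_baseline)
    res <- cross_validate_gpm(tab$features, coh, baseline_spec(states = "task"),
                              cv_kfold(5, 1, seed = s))
    res$pearson_r
  }, 0)
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("LOOCV and 10-fold give similar error on a planted cohort", {
  tab <- planted_table(n = 80, p_noise = 10, beta = 1, noise_sd = 0.5, seed = 5)
  spec <- baseline_spec(states = "task")
  m_loo <- cross_validate_gpm(tab$features, tab$cohort, spec, cv_loocv())$mse
  m_k10 <- cross_validate_gpm(tab$features, tab$cohort, spec,
                              cv_kfold(10, 1, seed = 2))$mse
  expect_lt(abs(m_loo - m_k10) / m_loo, 0.15)
})

test_that("identical inputs and seeds give bit-identical results", {
  tab <- planted_table(n = 40, p_noise = 6, seed = 8)
  spec <- baseline_spec(states = "task")
  a <- cross_validate_gpm(tab$features, tab$cohort, spec, cv_kfold(5, 2, seed = 4))
  b <- cross_validate_gpm(tab$features, tab$cohort, spec, cv_kfold(5, 2, seed = 4))
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$mse, b$mse)
})

test_that("the log1p transform is applied for mania and reported on that scale", {
  set.seed(12)
  n <- 40
  feats <- tibble::tibble(subject_id = sprintf("s%02d", 1:n),
                          `task:metric` = rnorm(n))
  # mania generated so that log(x+1) is exactly linear in the feature
  lat <- 1.5 + 0.8 * feats$`task:metric`
  cohort <- tibble::tibble(
    subject_id = feats$subject_id,
    medication_load = abs(rnorm(n)),
    anhedonia_baseline = rnorm(n), impulsivity_baseline = rnorm(n),
    mania_baseline = expm1(lat)
  )
  spec <- gpm_spec("mania", "baseline", states = "task")
  expect_equal(spec$transform, "log1p")
  res <- cross_validate_gpm(feats, cohort, spec, cv_loocv())
  expect_equal(sort(unique(res$predictions$observed)), sort(lat),
               tolerance = 1e-10) # modeling scale, not raw scores
  expect_lt(res$mse, 1)
  spec_none <- gpm_spec("mania", "baseline", transform = "none", states = "task")
  res2 <- cross_validate_gpm(feats, cohort, spec_none, cv_loocv())
  expect_equal(sort(unique(res2$predictions$observed)), sort(expm1(lat)))
})

test_that("null model ignores brain features and tracks covariates", {
  set.seed(44)
  n <- 60
  med <- rnorm(n)
  cohort <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:n),
    medication_load = med,
    anhedonia_baseline = 3 + 2 * med, # pure function of a covariate
    impulsivity_baseline = rnorm(n), mania_baseline = abs(rnorm(n))
  )
  res <- null_model_cv(cohort, baseline_spec(), cv_loocv())
  expect_lt(res$mse, 1e-10)
  expect_true(all(is.na(res$fold_summary$selected_feature)))

  # brain-only target: null MSE approaches the target variance
  tab <- planted_table(n = 100, p_noise = 3, beta = 1, noise_sd = 0.3, seed = 6)
  resn <- null_model_cv(tab$cohort, baseline_spec(), cv_loocv(),
                        features = tab$features)
  expect_equal(resn$mse, var(tab$target), tolerance = 0.25 * var(tab$target))
  # and the GPM beats it
  resg <- cross_validate_gpm(tab$features, tab$cohort,
                             baseline_spec(states = "task"), cv_loocv())
  expect_lt(resg$mse, resn$mse)
})

test_that("pairwise deletion drops subjects missing target, covariates or features", {
  tab <- planted_table(n = 30, p_noise = 4, seed = 14)
  coh <- tab$cohort
  coh$anhedonia_baseline[1] <- NA
  coh$medication_load[2] <- NA
  feats <- tab$features
  feats[[2]][3] <- NA
  res <- cross_validate_gpm(feats, coh, baseline_spec(states = "task"), cv_loocv())
  expect_equal(res$n_used, 27)
  expect_false(any(res$predictions$subject_id %in% sprintf("s%03d", 1:3)))
})

test_that("group transfer trains once on one group and predicts the other", {
  # identical planted effect in both groups: transfer MSE comparable to
  # within-group CV error
  spec <- baseline_spec(states = "task")
  ratios <- vapply(10:14, function(s) {
    tab <- planted_table(n = 200, p_noise = 6, beta = 1, noise_sd = 0.5, seed = s)
    tr <- transfer_fit_predict(tab$features, tab$cohort, spec,
                               train_group = "unipolar", test_group = "bipolar")
    expect_equal(tr$selected_feature, "task:planted_metric")
    expect_gt(tr$mse_diff, 0)
    uni <- tab$cohort$group == "unipolar"
    cvres <- cross_validate_gpm(tab$features[uni, ], tab$cohort[uni, ], spec,
                                cv_loocv())
    abs(tr$gpm$mse - cvres$mse) / cvres$mse
  }, 0)
  expect_lt(mean(ratios), 0.25)

  # effect present only in the training group: test r near zero
  set.seed(15)
  n <- 160
  feats <- tibble::tibble(subject_id = sprintf("s%03d", 1:n),
                          `task:metric` = rnorm(n), `task:noise` = rnorm(n))
  grp <- rep(c("unipolar", "bipolar"), each = n / 2)
  y <- ifelse(grp == "unipolar", feats$`task:metric`, 0) + rnorm(n, sd = 0.5)
  coh <- tibble::tibble(subject_id = feats$subject_id, group = grp,
                        medication_load = abs(rnorm(n)),
                        anhedonia_baseline = y,
                        impulsivity_baseline = rnorm(n),
                        mania_baseline = abs(rnorm(n)))
  tr2 <- transfer_fit_predict(feats, coh, spec)
  expect_lt(abs(tr2$gpm$pearson_r), 0.35)

  coh3 <- coh[coh$group == "unipolar", ]
  expect_error(transfer_fit_predict(feats, coh3, spec), "test group")
})
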