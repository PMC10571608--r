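#' Mean squared prediction error
#'
#' Mean of squared residuals over complete observed/predicted pairs.
#'
#' @param observed,predicted Equal-length numeric vectors; pairs with a
#'   missing value are dropped.
#' @return Scalar MSE.
#' @export
mse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ok <- !is.na(observed) & !is.na(predicted)
  if (!any(ok)) stop("no complete observed/predicted pairs", call. = FALSE)
  mean((observed[ok] - predicted[ok])^2)
}

#' Relative MSE difference between a model and its null
#'
#' `(mse_null - mse_model) / mse_null`: the fraction by which the model's
#' error is lower than the covariates-only null model's. Positive values
#' mean the brain predictor adds information beyond baseline symptoms and
#' medication load.
#'
#' @param mse_null,mse_model Mean squared errors of the null and full model.
#' @return Fraction (multiply by 100 for percent).
#' @examples
#' mse_relative_difference(136.78, 119.52) # 0.1262
#' @export
mse_relative_difference <- function(mse_null, mse_model) {
  if (!is.finite(mse_null) || mse_null <= 0) {
    stop("mse_null must be positive", call. = FALSE)
  }
  (mse_null - mse_model) / mse_null
}

#' Pearson correlation between predicted and observed scores
#'
#' @param observed,predicted Numeric vectors; pairs with missing values are
#'   dropped. Both must be non-constant with at least 3 complete pairs.
#' @return Scalar correlation.
#' @export
pearson_prediction_r <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ok <- !is.na(observed) & !is.na(predicted)
  if (sum(ok) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  o <- observed[ok]; p <- predicted[ok]
  if (stats::sd(o) == 0 || stats::sd(p) == 0) {
    stop("constant vector: correlation undefined", call. = FALSE)
  }
  stats::cor(o, p)
}

#' Corrected repeated k-fold cross-validation t-test
#'
#' Paired t-test on per-fold loss differences between two models evaluated
#' on identical folds, with the Nadeau-Bengio variance correction for the
#' overlap of training sets across folds:
#' `t = mean(d) / sqrt((1/(k r) + n_test/n_train) * var(d))` with
#' `df = k r - 1`. The naive resampled t-test (correction factor `1/(k r)`
#' alone) is anti-conservative because fold losses are positively
#' correlated; the added `n_test/n_train` term restores approximate
#' type-I-error control.
#'
#' @param error_diffs Vector of per-fold differences in mean loss
#'   (model A minus model B), length `k * repeats`.
#' @param n_train,n_test Training and test set sizes per fold (scalars;
#'   averages are fine for unequal folds).
#' @param corrected If `FALSE`, omit the `n_test/n_train` term (the naive,
#'   anti-conservative variant; exposed for calibration studies).
#' @return List with `t`, `p` (two-sided), `df`, `mean_diff`, and a
#'   `degenerate` flag for zero-variance inputs.
#' @export
corrected_cv_ttest <- function(error_diffs, n_train, n_test, corrected = TRUE) {
  d <- error_diffs[!is.na(error_diffs)]
  m <- length(d)
  if (m < 2) stop("need at least 2 fold-level differences", call. = FALSE)
  stopifnot(n_train > 0, n_test > 0)
  mu <- mean(d)
  v <- stats::var(d)
  fac <- 1 / m + if (corrected) n_test / n_train else 0
  df <- m - 1
  if (v == 0) {
    if (mu == 0) {
      return(list(t = 0, p = 1, df = df, mean_diff = 0, degenerate = TRUE))
    }
    return(list(t = sign(mu) * Inf, p = .Machine$double.xmin, df = df,
                mean_diff = mu, degenerate = TRUE))
  }
  t <- mu / sqrt(fac * v)
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df, mean_diff = mu,
       degenerate = FALSE)
}

# Per-fold MSE vector for one model on fixed folds/subjects.
fold_mse_for_model <- function(model, mf, folds, spec, E = NULL, cpm_opts = list()) {
  if (model == "gpm") {
    eng <- cv_engine(mf$X, mf$y, mf$C, folds, brain = TRUE, min_train = spec$min_train)
  } else if (model == "null") {
    eng <- cv_engine(NULL, mf$y, mf$C, folds, brain = FALSE, min_train = spec$min_train)
  } else if (model == "cpm") {
    eng <- do.call(cv_engine_cpm, c(list(E = E, y = mf$y, C = mf$C, folds = folds,
                                         min_train = spec$min_train), cpm_opts))
  } else {
    stop("unknown model: ", model, call. = FALSE)
  }
  eng
}

#' Compare two cross-validated models with the corrected CV t-test
#'
#' Evaluates both models on identical repeated k-fold assignments and
#' identical complete-case subjects, takes the per-fold difference in mean
#' squared error, and applies [corrected_cv_ttest()]. Also reports each
#' model's pooled MSE and the relative MSE difference. Models: `"gpm"`,
#' `"null"` (covariates only), or `"cpm"` (requires `connectomes`).
#'
#' @inheritParams cross_validate_gpm
#' @param model,reference The two models compared; `reference` losses are
#'   subtracted from `model` losses, so a negative `t` / positive `mse_diff`
#'   favors `model`.
#' @param connectomes List of [connectome()] objects (needed when either
#'   side is `"cpm"`).
#' @param cpm_opts Options passed to the CPM engine: `polarity`,
#'   `weight_mode`, `p_threshold`, `state`.
#' @param scheme A [cv_kfold()] scheme (repeated k-fold; the correction's
#'   variance term is undefined for leave-one-out folds).
#' @return An object of class `gpm_comparison`: `mse_model`, `mse_null`,
#'   `mse_diff`, `t`, `p`, `df`, fold sizes, and the per-fold difference
#'   table.
#' @export
compare_models <- function(features, cohort, spec = gpm_spec(),
                           scheme = cv_kfold(10, 10, seed = 1),
                           model = "gpm", reference = "null",
                           connectomes = NULL, cpm_opts = list()) {
  if (scheme$type != "kfold") {
    stop("compare_models requires a cv_kfold scheme (repeated k-fold)", call. = FALSE)
  }
  mf <- prepare_model_frame(cohort, spec, features)
  E <- NULL
  if ("cpm" %in% c(model, reference)) {
    if (is.null(connectomes)) stop("connectomes required for the CPM", call. = FALSE)
    em <- edge_matrix(connectomes,
                      state = cpm_opts$state %||% spec$states[1],
                      weight_mode = cpm_opts$weight_mode %||% "signed")
    keep <- mf$subject_id %in% em$subject_id
    if (!all(keep)) {
      mf <- lapply(mf, function(v) if (is.null(v) || length(v) == 1) v else
        if (is.matrix(v)) v[keep, , drop = FALSE] else v[keep])
      mf$n <- sum(keep)
    }
    E <- em$E[match(mf$subject_id, em$subject_id), , drop = FALSE]
    cpm_opts$state <- NULL; cpm_opts$weight_mode <- NULL
  }
  if (mf$n < 10) stop("need at least 10 complete cases, got ", mf$n, call. = FALSE)
  folds <- make_folds(mf$n, scheme)
  eng_a <- fold_mse_for_model(model, mf, folds, spec, E, cpm_opts)
  eng_b <- fold_mse_for_model(reference, mf, folds, spec, E, cpm_opts)
  d <- eng_a$fold_mse - eng_b$fold_mse
  n_train <- mean(eng_a$n_train)
  n_test <- mean(eng_a$n_test)
  tt <- corrected_cv_ttest(d, n_train, n_test)
  mse_a <- mean((mf$y[eng_a$idx] - eng_a$pred)^2)
  mse_b <- mean((mf$y[eng_b$idx] - eng_b$pred)^2)
  structure(
    list(model = model, reference = reference,
         mse_model = mse_a, mse_null = mse_b,
         mse_diff = mse_relative_difference(mse_b, mse_a),
         t = tt$t, p = tt$p, df = tt$df,
         k = scheme$k, repeats = scheme$repeats,
         n_train = n_train, n_test = n_test, n_used = mf$n,
         fold_diffs = tibble::tibble(
           repetition = eng_a$fold_rep, fold = eng_a$fold_id,
           mse_model = eng_a$fold_mse, mse_reference = eng_b$fold_mse,
           diff = d),
         spec = spec, scheme = scheme),
    class = "gpm_comparison"
  )
}

#' @export
print.gpm_comparison <- function(x, ...) {
  cat("<gpm_comparison>", x$model, "vs", x$reference, "on",
      x$spec$target_column, "\n")
  cat(sprintf("  MSE_%s = %.4g | MSE_%s = %.4g | MSE_diff = %.2f%%\n",
              x$model, x$mse_model, x$reference, x$mse_null, 100 * x$mse_diff))
  cat(sprintf("  corrected CV t(%d) = %.3f, p = %.3g (k = %d, repeats = %d, n = %d)\n",
              x$df, x$t, x$p, x$k, x$repeats, x$n_used))
  invisible(x)
}

#' Permutation test for better-than-chance prediction
#'
#' Shuffles the target scores among the included subjects (covariates and
#' features stay with their subjects), re-runs the full cross-validated
#' prediction for each permutation, and compares the observed
#' predicted-observed correlation against the permuted null distribution.
#' One-sided with the add-one rule:
#' `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)`.
#'
#' @inheritParams compare_models
#' @param scheme A [cv_loocv()] or [cv_kfold()] scheme used for every
#'   (re-)fit.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutations.
#' @return An object of class `gpm_permutation`: `p`, `r_obs`, the null
#'   distribution `r_null`, `n_perm`.
#' @export
permutation_test <- function(features, cohort, spec = gpm_spec(),
                             scheme = cv_loocv(), n_perm = 10000, seed = 1,
                             model = "gpm", connectomes = NULL,
                             cpm_opts = list()) {
  if (n_perm < 100) {
    warning("n_perm < 100 gives a very coarse p-value", call. = FALSE)
  }
  mf <- prepare_model_frame(cohort, spec, features)
  E <- NULL
  if (model == "cpm") {
    if (is.null(connectomes)) stop("connectomes required for the CPM", call. = FALSE)
    em <- edge_matrix(connectomes,
                      state = cpm_opts$state %||% spec$states[1],
                      weight_mode = cpm_opts$weight_mode %||% "signed")
    E <- em$E[match(mf$subject_id, em$subject_id), , drop = FALSE]
    cpm_opts$state <- NULL; cpm_opts$weight_mode <- NULL
  }
  if (stats::sd(mf$y) == 0) stop("target is constant; permutation test undefined", call. = FALSE)
  folds <- make_folds(mf$n, scheme)
  run_r <- function(y) {
    mfp <- mf; mfp$y <- y
    eng <- fold_mse_for_model(model, mfp, folds, spec, E, cpm_opts)
    suppressWarnings(stats::cor(y[eng$idx], eng$pred))
  }
  r_obs <- run_r(mf$y)
  r_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) run_r(sample(mf$y)), 0)
  })
  r_null[is.na(r_null)] <- -Inf
  p <- (1 + sum(r_null >= r_obs)) / (1 + n_perm)
  structure(
    list(p = p, r_obs = r_obs, r_null = r_null, n_perm = n_perm,
         seed = seed, model = model, spec = spec),
    class = "gpm_permutation"
  )
}

#' @export
print.gpm_permutation <- function(x, ...) {
  cat("<gpm_permutation>", x$model, "on", x$spec$target_column, "\n")
  cat(sprintf("  r_obs = %.3f, p = %.4g (%d permutations)\n",
              x$r_obs, x$p, x$n_perm))
  invisible(x)
}
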