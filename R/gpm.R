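#' Fit the covariate-adjusted symptom regression for one selected feature
#'
#' Ordinary least squares of the (transformed) target on the selected brain
#' feature plus covariates. This is the model-building step applied inside
#' every cross-validation fold; it is exported for single-fit use and
#' inspection.
#'
#' @param feature Numeric vector: the selected graph-metric values.
#' @param target Numeric target vector (already transformed if applicable).
#' @param covariates Optional numeric matrix or data frame of covariates.
#' @return An object of class `gpm_fit` with named coefficients
#'   (`(Intercept)`, `brain`, covariate names), fitted values and residuals.
#' @export
fit_gpm <- function(feature, target, covariates = NULL) {
  n <- length(target)
  stopifnot(length(feature) == n)
  C <- if (is.null(covariates)) NULL else {
    C <- as.matrix(covariates)
    stopifnot(nrow(C) == n)
    C
  }
  D <- cbind(`(Intercept)` = 1, brain = feature, C)
  keep <- stats::complete.cases(D, target)
  D <- D[keep, , drop = FALSE]
  y <- target[keep]
  if (nrow(D) < ncol(D) + 1) {
    stop("need at least ", ncol(D) + 1, " complete cases to fit ", ncol(D),
         " coefficients", call. = FALSE)
  }
  beta <- ols_fit(D, y)
  fitted <- drop(D %*% beta)
  structure(
    list(coefficients = beta, fitted = fitted, residuals = y - fitted,
         n = nrow(D)),
    class = "gpm_fit"
  )
}

#' @export
print.gpm_fit <- function(x, ...) {
  cat("<gpm_fit> n =", x$n, "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
predict.gpm_fit <- function(object, feature, covariates = NULL, ...) {
  D <- cbind(1, feature, if (is.null(covariates)) NULL else as.matrix(covariates))
  drop(D %*% object$coefficients)
}

# Align a feature table with a cohort and extract complete cases for a spec.
# Returns X (features, may be NULL), y (transformed target), C (covariates),
# subject ids, and group labels.
prepare_model_frame <- function(cohort, spec, features = NULL) {
  tc <- spec$target_column
  if (!tc %in% names(cohort)) stop("cohort lacks target column ", tc, call. = FALSE)
  miss_cov <- setdiff(spec$covariates, names(cohort))
  if (length(miss_cov)) stop("cohort lacks covariate column(s): ",
                             paste(miss_cov, collapse = ", "), call. = FALSE)
  y <- apply_transform(cohort[[tc]], spec$transform)
  C <- as.matrix(cohort[, spec$covariates, drop = FALSE])
  X <- NULL
  if (!is.null(features)) {
    stopifnot("subject_id" %in% names(features))
    m <- match(cohort$subject_id, features$subject_id)
    X <- feature_matrix(features)[m, , drop = FALSE]
  }
  complete <- !is.na(y) & stats::complete.cases(C)
  if (!is.null(X)) complete <- complete & stats::complete.cases(X)
  list(
    X = if (is.null(X)) NULL else X[complete, , drop = FALSE],
    y = y[complete],
    C = C[complete, , drop = FALSE],
    subject_id = cohort$subject_id[complete],
    group = if ("group" %in% names(cohort)) cohort$group[complete] else NULL,
    n = sum(complete)
  )
}

# Core cross-validation engine on plain matrices (kept lean: it is re-run
# thousands of times during permutation inference).
# folds: list of repeats, each a list of test-index vectors.
cv_engine <- function(X, y, C, folds, brain = TRUE, min_train = 10L) {
  n <- length(y)
  nfold <- sum(lengths(folds))
  idx_all <- integer(0); rep_all <- integer(0); fold_all <- integer(0)
  pred_all <- numeric(0)
  f_mse <- numeric(nfold); f_sel <- character(nfold); f_r <- numeric(nfold)
  f_ntr <- integer(nfold); f_nte <- integer(nfold)
  f_rep <- integer(nfold); f_id <- integer(nfold)
  pos <- 0L
  for (r in seq_along(folds)) {
    for (f in seq_along(folds[[r]])) {
      pos <- pos + 1L
      te <- folds[[r]][[f]]
      tr <- setdiff(seq_len(n), te)
      if (length(tr) < min_train) {
        stop("fold with only ", length(tr), " training cases (minimum ",
             min_train, ")", call. = FALSE)
      }
      if (brain) {
        sel <- select_feature_idx(X[tr, , drop = FALSE], y[tr])
        D <- cbind(1, X[tr, sel$index], C[tr, , drop = FALSE])
        Dte <- cbind(1, X[te, sel$index], C[te, , drop = FALSE])
        colnames(D) <- c("(Intercept)", "brain", colnames(C))
        f_sel[pos] <- colnames(X)[sel$index]; f_r[pos] <- sel$r
      } else {
        D <- cbind(1, C[tr, , drop = FALSE])
        Dte <- cbind(1, C[te, , drop = FALSE])
        colnames(D) <- c("(Intercept)", colnames(C))
        f_sel[pos] <- NA_character_; f_r[pos] <- NA_real_
      }
      beta <- ols_fit(D, y[tr])
      pred <- drop(Dte %*% beta)
      idx_all <- c(idx_all, te)
      rep_all <- c(rep_all, rep.int(r, length(te)))
      fold_all <- c(fold_all, rep.int(f, length(te)))
      pred_all <- c(pred_all, pred)
      f_mse[pos] <- mean((y[te] - pred)^2)
      f_ntr[pos] <- length(tr); f_nte[pos] <- length(te)
      f_rep[pos] <- r; f_id[pos] <- f
    }
  }
  list(idx = idx_all, rep = rep_all, fold = fold_all, pred = pred_all,
       fold_mse = f_mse, fold_selected = f_sel, fold_sel_r = f_r,
       fold_rep = f_rep, fold_id = f_id, n_train = f_ntr, n_test = f_nte)
}

# Wrap engine output into the user-facing prediction-result object.
as_gpm_cv <- function(eng, y, subject_id, model, spec, scheme) {
  predictions <- tibble::tibble(
    subject_id = subject_id[eng$idx],
    repetition = eng$rep, fold = eng$fold,
    observed = y[eng$idx], predicted = eng$pred,
    selected_feature = eng$fold_selected[match(
      paste(eng$rep, eng$fold), paste(eng$fold_rep, eng$fold_id))]
  )
  fold_summary <- tibble::tibble(
    repetition = eng$fold_rep, fold = eng$fold_id,
    selected_feature = eng$fold_selected, selection_r = eng$fold_sel_r,
    mse = eng$fold_mse, n_train = eng$n_train, n_test = eng$n_test
  )
  structure(
    list(predictions = predictions, fold_summary = fold_summary,
         mse = mean((predictions$observed - predictions$predicted)^2),
         pearson_r = stats::cor(predictions$observed, predictions$predicted),
         n_used = length(y), model = model, spec = spec, scheme = scheme,
         permutation_p = NA_real_),
    class = "gpm_cv"
  )
}

#' @export
print.gpm_cv <- function(x, ...) {
  cat("<gpm_cv>", x$model, "model; target", x$spec$target_column,
      if (x$spec$transform != "none") paste0("(", x$spec$transform, ")"), "\n")
  cat("  n =", x$n_used, "| MSE =", signif(x$mse, 5),
      "| r =", signif(x$pearson_r, 3))
  if (!is.na(x$permutation_p)) cat(" | permutation p =", signif(x$permutation_p, 3))
  cat("\n")
  if (any(!is.na(x$fold_summary$selected_feature))) {
    tab <- sort(table(x$fold_summary$selected_feature), decreasing = TRUE)
    cat("  selected (folds):", paste0(names(tab), " x", tab, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Cross-validated graph-theoretical predictive model
#'
#' The GPM: within each training fold, the single graph-metric feature most
#' correlated with the (transformed) target is selected, an OLS model with
#' the covariates is fitted, and the held-out subjects are predicted from
#' their own feature and covariate values. Feature selection and fitting
#' never see held-out subjects. Subjects missing the target, any covariate
#' or any candidate feature are excluded (pairwise deletion per model).
#'
#' @param features Feature tibble from [assemble_features()].
#' @param cohort Cohort tibble: `subject_id`, symptom columns named
#'   `<symptom>_<time>`, `medication_load`, optional `group`.
#' @param spec A [gpm_spec()].
#' @param scheme A [cv_loocv()] or [cv_kfold()] scheme.
#' @return A `gpm_cv` object: per-subject predictions, per-fold selected
#'   features, MSE and Pearson r on the modeling scale.
#' @export
cross_validate_gpm <- function(features, cohort, spec = gpm_spec(),
                               scheme = cv_loocv()) {
  mf <- prepare_model_frame(cohort, spec, features)
  if (mf$n < 10) stop("need at least 10 complete cases, got ", mf$n, call. = FALSE)
  folds <- make_folds(mf$n, scheme)
  eng <- cv_engine(mf$X, mf$y, mf$C, folds, brain = TRUE,
                   min_train = spec$min_train)
  as_gpm_cv(eng, mf$y, mf$subject_id, "gpm", spec, scheme)
}

#' Cross-validated null model (covariates only)
#'
#' The same cross-validation machinery as [cross_validate_gpm()] with the
#' brain predictor removed: baseline symptoms and medication load only. Pass
#' `features` to evaluate the null model on exactly the complete-case
#' subjects the GPM uses.
#'
#' @inheritParams cross_validate_gpm
#' @param features Optional feature tibble used only to align the
#'   complete-case subject set with the GPM's.
#' @return A `gpm_cv` object with `model = "null"`.
#' @export
null_model_cv <- function(cohort, spec = gpm_spec(), scheme = cv_loocv(),
                          features = NULL) {
  mf <- prepare_model_frame(cohort, spec, features)
  if (mf$n < 10) stop("need at least 10 complete cases, got ", mf$n, call. = FALSE)
  folds <- make_folds(mf$n, scheme)
  eng <- cv_engine(NULL, mf$y, mf$C, folds, brain = FALSE,
                   min_train = spec$min_train)
  as_gpm_cv(eng, mf$y, mf$subject_id, "null", spec, scheme)
}

#' Train on one diagnostic group, predict the other
#'
#' Group-transfer mode: the feature is selected and the model fitted once on
#' all complete cases of the training group, then applied to the test group.
#' A companion covariates-only null model is fitted the same way. Used to
#' ask whether a model trained on unipolar-disorder subjects generalizes to
#' bipolar-disorder subjects.
#'
#' @inheritParams cross_validate_gpm
#' @param train_group,test_group Values of the cohort `group` column.
#' @return An object of class `gpm_transfer` with elements `gpm` and `null`
#'   (each holding predictions, `mse`, `pearson_r`), the selected feature,
#'   and `mse_diff`.
#' @export
transfer_fit_predict <- function(features, cohort, spec = gpm_spec(),
                                 train_group = "unipolar",
                                 test_group = "bipolar") {
  if (!"group" %in% names(cohort)) stop("cohort lacks a group column", call. = FALSE)
  mf <- prepare_model_frame(cohort, spec, features)
  tr <- which(mf$group == train_group)
  te <- which(mf$group == test_group)
  if (length(tr) == 0) stop("no complete cases in training group '",
                            train_group, "'", call. = FALSE)
  if (length(te) == 0) stop("no complete cases in test group '",
                            test_group, "'", call. = FALSE)
  sel <- select_feature_idx(mf$X[tr, , drop = FALSE], mf$y[tr])
  fit <- fit_gpm(mf$X[tr, sel$index], mf$y[tr], mf$C[tr, , drop = FALSE])
  pred <- predict(fit, mf$X[te, sel$index], mf$C[te, , drop = FALSE])
  null_fit <- ols_fit(cbind(`(Intercept)` = 1, mf$C[tr, , drop = FALSE]), mf$y[tr])
  null_pred <- drop(cbind(1, mf$C[te, , drop = FALSE]) %*% null_fit)
  obs <- mf$y[te]
  res <- function(p) list(
    predictions = tibble::tibble(subject_id = mf$subject_id[te],
                                 observed = obs, predicted = p),
    mse = mean((obs - p)^2),
    pearson_r = suppressWarnings(stats::cor(obs, p))
  )
  structure(
    list(gpm = res(pred), null = res(null_pred),
         selected_feature = colnames(mf$X)[sel$index], selection_r = sel$r,
         mse_diff = (res(null_pred)$mse - res(pred)$mse) / res(null_pred)$mse,
         n_train = length(tr), n_test = length(te),
         train_group = train_group, test_group = test_group, spec = spec),
    class = "gpm_transfer"
  )
}

#' @export
print.gpm_transfer <- function(x, ...) {
  cat("<gpm_transfer>", x$train_group, "->", x$test_group,
      "| n_train =", x$n_train, "n_test =", x$n_test, "\n")
  cat("  selected:", x$selected_feature, "\n")
  cat("  GPM MSE =", signif(x$gpm$mse, 5), "| null MSE =",
      signif(x$null$mse, 5), "| MSE_diff =",
      sprintf("%.2f%%", 100 * x$mse_diff), "\n")
  invisible(x)
}
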