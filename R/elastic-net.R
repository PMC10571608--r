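#' Elastic-net variant of the GPM
#'
#' Instead of winner-take-all selection, all candidate graph-metric features
#' enter a penalized regression. Within each outer training fold, features
#' are standardized and an inner cross-validation grid search over the
#' elastic-net mixing parameter alpha (0 to 1 in steps of 0.05: 21 values,
#' ridge to lasso) and an automatic lambda path picks the (alpha, lambda)
#' pair minimizing inner CV error; the refitted model predicts the held-out
#' subjects. Covariates enter unpenalized — they are confound adjustments,
#' not selectable predictors.
#'
#' @inheritParams cross_validate_gpm
#' @param alpha_grid Vector of elastic-net mixing parameters.
#' @param inner_k Number of inner CV folds for the (alpha, lambda) search.
#' @param seed Integer seed for the inner fold assignment.
#' @return A `gpm_cv` object with `model = "elastic_net"`; the per-fold
#'   `selected_feature` slot records the chosen alpha, lambda and number of
#'   nonzero brain features, and `fold_coefs` holds the nonzero feature
#'   names per fold.
#' @export
elastic_net_gpm <- function(features, cohort, spec = gpm_spec(),
                            alpha_grid = seq(0, 1, by = 0.05),
                            scheme = cv_loocv(), inner_k = 5, seed = 1) {
  mf <- prepare_model_frame(cohort, spec, features)
  if (mf$n < 10) stop("need at least 10 complete cases, got ", mf$n, call. = FALSE)
  p_brain <- ncol(mf$X)
  Z <- cbind(mf$X, mf$C)
  pf <- c(rep(1, p_brain), rep(0, ncol(mf$C)))
  folds <- make_folds(mf$n, scheme)
  nfold <- sum(lengths(folds))
  idx_all <- integer(0); rep_all <- integer(0); fold_all <- integer(0)
  pred_all <- numeric(0)
  f_mse <- numeric(nfold); f_sel <- character(nfold)
  f_ntr <- integer(nfold); f_nte <- integer(nfold)
  f_rep <- integer(nfold); f_id <- integer(nfold)
  fold_coefs <- vector("list", nfold)
  pos <- 0L
  for (r in seq_along(folds)) {
    for (f in seq_along(folds[[r]])) {
      pos <- pos + 1L
      te <- folds[[r]][[f]]
      tr <- setdiff(seq_len(mf$n), te)
      if (length(tr) < max(spec$min_train, 3 * inner_k)) {
        stop("too few training cases (", length(tr),
             ") for inner ", inner_k, "-fold tuning", call. = FALSE)
      }
      foldid <- with_seed(derive_seed(seed, "elastic") + pos,
                          sample(rep_len(seq_len(inner_k), length(tr))))
      best <- NULL
      for (a in alpha_grid) {
        cvfit <- glmnet::cv.glmnet(Z[tr, , drop = FALSE], mf$y[tr],
                                   alpha = a, foldid = foldid,
                                   penalty.factor = pf, standardize = TRUE)
        cvm_min <- min(cvfit$cvm)
        if (is.null(best) || cvm_min < best$cvm) {
          best <- list(cvm = cvm_min, alpha = a, fit = cvfit,
                       lambda = cvfit$lambda.min)
        }
      }
      pred <- drop(stats::predict(best$fit, Z[te, , drop = FALSE],
                                  s = "lambda.min"))
      cf <- as.matrix(stats::coef(best$fit, s = "lambda.min"))[, 1]
      nz <- names(cf)[cf != 0]
      nz_brain <- intersect(nz, colnames(mf$X))
      idx_all <- c(idx_all, te)
      rep_all <- c(rep_all, rep.int(r, length(te)))
      fold_all <- c(fold_all, rep.int(f, length(te)))
      pred_all <- c(pred_all, pred)
      f_mse[pos] <- mean((mf$y[te] - pred)^2)
      f_sel[pos] <- sprintf("alpha=%.2f,lambda=%.3g,nonzero=%d",
                            best$alpha, best$lambda, length(nz_brain))
      fold_coefs[[pos]] <- nz_brain
      f_ntr[pos] <- length(tr); f_nte[pos] <- length(te)
      f_rep[pos] <- r; f_id[pos] <- f
    }
  }
  eng <- list(idx = idx_all, rep = rep_all, fold = fold_all, pred = pred_all,
              fold_mse = f_mse, fold_selected = f_sel,
              fold_sel_r = rep(NA_real_, nfold),
              fold_rep = f_rep, fold_id = f_id,
              n_train = f_ntr, n_test = f_nte)
  out <- as_gpm_cv(eng, mf$y, mf$subject_id, "elastic_net", spec, scheme)
  out$fold_coefs <- fold_coefs
  out$alpha_grid <- alpha_grid
  out
}
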