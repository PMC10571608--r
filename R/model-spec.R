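#' Specify a symptom-prediction model
#'
#' A model spec names the target (symptom scale and time point), the target
#' transform, the covariate set, and the candidate brain features. For
#' baseline targets, the two other baseline symptom scales plus medication
#' load are covaried; for follow-up targets, all three baseline scales plus
#' medication load. Covariates enter the regression only, never feature
#' selection. For the (hypo)mania scale, whose scores are right-skewed, a
#' `log(x + 1)` transform is applied to the target (and prediction error is
#' reported on that modeling scale).
#'
#' @param target Symptom scale: `"anhedonia"`, `"impulsivity"` or `"mania"`.
#' @param time Time point: `"baseline"`, `"m3"` or `"m6"`.
#' @param transform `"auto"` (log1p iff target is mania), `"none"`, or
#'   `"log1p"`.
#' @param states Candidate cognitive states whose metrics form the feature
#'   pool (selection spans all of them).
#' @param metrics Optional character vector restricting candidate metric
#'   names; `NULL` uses every available metric.
#' @param covariates Optional explicit covariate column names, overriding the
#'   default structure described above.
#' @param min_train Minimum complete training cases required in any fold.
#' @return An object of class `gpm_spec`.
#' @examples
#' gpm_spec("anhedonia", "baseline", states = "task")
#' @export
gpm_spec <- function(target = c("anhedonia", "impulsivity", "mania"),
                     time = c("baseline", "m3", "m6"),
                     transform = c("auto", "none", "log1p"),
                     states = c("task", "rest"),
                     metrics = NULL,
                     covariates = NULL,
                     min_train = 10L) {
  target <- match.arg(target)
  time <- match.arg(time)
  transform <- match.arg(transform)
  if (transform == "auto") transform <- if (target == "mania") "log1p" else "none"
  if (is.null(covariates)) {
    base_scales <- if (time == "baseline") setdiff(symptom_scales, target) else symptom_scales
    covariates <- c(paste0(base_scales, "_baseline"), "medication_load")
  }
  tc <- target_column(target, time)
  if (tc %in% covariates) stop("target cannot be among the covariates", call. = FALSE)
  structure(
    list(target = target, time = time, target_column = tc,
         transform = transform, states = states, metrics = metrics,
         covariates = covariates, min_train = as.integer(min_train)),
    class = "gpm_spec"
  )
}

#' @export
print.gpm_spec <- function(x, ...) {
  cat("<gpm_spec> target:", x$target_column,
      if (x$transform != "none") paste0("(", x$transform, ")"), "\n")
  cat("  states:", paste(x$states, collapse = ", "), "\n")
  cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

apply_transform <- function(y, transform) {
  switch(transform,
    none = y,
    log1p = {
      if (any(y < -1, na.rm = TRUE)) {
        stop("log1p transform requires scores > -1", call. = FALSE)
      }
      log1p(y)
    },
    stop("unknown transform: ", transform, call. = FALSE)
  )
}

#' Cross-validation schemes
#'
#' `cv_loocv()` is leave-one-out cross-validation (each subject predicted by
#' a model trained on all others); `cv_kfold()` is (repeated) k-fold with a
#' seed controlling the fold assignment.
#'
#' @param k Number of folds.
#' @param repeats Number of independent repetitions of the k-fold split.
#' @param seed Integer seed for fold assignment.
#' @return An object of class `cv_scheme`.
#' @export
cv_loocv <- function() {
  structure(list(type = "loocv"), class = "cv_scheme")
}

#' @rdname cv_loocv
#' @export
cv_kfold <- function(k = 10, repeats = 1, seed = 1) {
  stopifnot(k >= 2, repeats >= 1)
  structure(list(type = "kfold", k = as.integer(k),
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "cv_scheme")
}

# Fold assignments: a list of repeats, each a list of test-index vectors.
make_folds <- function(n, scheme) {
  stopifnot(inherits(scheme, "cv_scheme"))
  if (scheme$type == "loocv") {
    return(list(as.list(seq_len(n))))
  }
  if (n < scheme$k) stop("fewer cases (", n, ") than folds (", scheme$k, ")", call. = FALSE)
  with_seed(scheme$seed, {
    lapply(seq_len(scheme$repeats), function(r) {
      assign_k <- sample(rep_len(seq_len(scheme$k), n))
      lapply(seq_len(scheme$k), function(f) which(assign_k == f))
    })
  })
}
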