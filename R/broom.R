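#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-subject predictions from a cross-validated model
#'
#' @param x A `gpm_cv` object.
#' @param ... Unused.
#' @return A tibble with one row per held-out prediction: `subject_id`,
#'   `repetition`, `fold`, `observed`, `predicted`, `residual`,
#'   `selected_feature`.
#' @export
tidy.gpm_cv <- function(x, ...) {
  dplyr::mutate(x$predictions, residual = .data$observed - .data$predicted,
                .after = "predicted")
}

#' One-row model summary for a cross-validated model
#'
#' @param x A `gpm_cv` object.
#' @param ... Unused.
#' @return A tibble: `model`, `target`, `transform`, `n_used`, `mse`,
#'   `pearson_r`, `permutation_p`, `n_folds`.
#' @export
glance.gpm_cv <- function(x, ...) {
  tibble::tibble(
    model = x$model, target = x$spec$target_column,
    transform = x$spec$transform, n_used = x$n_used,
    mse = x$mse, pearson_r = x$pearson_r,
    permutation_p = x$permutation_p,
    n_folds = nrow(x$fold_summary)
  )
}

#' @export
tidy.gpm_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.gpm_fit <- function(x, ...) {
  tibble::tibble(n = x$n,
                 sigma = sqrt(sum(x$residuals^2) / (x$n - length(x$coefficients))),
                 r_squared = 1 - sum(x$residuals^2) /
                   sum((x$fitted + x$residuals - mean(x$fitted + x$residuals))^2))
}

#' @export
tidy.gpm_comparison <- function(x, ...) {
  tibble::tibble(
    model = x$model, reference = x$reference,
    mse_model = x$mse_model, mse_null = x$mse_null,
    mse_diff = x$mse_diff, t = x$t, p = x$p, df = x$df,
    k = x$k, repeats = x$repeats, n_used = x$n_used
  )
}

#' @export
glance.gpm_comparison <- function(x, ...) tidy.gpm_comparison(x, ...)

#' @export
tidy.gpm_permutation <- function(x, ...) {
  tibble::tibble(r_null = x$r_null)
}

#' @export
glance.gpm_permutation <- function(x, ...) {
  tibble::tibble(model = x$model, r_obs = x$r_obs, p = x$p,
                 n_perm = x$n_perm)
}

#' @export
tidy.gpm_transfer <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$gpm$predictions, model = "gpm"),
    dplyr::mutate(x$null$predictions, model = "null")
  )
}

#' @export
glance.gpm_transfer <- function(x, ...) {
  tibble::tibble(
    train_group = x$train_group, test_group = x$test_group,
    selected_feature = x$selected_feature,
    mse_gpm = x$gpm$mse, mse_null = x$null$mse, mse_diff = x$mse_diff,
    r_gpm = x$gpm$pearson_r, n_train = x$n_train, n_test = x$n_test
  )
}

#' @export
tidy.gpm_recovery <- function(x, ...) x$replicates

#' @export
glance.gpm_recovery <- function(x, ...) {
  tibble::tibble(
    n_replicates = nrow(x$replicates),
    selection_rate = x$selection_rate, mean_r = x$mean_r,
    mean_mse_diff = x$mean_mse_diff, frac_beats_null = x$frac_beats_null
  )
}
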