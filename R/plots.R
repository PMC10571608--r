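#' Predicted-versus-observed scatter for a cross-validated model
#'
#' The standard predictive-modeling display: held-out predictions against
#' observed scores on the modeling scale, with the identity line and the
#' least-squares trend.
#'
#' @param object A `gpm_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gpm_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(
      title = sprintf("%s model: %s", object$model, object$spec$target_column),
      subtitle = sprintf("MSE = %.3g, r = %.3f, n = %d",
                         object$mse, object$pearson_r, object$n_used),
      x = "observed score", y = "predicted score"
    ) +
    ggplot2::theme_minimal()
}

#' Permutation null distribution of the prediction correlation
#'
#' @param object A `gpm_permutation` object.
#' @param ... Unused.
#' @return A ggplot object: histogram of permuted r with the observed r
#'   marked.
#' @export
autoplot.gpm_permutation <- function(object, ...) {
  df <- tibble::tibble(r = object$r_null[is.finite(object$r_null)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey75", colour = "white") +
    ggplot2::geom_vline(xintercept = object$r_obs, colour = "firebrick") +
    ggplot2::labs(
      title = sprintf("Permutation null (%d shuffles)", object$n_perm),
      subtitle = sprintf("r_obs = %.3f, p = %.4g", object$r_obs, object$p),
      x = "predicted-observed r under shuffled targets", y = "count"
    ) +
    ggplot2::theme_minimal()
}

#' Selected-feature frequency across cross-validation folds
#'
#' Shows how stable the winner-take-all selection is: the fraction of folds
#' in which each candidate feature won.
#'
#' @param x A `gpm_cv` object.
#' @return A ggplot object.
#' @export
plot_selection_stability <- function(x) {
  stopifnot(inherits(x, "gpm_cv"))
  df <- x$fold_summary |>
    dplyr::count(.data$selected_feature) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$selected_feature, .data$fraction),
    y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of folds selected",
                  title = "In-fold feature selection") +
    ggplot2::theme_minimal()
}

#' Heatmap of a connectome's Fisher-z matrix
#'
#' @param cz A [connectome()] object.
#' @return A ggplot object.
#' @export
plot_connectome <- function(cz) {
  stopifnot(inherits(cz, "connectome"))
  df <- tibble::as_tibble(as.data.frame.table(cz$z, responseName = "z"))
  names(df)[1:2] <- c("row", "col")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(title = sprintf("Connectome: %s (%s)", cz$subject_id,
                                  cz$state),
                  x = NULL, y = NULL, fill = "Fisher z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
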