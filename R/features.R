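#' Assemble the subject-by-feature table of candidate brain predictors
#'
#' Pivots long-format metric values (one row per subject, state and metric)
#' into a wide table with one column per candidate feature, named
#' `"state:metric"`. Columns are in canonical order: state label, then
#' metric name, both alphabetical — ties in feature selection are broken by
#' this order. Subjects missing a state's scan simply have `NA` in that
#' state's columns; exclusion is handled per model (pairwise deletion).
#'
#' @param metrics Long tibble with columns `subject_id`, `state`, `metric`,
#'   `value` (as produced by [connectome_metrics()]).
#' @param spec A [gpm_spec()]; its `states` and `metrics` fields restrict
#'   the candidate pool.
#' @return A tibble: `subject_id` plus one numeric column per feature.
#' @export
assemble_features <- function(metrics, spec = gpm_spec()) {
  stopifnot(is.data.frame(metrics),
            all(c("subject_id", "state", "metric", "value") %in% names(metrics)))
  pool <- dplyr::filter(metrics, .data$state %in% spec$states)
  if (!is.null(spec$metrics)) {
    pool <- dplyr::filter(pool, .data$metric %in% spec$metrics)
  }
  if (nrow(pool) == 0) stop("no candidate features after filtering", call. = FALSE)
  wide <- pool |>
    dplyr::mutate(feature = paste(.data$state, .data$metric, sep = ":")) |>
    dplyr::select("subject_id", "feature", "value") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "value")
  ord <- order(names(wide)[-1])
  wide[, c(1, 1 + ord)]
}

# Index of the |Pearson r|-maximizing column of X against y.
# Zero-variance columns are skipped; ties go to the first (canonical) column.
select_feature_idx <- function(X, y) {
  if (length(y) < 3) stop("feature selection requires >= 3 training subjects", call. = FALSE)
  r <- suppressWarnings(as.vector(stats::cor(X, y)))
  r[!is.finite(r)] <- NA_real_
  if (all(is.na(r))) stop("all candidate features have zero variance", call. = FALSE)
  j <- which.max(abs(r))
  list(index = j, r = r[j])
}

#' Select the single most symptom-associated feature
#'
#' The winner-take-all selection step: among the candidate features, return
#' the one with the largest absolute Pearson correlation with the
#' (transformed) target over the training subjects. Covariates play no role
#' here. Zero-variance features are skipped; ties are broken by canonical
#' column order.
#'
#' @param features Feature tibble from [assemble_features()] (or a bare
#'   numeric matrix).
#' @param target Numeric target vector aligned with `features` rows.
#' @param training_index Optional row indices restricting selection to the
#'   training subjects (default: all rows).
#' @return The selected feature name, with attribute `r` (the training
#'   correlation).
#' @export
select_feature <- function(features, target, training_index = NULL) {
  X <- feature_matrix(features)
  if (is.null(training_index)) training_index <- seq_len(nrow(X))
  Xt <- X[training_index, , drop = FALSE]
  yt <- target[training_index]
  keep <- stats::complete.cases(Xt, yt)
  sel <- select_feature_idx(Xt[keep, , drop = FALSE], yt[keep])
  structure(colnames(X)[sel$index], r = sel$r)
}

feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  stopifnot(is.data.frame(features))
  cols <- setdiff(names(features), "subject_id")
  X <- as.matrix(features[, cols, drop = FALSE])
  rownames(X) <- if ("subject_id" %in% names(features)) features$subject_id else NULL
  X
}
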