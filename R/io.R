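#' Read and write the pipeline's delimited file formats
#'
#' All tables are plain delimited text (tab-separated by default). Missing
#' values are empty fields. Connectome matrices are written as full
#' symmetric square matrices with node labels as header; the reader
#' validates symmetry within 1e-10.
#'
#' @name gpmnet-io
NULL

#' @describeIn gpmnet-io Read a node-by-time series matrix (nodes as rows;
#'   optional header row of node labels when `header = TRUE`).
#' @param path File path.
#' @param header Whether the first row holds node labels (time-series files)
#'   — node labels are always present for connectome files.
#' @param delim Field delimiter.
#' @export
read_matrix <- function(path, header = FALSE, delim = "\t") {
  x <- utils::read.table(path, header = header, sep = delim,
                         check.names = FALSE)
  as.matrix(x)
}

#' @describeIn gpmnet-io Write a bare numeric matrix.
#' @param m Matrix to write.
#' @export
write_matrix <- function(m, path, delim = "\t") {
  utils::write.table(m, path, sep = delim, row.names = FALSE,
                     col.names = !is.null(colnames(m)), quote = FALSE, na = "")
  invisible(path)
}

#' @describeIn gpmnet-io Read a square connectome matrix (node labels as
#'   header) into a [connectome()]; errors if asymmetric beyond 1e-10.
#' @param subject_id,state Identifiers attached to the connectome.
#' @export
read_connectome <- function(path, subject_id = NA_character_,
                            state = NA_character_, delim = "\t") {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = delim,
                                   check.names = FALSE))
  connectome(m, subject_id = subject_id, state = state,
             node_labels = colnames(m))
}

#' @describeIn gpmnet-io Write a connectome's full symmetric z matrix.
#' @param cz A [connectome()] object.
#' @export
write_connectome <- function(cz, path, delim = "\t") {
  stopifnot(inherits(cz, "connectome"))
  utils::write.table(format(cz$z, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = delim, row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

cohort_value_columns <- function() {
  c(as.vector(outer(symptom_scales, time_points, target_column)),
    "medication_load")
}

#' @describeIn gpmnet-io Read a cohort table (`subject_id`, `group`,
#'   `medication_load`, `<symptom>_<time>` columns; empty fields are
#'   missing). Unknown columns are kept with a warning.
#' @export
read_cohort_table <- function(path, delim = "\t") {
  tb <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          na = c("", "NA"))
  if (!"subject_id" %in% names(tb)) {
    stop("cohort table lacks a subject_id column", call. = FALSE)
  }
  tb$subject_id <- as.character(tb$subject_id)
  known <- c("subject_id", "group", cohort_value_columns())
  extra <- setdiff(names(tb), known)
  if (length(extra)) {
    warning("unknown cohort column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  tb
}

#' @describeIn gpmnet-io Write a cohort table (missing values as empty
#'   fields).
#' @param cohort Cohort tibble.
#' @export
write_cohort_table <- function(cohort, path, delim = "\t") {
  readr::write_delim(cohort, path, delim = delim, na = "")
  invisible(path)
}

#' @describeIn gpmnet-io Write long-format metric values
#'   (`subject_id`, `state`, `metric`, `value`).
#' @param metrics Long metric tibble.
#' @export
write_metrics <- function(metrics, path, delim = "\t") {
  readr::write_delim(metrics, path, delim = delim, na = "")
  invisible(path)
}

#' @describeIn gpmnet-io Read long-format metric values.
#' @export
read_metrics <- function(path, delim = "\t") {
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    na = c("", "NA"))
}

#' @describeIn gpmnet-io Write a prediction result: per-subject table plus a
#'   `# summary:` comment block (MSE, r, n).
#' @param result A `gpm_cv` object.
#' @export
write_prediction_result <- function(result, path, delim = "\t") {
  stopifnot(inherits(result, "gpm_cv"))
  summary_lines <- c(
    sprintf("# model: %s", result$model),
    sprintf("# target: %s (transform: %s)", result$spec$target_column,
            result$spec$transform),
    sprintf("# mse: %.10g", result$mse),
    sprintf("# pearson_r: %.10g", result$pearson_r),
    sprintf("# n_used: %d", result$n_used),
    if (!is.na(result$permutation_p))
      sprintf("# permutation_p: %.10g", result$permutation_p)
  )
  writeLines(summary_lines, path)
  suppressWarnings(
    readr::write_delim(result$predictions, path, delim = delim, na = "",
                       append = TRUE, col_names = TRUE)
  )
  invisible(path)
}

#' @describeIn gpmnet-io Read an ROI map from a YAML file (section
#'   `roi`: region name -> 1-based node indices).
#' @export
read_roi_map <- function(path) {
  y <- yaml::read_yaml(path)
  entries <- if (!is.null(y$roi)) y$roi else y
  roi_map(entries)
}
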