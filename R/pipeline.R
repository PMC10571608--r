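#' Run the full prediction pipeline from a configuration
#'
#' Orchestrates connectome construction (or reading), graph metrics, the
#' cross-validated GPM and its null model, and optionally the CPM, the
#' elastic-net variant, group transfer, model comparison and permutation
#' inference, for one or more model specs. Results and a machine-readable
#' run manifest (seeds, config hash, package version) are written to the
#' output directory. A failing model spec is reported and skipped; the
#' returned object records per-spec status.
#'
#' The configuration may be a YAML file path or an equivalent nested list:
#' \preformatted{
#' synthetic: { n_subjects: 40, effect_size: 0.25, ... }  # or
#' inputs: { connectomes: dir/, cohort: cohort.tsv, roi: roi.yaml }
#' models:
#'   - target: anhedonia
#'     time: baseline
#'     states: [task, rest]
#'     scheme: { type: loocv }          # or {type: kfold, k: 10, repeats: 10}
#'     compare: true                    # corrected CV t-test vs null
#'     cpm: false                       # add the CPM comparator
#'     permutations: 0                  # permutation test if > 0
#' seed: 1
#' output: out/
#' }
#' With a `synthetic` section the cohort is generated by
#' [simulate_cohort()]; with an `inputs` section, connectome matrices (one
#' file per subject/state named `<subject>_<state>.tsv`), the cohort table
#' and the ROI map are read from disk.
#'
#' @param config YAML file path or a nested list as above.
#' @return An object of class `gpm_pipeline`: per-spec results and the run
#'   manifest. Side effect: result tables and `manifest.json` under
#'   `output`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$output %||% NULL
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  if (!is.null(config$synthetic)) {
    cfg <- do.call(synthetic_config, config$synthetic)
    sc <- simulate_cohort(cfg, seed = seed)
    cohort <- sc$cohort; metrics <- sc$metrics
    connectomes <- sc$connectomes; roi <- sc$roi
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    for (p in c(inp$connectomes, inp$cohort, inp$roi)) {
      if (!is.null(p) && !file.exists(p)) {
        stop("input path does not exist: ", p, call. = FALSE)
      }
    }
    cohort <- read_cohort_table(inp$cohort)
    roi <- if (!is.null(inp$roi)) read_roi_map(inp$roi) else roi_map()
    files <- list.files(inp$connectomes, pattern = "\\.(tsv|txt|csv)$",
                        full.names = TRUE)
    if (length(files) == 0) stop("no connectome files found in ",
                                 inp$connectomes, call. = FALSE)
    connectomes <- lapply(files, function(f) {
      parts <- strsplit(sub("\\.[^.]+$", "", basename(f)), "_")[[1]]
      read_connectome(f, subject_id = parts[1],
                      state = paste(parts[-1], collapse = "_"))
    })
    metrics <- connectome_metrics(connectomes, roi)
  } else {
    stop("config needs either a 'synthetic' or an 'inputs' section", call. = FALSE)
  }

  model_cfgs <- config$models %||% list(list())
  results <- vector("list", length(model_cfgs))
  status <- character(length(model_cfgs))
  log_msg <- function(...) message("[gpmnet] ", ...)
  log_msg("cohort: ", nrow(cohort), " subjects; ",
          length(connectomes), " connectomes")

  for (i in seq_along(model_cfgs)) {
    mc <- model_cfgs[[i]]
    res <- tryCatch({
      spec <- gpm_spec(
        target = mc$target %||% "anhedonia",
        time = mc$time %||% "baseline",
        transform = mc$transform %||% "auto",
        states = unlist(mc$states %||% unique(metrics$state)),
        metrics = unlist(mc$metrics) %||% NULL
      )
      sch <- mc$scheme %||% list(type = "loocv")
      scheme <- if (identical(sch$type, "kfold")) {
        cv_kfold(sch$k %||% 10, sch$repeats %||% 1,
                 seed = sch$seed %||% derive_seed(seed, "folds"))
      } else cv_loocv()
      features <- assemble_features(metrics, spec)
      gpm <- cross_validate_gpm(features, cohort, spec, scheme)
      nul <- null_model_cv(cohort, spec, scheme, features = features)
      log_msg(spec$target_column, ": n = ", gpm$n_used,
              ", MSE = ", signif(gpm$mse, 5),
              " (null ", signif(nul$mse, 5), ")")
      one <- list(spec = spec, gpm = gpm, null = nul,
                  mse_diff = mse_relative_difference(nul$mse, gpm$mse))
      if (isTRUE(mc$compare)) {
        one$comparison <- compare_models(
          features, cohort, spec,
          scheme = cv_kfold(10, 10, seed = derive_seed(seed, "folds")))
      }
      if (isTRUE(mc$cpm)) {
        one$cpm <- cross_validate_cpm(connectomes, cohort, spec,
                                      scheme = scheme)
        one$cpm_comparison <- compare_models(
          features, cohort, spec,
          scheme = cv_kfold(10, 10, seed = derive_seed(seed, "folds")),
          model = "gpm", reference = "cpm", connectomes = connectomes)
      }
      n_perm <- mc$permutations %||% 0
      if (n_perm > 0) {
        perm <- permutation_test(features, cohort, spec, scheme,
                                 n_perm = n_perm,
                                 seed = derive_seed(seed, "permutation"))
        one$gpm$permutation_p <- perm$p
        one$permutation <- perm
      }
      if (!is.null(out_dir)) {
        write_prediction_result(
          one$gpm, file.path(out_dir, paste0(spec$target_column, "_gpm.tsv")))
        write_prediction_result(
          one$null, file.path(out_dir, paste0(spec$target_column, "_null.tsv")))
      }
      one
    }, error = function(e) {
      log_msg("model ", i, " FAILED: ", conditionMessage(e))
      structure(list(error = conditionMessage(e)), class = "gpm_pipeline_error")
    })
    results[[i]] <- res
    status[i] <- if (inherits(res, "gpm_pipeline_error")) "failed" else "ok"
  }

  manifest <- list(
    package = "gpmnet",
    version = as.character(utils::packageVersion("gpmnet")),
    seed = seed,
    config_hash = rlang::hash(config),
    n_models = length(model_cfgs),
    status = as.list(setNames(status, paste0("model_", seq_along(status)))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(
    list(results = results, status = status, manifest = manifest,
         cohort = cohort, metrics = metrics),
    class = "gpm_pipeline"
  )
}

#' @export
print.gpm_pipeline <- function(x, ...) {
  cat("<gpm_pipeline>", length(x$results), "model(s):",
      paste(x$status, collapse = ", "), "\n")
  for (res in x$results) {
    if (inherits(res, "gpm_pipeline_error")) {
      cat("  [failed]", res$error, "\n")
    } else {
      cat(sprintf("  %s: MSE = %.4g (null %.4g, MSE_diff %.2f%%)\n",
                  res$spec$target_column, res$gpm$mse, res$null$mse,
                  100 * res$mse_diff))
    }
  }
  invisible(x)
}
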