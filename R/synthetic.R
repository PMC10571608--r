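#' Configure a synthetic cohort with a planted brain-symptom effect
#'
#' The generator emulates the data structure the GPM consumes: per-subject,
#' per-state Fisher-z connectomes with latent community (block) structure;
#' three correlated symptom scales at baseline, 3 and 6 months with
#' realistic attrition; a medication-load covariate; and a two-level
#' diagnostic group label. One symptom at one time point carries a planted
#' linear dependence on a brain score with a configurable variance share
#' (`effect_size`, the target R-squared of the brain term). The brain score
#' is either a named graph metric (whose between-subject variation is driven
#' by a per-subject within-block connectivity gain) or, for edge-level
#' signals, a latent score written additively into a fixed set of edges.
#'
#' @param n_subjects Cohort size.
#' @param n_nodes,n_blocks Connectome size and number of latent communities.
#' @param states State labels; each state gets an independent realization of
#'   the shared block structure.
#' @param run_lengths Named list: time points per run for each state (the
#'   task state uses three runs, concatenated before correlation).
#' @param within_loading,global_loading Factor loadings of the block factor
#'   and a weak global factor shared by all nodes (keeps between-block
#'   correlations mildly positive, as in real connectomes).
#' @param ts_noise_sd Node-level time-series noise SD.
#' @param subject_gain_sd SD of the per-subject, per-block within-community
#'   connectivity gain.
#' @param between_gain_sd SD of the per-subject between-community
#'   (global-factor) gain — the main driver of integration metrics.
#' @param node_gain_sd SD of per-node connectivity gains — regional
#'   heterogeneity that gives nodal metrics node-specific variance.
#' @param state_cor Correlation of all connectivity gains across states
#'   (task and rest connectomes of one subject are similar but not
#'   identical).
#' @param planted_feature Feature name `"state:metric"` carrying the effect
#'   (metric mode), or `"none"` for a pure-null cohort.
#' @param planted_mode `"metric"` (effect rides on a graph metric) or
#'   `"edges"` (effect written into `n_signal_edges` random edges — the
#'   regime CPM is designed for).
#' @param n_signal_edges,edge_signal_sd Edge-mode signal geometry.
#' @param target_symptom,target_time Which symptom/time carries the effect.
#' @param effect_size Target R-squared of the brain term, in `[0, 1)`.
#' @param covariate_effects Standardized coefficients of the baseline
#'   symptom covariates and medication load in the generating model.
#' @param follow_up_ar Autocorrelation of follow-up scores with baseline
#'   (follow-up variance is mostly captured by baseline scores).
#' @param noise_sd Residual SD of the generating model on the standardized
#'   scale.
#' @param scale_cor Pairwise correlation of the three symptom scales.
#' @param missingness Named per-time-point visit-missingness rates; defaults
#'   follow typical longitudinal attrition (about 10% lost at 3 months,
#'   about 16% at 6 months).
#' @param bipolar_fraction Fraction of subjects labelled `"bipolar"`.
#' @param effect_groups Groups in which the planted effect is active
#'   (default both; restrict to test group-transfer behavior).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 80,
                             n_nodes = 16,
                             n_blocks = 4,
                             states = c("task", "rest"),
                             run_lengths = list(task = c(60, 60, 60), rest = 180),
                             within_loading = 0.9,
                             global_loading = 0.35,
                             ts_noise_sd = 1,
                             subject_gain_sd = 0.25,
                             between_gain_sd = 0.3,
                             node_gain_sd = 0.3,
                             state_cor = 0.4,
                             planted_feature = "rest:L_ACC_betweenness",
                             planted_mode = c("metric", "edges"),
                             n_signal_edges = 20,
                             edge_signal_sd = 0.08,
                             target_symptom = "impulsivity",
                             target_time = "baseline",
                             effect_size = 0.2,
                             covariate_effects = c(baseline_symptom = 0.3,
                                                   medication = 0.15),
                             follow_up_ar = 0.6,
                             noise_sd = 0.6,
                             scale_cor = 0.35,
                             missingness = c(baseline = 0.02, m3 = 0.10, m6 = 0.16),
                             bipolar_fraction = 22 / 80,
                             effect_groups = c("unipolar", "bipolar")) {
  planted_mode <- match.arg(planted_mode)
  stopifnot(n_nodes >= 8, n_blocks >= 2, n_nodes >= n_blocks,
            effect_size >= 0, effect_size < 1,
            bipolar_fraction >= 0, bipolar_fraction <= 1,
            all(missingness >= 0), all(missingness <= 1),
            all(names(run_lengths) %in% states) || length(run_lengths) >= length(states),
            target_symptom %in% symptom_scales, target_time %in% time_points)
  structure(
    list(n_subjects = n_subjects, n_nodes = n_nodes, n_blocks = n_blocks,
         states = states, run_lengths = run_lengths,
         within_loading = within_loading, global_loading = global_loading,
         ts_noise_sd = ts_noise_sd, subject_gain_sd = subject_gain_sd,
         between_gain_sd = between_gain_sd, node_gain_sd = node_gain_sd,
         state_cor = state_cor,
         planted_feature = planted_feature, planted_mode = planted_mode,
         n_signal_edges = n_signal_edges, edge_signal_sd = edge_signal_sd,
         target_symptom = target_symptom, target_time = target_time,
         effect_size = effect_size, covariate_effects = covariate_effects,
         follow_up_ar = follow_up_ar, noise_sd = noise_sd,
         scale_cor = scale_cor, missingness = missingness,
         bipolar_fraction = bipolar_fraction, effect_groups = effect_groups),
    class = "synthetic_config"
  )
}

# Observed-scale parameters of the three symptom scales. Anhedonia and
# impulsivity are roughly questionnaire-total-like; mania is parameterized
# on the log scale and exponentiated, so log(x + 1) is its natural
# transform.
scale_params <- list(
  anhedonia = list(mean = 80, sd = 13, log = FALSE),
  impulsivity = list(mean = 68, sd = 11, log = FALSE),
  mania = list(mean = 1.6, sd = 0.7, log = TRUE)
)

to_observed <- function(latent, scale) {
  p <- scale_params[[scale]]
  raw <- p$mean + p$sd * latent
  if (p$log) expm1(pmax(raw, 0)) else raw
}

#' Default ROI map for synthetic connectomes
#'
#' Assigns up to 12 side-tagged reward-circuit region names (bilateral ACC,
#' caudate, putamen, NAc, lateral and medial OFC) to the first nodes of a
#' synthetic connectome, one node each.
#'
#' @param n_nodes Number of nodes available.
#' @return A [roi_map()].
#' @export
synthetic_roi_map <- function(n_nodes = 16) {
  regions <- c("L_ACC", "R_ACC", "L_caudate", "R_caudate",
               "L_putamen", "R_putamen", "L_NAc", "R_NAc",
               "L_lOFC", "R_lOFC", "L_mOFC", "R_mOFC")
  k <- min(length(regions), n_nodes)
  roi_map(setNames(as.list(seq_len(k)), regions[seq_len(k)]), n = n_nodes)
}

#' Generate per-subject, per-state synthetic connectomes
#'
#' Each subject's node time series follow a latent block-factor model: nodes
#' load on their community's factor (scaled by a per-subject gain) plus a
#' weak global factor and noise; runs are generated per state and passed
#' through [build_connectome()]. In edge mode, a latent subject score is
#' additionally written into a fixed random edge set of the first state.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed.
#' @return A list of [connectome()] objects (subjects x states) with
#'   attributes `gains`, `blocks`, `subject_id`, and in edge mode
#'   `edge_latent` and `signal_edges`.
#' @export
generate_connectomes <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(seed, {
    n <- cfg$n_subjects
    ids <- sprintf("s%03d", seq_len(n))
    blocks <- sort(rep_len(seq_len(cfg$n_blocks), cfg$n_nodes))
    # cross-state-correlated gain fields: a shared subject component mixed
    # with a state-specific one at correlation state_cor
    mix <- function(shared, specific) {
      sqrt(cfg$state_cor) * shared + sqrt(1 - cfg$state_cor) * specific
    }
    block_trait <- matrix(stats::rnorm(n * cfg$n_blocks), n)
    between_trait <- stats::rnorm(n)
    node_trait <- matrix(stats::rnorm(n * cfg$n_nodes), n)
    gain_field <- lapply(cfg$states, function(s) {
      list(
        within = pmax(1 + cfg$subject_gain_sd *
                        mix(block_trait,
                            matrix(stats::rnorm(n * cfg$n_blocks), n)), 0.2),
        between = pmax(1 + cfg$between_gain_sd *
                         mix(between_trait, stats::rnorm(n)), 0.2),
        node = pmax(1 + cfg$node_gain_sd *
                      mix(node_trait,
                          matrix(stats::rnorm(n * cfg$n_nodes), n)), 0.2)
      )
    })
    names(gain_field) <- cfg$states
    edge_latent <- stats::rnorm(n)
    ut <- which(upper.tri(diag(cfg$n_nodes)))
    signal_edges <- sample(ut, min(cfg$n_signal_edges, length(ut)))
    out <- vector("list", n * length(cfg$states))
    pos <- 0L
    for (i in seq_len(n)) {
      for (s in cfg$states) {
        gf <- gain_field[[s]]
        node_amp <- gf$node[i, ]
        block_amp <- cfg$within_loading * gf$within[i, blocks]
        lens <- cfg$run_lengths[[s]]
        if (is.null(lens)) lens <- 150
        runs <- lapply(lens, function(tt) {
          f_block <- matrix(stats::rnorm(cfg$n_blocks * tt), cfg$n_blocks, tt)
          f_global <- stats::rnorm(tt)
          noise <- matrix(stats::rnorm(cfg$n_nodes * tt, sd = cfg$ts_noise_sd),
                          cfg$n_nodes, tt)
          node_amp * (block_amp * f_block[blocks, , drop = FALSE] +
                        cfg$global_loading * gf$between[i] *
                          rep(1, cfg$n_nodes) %o% f_global) + noise
        })
        cz <- build_connectome(time_series(runs, ids[i], s))
        if (cfg$planted_mode == "edges" && s == cfg$states[1]) {
          z <- cz$z
          bump <- cfg$edge_signal_sd * edge_latent[i]
          z[signal_edges] <- z[signal_edges] + bump # upper-triangle indices
          z[lower.tri(z)] <- t(z)[lower.tri(z)]
          cz <- connectome(z, ids[i], s, cz$node_labels)
        }
        pos <- pos + 1L
        out[[pos]] <- cz
      }
    }
    attr(out, "subject_id") <- ids
    attr(out, "gains") <- gain_field
    attr(out, "blocks") <- blocks
    if (cfg$planted_mode == "edges") {
      attr(out, "edge_latent") <- edge_latent
      attr(out, "signal_edges") <- signal_edges
    }
    out
  })
}

#' Generate symptom scores with a planted, calibrated brain effect
#'
#' Builds the cohort table: three correlated symptom scales at baseline, 3
#' and 6 months, medication load and group. The planted target is composed
#' as `beta * standardized(brain score) + sum(gamma * covariates) + noise`,
#' with `beta` calibrated so the brain term explains `effect_size` of the
#' target variance; follow-up scores are autocorrelated with baseline, and
#' visit-level missingness is applied per time point.
#'
#' @param cfg A [synthetic_config()].
#' @param metrics Long metric tibble from [connectome_metrics()] (ignored in
#'   edge mode when `brain_score` is supplied).
#' @param seed Integer seed.
#' @param brain_score Optional explicit brain score vector (one per
#'   subject), used in edge mode.
#' @return A cohort tibble with attribute `planted` (feature, beta, brain
#'   score).
#' @export
generate_symptoms <- function(cfg, metrics, seed = 1, brain_score = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_subjects
  planted_on <- !identical(cfg$planted_feature, "none") || !is.null(brain_score)
  if (is.null(brain_score) && planted_on) {
    spec0 <- gpm_spec(cfg$target_symptom, cfg$target_time, states = cfg$states)
    feats <- assemble_features(metrics, spec0)
    if (!cfg$planted_feature %in% names(feats)) {
      stop("planted feature '", cfg$planted_feature,
           "' absent from metric vectors", call. = FALSE)
    }
    ids <- feats$subject_id
    brain_score <- feats[[cfg$planted_feature]]
  } else {
    ids <- unique(metrics$subject_id)
    if (is.null(brain_score)) brain_score <- rep(0, n)
  }
  stopifnot(length(brain_score) == n)
  z_m <- if (stats::sd(brain_score) > 0) as.vector(scale(brain_score)) else rep(0, n)
  with_seed(seed, {
    group <- sample(c(rep("bipolar", round(n * cfg$bipolar_fraction)),
                      rep("unipolar", n - round(n * cfg$bipolar_fraction))))
    med <- round(pmax(stats::rnorm(n, 1.5, 1), 0), 2)
    z_med <- as.vector(scale(med))
    # correlated baseline scale latents via a shared mood factor
    u <- stats::rnorm(n)
    lat <- sapply(symptom_scales, function(s) {
      sqrt(cfg$scale_cor) * u + sqrt(1 - cfg$scale_cor) * stats::rnorm(n)
    })
    gam_s <- cfg$covariate_effects[["baseline_symptom"]]
    gam_m <- cfg$covariate_effects[["medication"]]
    # generating model for the planted target
    if (cfg$target_time == "baseline") {
      covs <- lat[, setdiff(symptom_scales, cfg$target_symptom), drop = FALSE]
      q <- covs %*% rep(gam_s, ncol(covs)) + gam_m * z_med
    } else {
      q <- lat %*% rep(gam_s, 3) + cfg$follow_up_ar * lat[, cfg$target_symptom] +
        gam_m * z_med
    }
    q <- drop(q) + stats::rnorm(n, sd = cfg$noise_sd)
    beta <- if (planted_on && cfg$effect_size > 0) {
      sqrt(cfg$effect_size * stats::var(q) / (1 - cfg$effect_size))
    } else 0
    active <- group %in% cfg$effect_groups
    t_std <- beta * z_m * active + q
    t_std <- t_std / stats::sd(t_std)
    # assemble all scale x time latents
    cols <- list()
    for (s in symptom_scales) {
      base_lat <- if (s == cfg$target_symptom && cfg$target_time == "baseline")
        t_std else lat[, s]
      fu <- function(prev) cfg$follow_up_ar * prev +
        sqrt(1 - cfg$follow_up_ar^2) * stats::rnorm(n)
      m3_lat <- if (s == cfg$target_symptom && cfg$target_time == "m3")
        t_std else fu(base_lat)
      m6_lat <- if (s == cfg$target_symptom && cfg$target_time == "m6")
        t_std else fu(m3_lat)
      cols[[paste0(s, "_baseline")]] <- to_observed(base_lat, s)
      cols[[paste0(s, "_m3")]] <- to_observed(m3_lat, s)
      cols[[paste0(s, "_m6")]] <- to_observed(m6_lat, s)
    }
    # visit-level missingness per time point
    for (tp in time_points) {
      lost <- stats::runif(n) < cfg$missingness[[tp]]
      if (any(lost)) {
        for (s in symptom_scales) {
          cols[[paste0(s, "_", tp)]][lost] <- NA_real_
        }
      }
    }
    cohort <- tibble::tibble(
      subject_id = ids, group = group, medication_load = med, !!!cols
    )
    attr(cohort, "planted") <- list(
      feature = cfg$planted_feature, mode = cfg$planted_mode,
      target_column = target_column(cfg$target_symptom, cfg$target_time),
      beta = beta, brain_score = z_m, effect_size = cfg$effect_size
    )
    cohort
  })
}

#' Simulate a complete synthetic cohort
#'
#' Runs the full generative pipeline: connectomes, graph metrics on the
#' positive-weighted graphs, feature table, and symptom scores with the
#' planted effect. Everything is deterministic given `seed`.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer master seed (stage seeds are derived from it).
#' @param roi A [roi_map()]; default [synthetic_roi_map()].
#' @return An object of class `gpm_cohort`: list with `cohort`, `metrics`,
#'   `features`, `connectomes`, `roi`, `config`.
#' @export
simulate_cohort <- function(cfg = synthetic_config(), seed = 1,
                            roi = synthetic_roi_map(cfg$n_nodes)) {
  conn <- generate_connectomes(cfg, derive_seed(seed, "connectomes"))
  metrics <- connectome_metrics(conn, roi)
  brain_score <- if (cfg$planted_mode == "edges") attr(conn, "edge_latent") else NULL
  cohort <- generate_symptoms(cfg, metrics, derive_seed(seed, "symptoms"),
                              brain_score = brain_score)
  spec <- gpm_spec(cfg$target_symptom, cfg$target_time, states = cfg$states)
  features <- assemble_features(metrics, spec)
  structure(
    list(cohort = cohort, metrics = metrics, features = features,
         connectomes = conn, roi = roi, config = cfg, seed = seed),
    class = "gpm_cohort"
  )
}

#' @export
print.gpm_cohort <- function(x, ...) {
  cat("<gpm_cohort>", x$config$n_subjects, "subjects,",
      x$config$n_nodes, "nodes,", length(x$config$states), "states\n")
  cat("  planted:", x$config$planted_feature, "->",
      target_column(x$config$target_symptom, x$config$target_time),
      sprintf("(R^2 = %.2f, mode = %s)\n",
              x$config$effect_size, x$config$planted_mode))
  invisible(x)
}

#' End-to-end parameter-recovery experiment
#'
#' Repeatedly simulates cohorts, runs the cross-validated GPM and its null
#' model on each, and summarizes how often the planted feature is recovered
#' (the modal in-fold selection), the distribution of prediction r and of
#' the relative MSE difference.
#'
#' @param cfg A [synthetic_config()].
#' @param n_replicates Number of simulated cohorts.
#' @param seed Integer master seed; replicate seeds are derived from it.
#' @param scheme CV scheme for each replicate (default LOOCV).
#' @return An object of class `gpm_recovery`: tibble `replicates` plus
#'   aggregate fields `selection_rate`, `mean_r`, `mean_mse_diff`,
#'   `frac_beats_null`.
#' @export
recovery_experiment <- function(cfg = synthetic_config(), n_replicates = 20,
                                seed = 1, scheme = cv_loocv()) {
  spec <- gpm_spec(cfg$target_symptom, cfg$target_time, states = cfg$states)
  base <- derive_seed(seed, "replicate")
  rows <- purrr::map_dfr(seq_len(n_replicates), function(i) {
    sc <- simulate_cohort(cfg, seed = base + i)
    gpm <- cross_validate_gpm(sc$features, sc$cohort, spec, scheme)
    nul <- null_model_cv(sc$cohort, spec, scheme, features = sc$features)
    tab <- table(gpm$fold_summary$selected_feature)
    modal <- names(tab)[which.max(tab)]
    tibble::tibble(
      replicate = i, seed = base + i,
      modal_feature = modal,
      planted_selected = identical(modal, cfg$planted_feature),
      selection_fraction = max(tab) / sum(tab),
      r = gpm$pearson_r, mse_gpm = gpm$mse, mse_null = nul$mse,
      mse_diff = mse_relative_difference(nul$mse, gpm$mse),
      n_used = gpm$n_used
    )
  })
  structure(
    list(replicates = rows,
         selection_rate = mean(rows$planted_selected),
         mean_r = mean(rows$r),
         mean_mse_diff = mean(rows$mse_diff),
         frac_beats_null = mean(rows$mse_gpm < rows$mse_null),
         config = cfg, scheme = scheme, seed = seed),
    class = "gpm_recovery"
  )
}

#' @export
print.gpm_recovery <- function(x, ...) {
  cat("<gpm_recovery>", nrow(x$replicates), "replicates of n =",
      x$config$n_subjects, "\n")
  cat(sprintf("  planted feature selected: %.0f%% | mean r = %.3f | mean MSE_diff = %.1f%% | beats null: %.0f%%\n",
              100 * x$selection_rate, x$mean_r, 100 * x$mean_mse_diff,
              100 * x$frac_beats_null))
  invisible(x)
}
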