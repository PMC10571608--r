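# Small synthetic configurations shared across test files. Sizes are kept
# modest so each test file runs in seconds; the statistical conditions
# (n = 80 subjects, planted R^2) follow the package defaults where a test
# needs them.

tiny_cfg <- function(...) {
  args <- list(n_subjects = 30, n_nodes = 10, n_blocks = 2,
               run_lengths = list(task = c(40, 40, 40), rest = 120),
               missingness = c(baseline = 0, m3 = 0, m6 = 0))
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

# A deterministic feature table + cohort with an exactly planted linear
# target, for tests that need full control (no connectome simulation).
planted_table <- function(n = 80, p_noise = 40, beta = 1, noise_sd = 0.5,
                          seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    X <- matrix(rnorm(n * (p_noise + 1)), n)
    colnames(X) <- c("task:planted_metric",
                     sprintf("task:noise_%02d", seq_len(p_noise)))
    med <- abs(rnorm(n))
    target <- beta * X[, 1] + rnorm(n, sd = noise_sd)
    features <- tibble::tibble(subject_id = sprintf("s%03d", 1:n),
                               tibble::as_tibble(X))
    cohort <- tibble::tibble(
      subject_id = features$subject_id,
      group = rep(c("unipolar", "bipolar"), length.out = n),
      medication_load = med,
      anhedonia_baseline = target,
      impulsivity_baseline = rnorm(n),
      mania_baseline = abs(rnorm(n))
    )
    list(features = features, cohort = cohort, target = target)
  })
}

baseline_spec <- function(...) gpm_spec("anhedonia", "baseline", ...)
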