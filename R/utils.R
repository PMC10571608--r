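#' @importFrom rlang .data
#' @importFrom stats setNames
NULL

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a stage seed from a master seed; keeps results < 2^31.
derive_seed <- function(master, stage) {
  offsets <- c(connectomes = 11L, symptoms = 23L, folds = 37L,
               permutation = 53L, replicate = 71L, elastic = 89L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else 101L
  as.integer((as.double(master) * 48271 + off) %% 2147483647)
}

# OLS via QR with an informative error on rank deficiency.
ols_fit <- function(D, y) {
  qrd <- qr(D)
  if (qrd$rank < ncol(D)) {
    bad <- colnames(D)[qrd$pivot[(qrd$rank + 1):ncol(D)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  qr.coef(qrd, y)
}

symptom_scales <- c("anhedonia", "impulsivity", "mania")
time_points <- c("baseline", "m3", "m6")

target_column <- function(symptom, time) paste(symptom, time, sep = "_")
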