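#' Connectome-based predictive modeling (CPM) comparator
#'
#' The CPM predicts symptoms from summed edge weights rather than graph
#' metrics: within each training fold, every edge is correlated with the
#' target, edges crossing a p-value threshold form a positive- or
#' negative-feature set, and each subject's network strength (sum of z over
#' selected edges) enters the same covariate-adjusted regression and
#' cross-validation machinery as the GPM.
#'
#' @name cpm
NULL

# Subjects x edges matrix of upper-triangle z values for one state.
edge_matrix <- function(connectomes, state, weight_mode = c("signed", "positive_only")) {
  weight_mode <- match.arg(weight_mode)
  sel <- Filter(function(cz) identical(cz$state, state), connectomes)
  if (length(sel) == 0) stop("no connectomes for state '", state, "'", call. = FALSE)
  n <- nrow(sel[[1]]$z)
  ut <- which(upper.tri(sel[[1]]$z))
  E <- t(vapply(sel, function(cz) cz$z[ut], numeric(length(ut))))
  if (weight_mode == "positive_only") E[E < 0] <- 0
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  colnames(E) <- paste0("e", pairs[, 1], "_", pairs[, 2])
  list(E = E, pairs = pairs, n_nodes = n,
       subject_id = vapply(sel, function(cz) as.character(cz$subject_id), ""),
       state = state)
}

# Two-sided p-value of a Pearson correlation via the t transform.
cor_pvalue <- function(r, m) {
  t <- r * sqrt((m - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(t), m - 2)
}

#' Select symptom-associated edges
#'
#' Correlates every edge with the (transformed) target over the training
#' subjects and returns the positive- and negative-feature sets: edges whose
#' correlation p-value falls below `p_threshold`, split by correlation sign.
#' Zero-variance edges are skipped.
#'
#' @param connectomes List of [connectome()] objects (one state).
#' @param target Numeric target aligned with the connectome list order.
#' @param training_index Optional training row indices (default all).
#' @param p_threshold Selection threshold on the correlation p-value.
#' @param state State label to select connectomes by (default: state of the
#'   first connectome).
#' @return A list with elements `positive` and `negative`, each an
#'   `edge_mask`: fields `polarity`, `edges` (two-column index matrix),
#'   `p_threshold`.
#' @export
select_edges <- function(connectomes, target, training_index = NULL,
                         p_threshold = 0.01, state = NULL) {
  state <- state %||% connectomes[[1]]$state
  em <- edge_matrix(connectomes, state)
  if (is.null(training_index)) training_index <- seq_len(nrow(em$E))
  sel <- select_edges_idx(em$E[training_index, , drop = FALSE],
                          target[training_index], p_threshold)
  mask <- function(polarity, idx) {
    structure(list(polarity = polarity,
                   edges = em$pairs[idx, , drop = FALSE],
                   p_threshold = p_threshold, n_nodes = em$n_nodes),
              class = "edge_mask")
  }
  list(positive = mask("positive", sel$positive),
       negative = mask("negative", sel$negative))
}

# Column indices of selected positive/negative edges.
select_edges_idx <- function(E, y, p_threshold) {
  if (length(y) < 3) stop("edge selection requires >= 3 training subjects", call. = FALSE)
  r <- suppressWarnings(as.vector(stats::cor(E, y)))
  ok <- is.finite(r)
  p <- rep(1, length(r))
  p[ok] <- cor_pvalue(r[ok], length(y))
  hit <- ok & p < p_threshold
  list(positive = which(hit & r > 0), negative = which(hit & r < 0))
}

#' @export
print.edge_mask <- function(x, ...) {
  cat("<edge_mask>", x$polarity, "-", nrow(x$edges), "edges at p <",
      x$p_threshold, "\n")
  invisible(x)
}

#' Network strength: summed z over a selected edge set
#'
#' @param connectome A [connectome()] object.
#' @param mask An `edge_mask` from [select_edges()].
#' @return Scalar sum of Fisher-z values over the mask's edges (each
#'   unordered pair counted once); 0 with a warning for an empty mask.
#' @export
network_strength <- function(connectome, mask) {
  stopifnot(inherits(mask, "edge_mask"))
  if (nrow(mask$edges) == 0) {
    warning("empty edge mask: network strength is 0", call. = FALSE)
    return(0)
  }
  sum(connectome$z[mask$edges])
}

# CPM cross-validation engine on an edge matrix. Mirrors cv_engine(); folds
# with no selected edges fall back to the covariates-only model (recorded in
# the selected-feature slot).
cv_engine_cpm <- function(E, y, C, folds, polarity = "positive",
                          p_threshold = 0.01, min_train = 10L) {
  n <- length(y)
  nfold <- sum(lengths(folds))
  idx_all <- integer(0); rep_all <- integer(0); fold_all <- integer(0)
  pred_all <- numeric(0)
  f_mse <- numeric(nfold); f_sel <- character(nfold); f_r <- numeric(nfold)
  f_ntr <- integer(nfold); f_nte <- integer(nfold)
  f_rep <- integer(nfold); f_id <- integer(nfold)
  pos <- 0L
  for (r in seq_along(folds)) {
    for (f in seq_along(folds[[r]])) {
      pos <- pos + 1L
      te <- folds[[r]][[f]]
      tr <- setdiff(seq_len(n), te)
      if (length(tr) < min_train) {
        stop("fold with only ", length(tr), " training cases (minimum ",
             min_train, ")", call. = FALSE)
      }
      sel <- select_edges_idx(E[tr, , drop = FALSE], y[tr], p_threshold)
      idxs <- if (polarity == "both") list(sel$positive, sel$negative)
              else list(sel[[polarity]])
      strengths <- lapply(idxs, function(ix) {
        if (length(ix) == 0) NULL else rowSums(E[, ix, drop = FALSE])
      })
      strengths <- Filter(Negate(is.null), strengths)
      if (length(strengths) == 0) {
        # no edge survives selection in this fold: covariates-only fallback
        D <- cbind(1, C[tr, , drop = FALSE])
        Dte <- cbind(1, C[te, , drop = FALSE])
        colnames(D) <- c("(Intercept)", colnames(C))
        f_sel[pos] <- "fallback:covariates_only"
      } else {
        S <- do.call(cbind, strengths)
        D <- cbind(1, S[tr, , drop = FALSE], C[tr, , drop = FALSE])
        Dte <- cbind(1, S[te, , drop = FALSE], C[te, , drop = FALSE])
        colnames(D) <- c("(Intercept)",
                         paste0("strength", seq_len(ncol(S))), colnames(C))
        f_sel[pos] <- paste0(polarity, ":", sum(lengths(idxs)), "_edges")
      }
      beta <- ols_fit(D, y[tr])
      pred <- drop(Dte %*% beta)
      idx_all <- c(idx_all, te)
      rep_all <- c(rep_all, rep.int(r, length(te)))
      fold_all <- c(fold_all, rep.int(f, length(te)))
      pred_all <- c(pred_all, pred)
      f_mse[pos] <- mean((y[te] - pred)^2)
      f_r[pos] <- NA_real_
      f_ntr[pos] <- length(tr); f_nte[pos] <- length(te)
      f_rep[pos] <- r; f_id[pos] <- f
    }
  }
  list(idx = idx_all, rep = rep_all, fold = fold_all, pred = pred_all,
       fold_mse = f_mse, fold_selected = f_sel, fold_sel_r = f_r,
       fold_rep = f_rep, fold_id = f_id, n_train = f_ntr, n_test = f_nte)
}

#' Cross-validated CPM prediction
#'
#' Per fold: edges are selected on the training subjects at `p_threshold`,
#' summed into a network-strength predictor, and the same covariate
#' structure, target transform and cross-validation machinery as
#' [cross_validate_gpm()] produce held-out predictions. A fold in which no
#' edge survives selection falls back to the covariates-only model.
#'
#' @inheritParams cross_validate_gpm
#' @param connectomes List of [connectome()] objects.
#' @param polarity `"positive"`, `"negative"` (evaluated as separate
#'   models), or `"both"` (a combined two-predictor mode, off by default).
#' @param weight_mode `"signed"` keeps the full connectome including
#'   negative weights (the original CPM); `"positive_only"` zeroes negative
#'   z first (matching the graph the GPM uses).
#' @param p_threshold Edge-selection threshold.
#' @param state Which state's connectomes to use (default: first candidate
#'   state of `spec`).
#' @return A `gpm_cv` object with `model = "cpm"`.
#' @export
cross_validate_cpm <- function(connectomes, cohort, spec = gpm_spec(),
                               polarity = c("positive", "negative", "both"),
                               weight_mode = c("signed", "positive_only"),
                               p_threshold = 0.01, scheme = cv_loocv(),
                               state = NULL) {
  polarity <- match.arg(polarity)
  weight_mode <- match.arg(weight_mode)
  state <- state %||% spec$states[1]
  em <- edge_matrix(connectomes, state, weight_mode)
  cohort <- cohort[cohort$subject_id %in% em$subject_id, , drop = FALSE]
  mf <- prepare_model_frame(cohort, spec, features = NULL)
  if (mf$n < 10) stop("need at least 10 complete cases, got ", mf$n, call. = FALSE)
  E <- em$E[match(mf$subject_id, em$subject_id), , drop = FALSE]
  folds <- make_folds(mf$n, scheme)
  eng <- cv_engine_cpm(E, mf$y, mf$C, folds, polarity = polarity,
                       p_threshold = p_threshold, min_train = spec$min_train)
  out <- as_gpm_cv(eng, mf$y, mf$subject_id, "cpm", spec, scheme)
  out$polarity <- polarity
  out$weight_mode <- weight_mode
  out$p_threshold <- p_threshold
  out
}
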