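#' Bundle node-by-time BOLD runs for one subject and state
#'
#' A time-series object holds one or more runs of regional BOLD signal for a
#' single subject in a single cognitive state (e.g. `"task"`, `"rest"`). All
#' runs must share the same nodes in the same order; runs are concatenated
#' along time before correlation by [build_connectome()].
#'
#' @param runs A numeric matrix (nodes x time) or a list of such matrices.
#' @param subject_id Subject identifier.
#' @param state State label, e.g. `"task"` or `"rest"`.
#' @param node_labels Optional character vector of node names; defaults to
#'   rownames of the first run or `"n1" ... "nK"`.
#' @return An object of class `time_series`.
#' @examples
#' ts <- time_series(matrix(rnorm(40), nrow = 4), "s01", "rest")
#' @export
time_series <- function(runs, subject_id, state, node_labels = NULL) {
  if (is.matrix(runs)) runs <- list(runs)
  stopifnot(is.list(runs), length(runs) >= 1)
  runs <- lapply(runs, function(r) {
    r <- as.matrix(r)
    storage.mode(r) <- "double"
    r
  })
  n <- nrow(runs[[1]])
  if (any(vapply(runs, nrow, 0L) != n)) {
    stop("all runs must have the same number of nodes", call. = FALSE)
  }
  for (i in seq_along(runs)) {
    if (ncol(runs[[i]]) < 3) {
      stop("run ", i, " has fewer than 3 time points", call. = FALSE)
    }
    sds <- apply(runs[[i]], 1, stats::sd)
    if (any(sds == 0)) {
      bad <- which(sds == 0)[1]
      lbl <- if (!is.null(node_labels)) node_labels[bad] else
        if (!is.null(rownames(runs[[i]]))) rownames(runs[[i]])[bad] else bad
      stop("node ", lbl, " is constant in run ", i,
           "; correlation undefined", call. = FALSE)
    }
  }
  if (is.null(node_labels)) {
    node_labels <- rownames(runs[[1]])
    if (is.null(node_labels)) node_labels <- paste0("n", seq_len(n))
  }
  stopifnot(length(node_labels) == n)
  structure(
    list(subject_id = subject_id, state = state, runs = runs,
         node_labels = node_labels),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat("<time_series> subject", x$subject_id, "state", x$state, "-",
      length(x$runs), "run(s),", nrow(x$runs[[1]]), "nodes,",
      sum(vapply(x$runs, ncol, 0L)), "time points total\n")
  invisible(x)
}

#' Construct a connectome object directly from a Fisher-z matrix
#'
#' @param z Symmetric numeric matrix of Fisher-transformed correlations with
#'   zero diagonal.
#' @param subject_id,state Identifiers carried along with the matrix.
#' @param node_labels Optional node names (defaults to rownames or n1..nK).
#' @return An object of class `connectome`.
#' @export
connectome <- function(z, subject_id = NA_character_, state = NA_character_,
                       node_labels = NULL) {
  z <- as.matrix(z)
  storage.mode(z) <- "double"
  n <- nrow(z)
  stopifnot(ncol(z) == n)
  if (any(!is.finite(z))) stop("connectome entries must be finite", call. = FALSE)
  if (max(abs(z - t(z))) > 1e-10) {
    stop("connectome matrix is not symmetric (tolerance 1e-10)", call. = FALSE)
  }
  z <- (z + t(z)) / 2
  diag(z) <- 0
  if (is.null(node_labels)) {
    node_labels <- rownames(z)
    if (is.null(node_labels)) node_labels <- paste0("n", seq_len(n))
  }
  dimnames(z) <- list(node_labels, node_labels)
  structure(
    list(subject_id = subject_id, state = state, z = z,
         node_labels = node_labels),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> subject", x$subject_id, "state", x$state, "-",
      nrow(x$z), "nodes; mean |z| =",
      signif(mean(abs(x$z[upper.tri(x$z)])), 3), "\n")
  invisible(x)
}

#' Build a Fisher-z functional connectome from node time series
#'
#' Runs are demeaned per run and per node, concatenated along time, and the
#' Pearson correlation between every pair of node series is Fisher
#' z-transformed (`atanh`). Correlations are clipped to `r_clip` in magnitude
#' so that perfectly (anti-)correlated pairs stay finite after the transform.
#'
#' @param ts A [time_series()] object.
#' @param r_clip Magnitude bound applied to correlations before `atanh`.
#' @return A [connectome()] object: symmetric Fisher-z matrix with zero
#'   diagonal.
#' @examples
#' x <- matrix(rnorm(5 * 60), nrow = 5)
#' cz <- build_connectome(time_series(x, "s01", "rest"))
#' @export
build_connectome <- function(ts, r_clip = 0.999) {
  stopifnot(inherits(ts, "time_series"), r_clip > 0, r_clip < 1)
  demeaned <- lapply(ts$runs, function(r) r - rowMeans(r))
  x <- do.call(cbind, demeaned)
  r <- stats::cor(t(x))
  r <- pmin(pmax(r, -r_clip), r_clip)
  z <- atanh(r)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  connectome(z, subject_id = ts$subject_id, state = ts$state,
             node_labels = ts$node_labels)
}

#' Reduce a connectome to its positive-weighted graph
#'
#' Negative functional connections are discarded (set to zero weight): most
#' weighted graph measures are defined only for nonnegative weights. Edge
#' lengths for shortest-path computations are the reciprocal weights
#' `1/w` (stronger connection = shorter length); absent edges have infinite
#' length.
#'
#' @param c A [connectome()] object, or a bare symmetric z matrix.
#' @return An object of class `weighted_graph` with fields `w` (weights),
#'   `lengths`, `n`, `node_labels`.
#' @examples
#' g <- to_positive_graph(connectome(matrix(c(0, .5, .5, 0), 2), "s", "rest"))
#' @export
to_positive_graph <- function(c) {
  if (!inherits(c, "connectome")) c <- connectome(c)
  w <- pmax(c$z, 0)
  weighted_graph(w, node_labels = c$node_labels)
}

#' Construct a weighted graph from a nonnegative weight matrix
#'
#' @param w Symmetric nonnegative weight matrix; zero means no edge.
#' @param node_labels Optional node names.
#' @return An object of class `weighted_graph`.
#' @export
weighted_graph <- function(w, node_labels = NULL) {
  w <- as.matrix(w)
  storage.mode(w) <- "double"
  n <- nrow(w)
  stopifnot(ncol(w) == n)
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (max(abs(w - t(w))) > 1e-10) stop("weight matrix must be symmetric", call. = FALSE)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  lengths <- ifelse(w > 0, 1 / w, Inf)
  diag(lengths) <- 0
  if (is.null(node_labels)) {
    node_labels <- rownames(w)
    if (is.null(node_labels)) node_labels <- paste0("n", seq_len(n))
  }
  dimnames(w) <- dimnames(lengths) <- list(node_labels, node_labels)
  structure(
    list(w = w, lengths = lengths, n = n, node_labels = node_labels,
         cache = new.env(parent = emptyenv())),
    class = "weighted_graph"
  )
}

#' @export
print.weighted_graph <- function(x, ...) {
  ne <- sum(x$w[upper.tri(x$w)] > 0)
  cat("<weighted_graph>", x$n, "nodes,", ne, "positive edges\n")
  invisible(x)
}
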