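#' Graph measures of integration, segregation and centrality
#'
#' These functions compute the weighted graph measures used as brain
#' predictors: characteristic path length and global efficiency
#' (integration), clustering coefficient and local efficiency (segregation),
#' and betweenness centrality (centrality). All operate on the positive
#' weighted graph produced by [to_positive_graph()], with shortest paths
#' taken over reciprocal-weight edge lengths.
#'
#' @name graph-metrics
NULL

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Shortest-path distance matrix
#'
#' Dijkstra's algorithm from every source over edge lengths `1/w`.
#' Disconnected pairs have infinite distance. The result is cached on the
#' graph object.
#'
#' @param g A [weighted_graph()].
#' @return An `n x n` symmetric matrix of distances with zero diagonal.
#' @export
distance_matrix <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  if (!is.null(g$cache$d)) return(g$cache$d)
  ig <- as_igraph(g)
  wts <- igraph::E(ig)$weight
  d <- igraph::distances(ig, weights = 1 / wts, algorithm = "dijkstra")
  d <- (d + t(d)) / 2
  dimnames(d) <- dimnames(g$w)
  g$cache$d <- d
  d
}

#' Global efficiency: mean inverse shortest-path length
#'
#' The average of `1/d_ij` over all ordered node pairs `i != j`, with
#' disconnected pairs contributing zero. A measure of network integration.
#'
#' @param g A [weighted_graph()].
#' @return Scalar in `[0, Inf)`.
#' @export
global_efficiency <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  if (g$n < 2) stop("global efficiency requires at least 2 nodes", call. = FALSE)
  d <- distance_matrix(g)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0 # 1/Inf and the 1/0 diagonal both drop out
  diag(inv) <- 0
  sum(inv) / (g$n * (g$n - 1))
}

#' Characteristic path length: mean shortest-path distance
#'
#' The mean of finite distances over node pairs `i != j`. When some pairs are
#' disconnected only the finite pairs are averaged and the `"connected"`
#' attribute of the result is `FALSE`.
#'
#' @param g A [weighted_graph()].
#' @return Scalar with a logical attribute `connected`.
#' @export
characteristic_path_length <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  if (g$n < 2) stop("characteristic path length requires at least 2 nodes", call. = FALSE)
  d <- distance_matrix(g)
  off <- d[upper.tri(d)]
  fin <- off[is.finite(off)]
  if (length(fin) == 0) stop("graph has no finite node pair distances", call. = FALSE)
  structure(mean(fin), connected = length(fin) == length(off))
}

#' Weighted clustering coefficient (Onnela form)
#'
#' Weights are normalized by the graph maximum; node `i`'s coefficient is the
#' sum of geometric means of its triangle weights divided by `k_i (k_i - 1)`
#' where `k_i` is the node degree. Nodes with fewer than two neighbors score
#' zero. With max-normalized weights, values lie in `[0, 1]`.
#'
#' @param g A [weighted_graph()].
#' @return Named numeric vector (one value per node).
#' @export
nodal_clustering <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  wmax <- max(g$w)
  k <- colSums(g$w > 0)
  out <- stats::setNames(numeric(g$n), g$node_labels)
  if (wmax == 0) return(out)
  wh <- (g$w / wmax)^(1 / 3)
  cyc <- diag(wh %*% wh %*% wh)
  ok <- k >= 2
  out[ok] <- cyc[ok] / (k[ok] * (k[ok] - 1))
  out
}

#' @rdname nodal_clustering
#' @export
mean_clustering <- function(g) mean(nodal_clustering(g))

#' Local efficiency: efficiency of the neighbor-induced subgraph
#'
#' For each node, the global efficiency of the subgraph induced on its
#' neighbors (original weights restricted to those nodes). Nodes with fewer
#' than two neighbors score zero.
#'
#' @param g A [weighted_graph()].
#' @return Named numeric vector (one value per node).
#' @export
nodal_local_efficiency <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  out <- stats::setNames(numeric(g$n), g$node_labels)
  for (i in seq_len(g$n)) {
    nb <- which(g$w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    d <- fw_dist(g$lengths[nb, nb, drop = FALSE])
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    out[i] <- sum(inv) / (k * (k - 1))
  }
  out
}

# Vectorized all-pairs shortest paths on an edge-length matrix; used for the
# many small neighbor subgraphs of local efficiency, where per-subgraph
# graph-object construction would dominate the cost.
fw_dist <- function(l) {
  n <- nrow(l)
  d <- l
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    upd <- which(dk < d)
    if (length(upd)) d[upd] <- dk[upd]
  }
  d
}

#' @rdname nodal_local_efficiency
#' @export
mean_local_efficiency <- function(g) mean(nodal_local_efficiency(g))

#' Weighted betweenness centrality
#'
#' Fraction of all-pairs shortest paths that pass through each node, with
#' shortest paths over reciprocal-weight lengths and tied geodesics sharing
#' credit equally (Brandes accumulation). Normalized by `(n-1)(n-2)` so
#' values lie in `[0, 1]`. Graphs with fewer than 3 nodes score zero
#' everywhere.
#'
#' @param g A [weighted_graph()].
#' @return Named numeric vector (one value per node).
#' @export
nodal_betweenness <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  out <- stats::setNames(numeric(g$n), g$node_labels)
  if (g$n < 3) return(out)
  ig <- as_igraph(g)
  wts <- igraph::E(ig)$weight
  raw <- igraph::betweenness(ig, weights = 1 / wts, directed = FALSE)
  out[] <- raw / ((g$n - 1) * (g$n - 2))
  out
}

#' @rdname nodal_betweenness
#' @export
mean_betweenness <- function(g) mean(nodal_betweenness(g))

#' Map named regions of interest to node indices
#'
#' An ROI map assigns region names (e.g. bilateral reward-circuit regions:
#' ACC, caudate, putamen, NAc, lateral/medial OFC) to 1-based node indices.
#' Note that indices are 1-based, following R convention; multi-node regions
#' are averaged by [metric_vector()].
#'
#' @param ... Named arguments, each a vector of 1-based node indices, or a
#'   single named list.
#' @param n Optional node count for bounds checking.
#' @return An object of class `roi_map` (named list of integer vectors).
#' @examples
#' roi_map(L_ACC = 201, R_ACC = 202, L_caudate = 203)
#' @export
roi_map <- function(..., n = NULL) {
  entries <- list(...)
  if (length(entries) == 1 && is.list(entries[[1]]) && is.null(names(entries)[1])) {
    entries <- entries[[1]]
  }
  if (length(entries) > 0) {
    if (is.null(names(entries)) || any(names(entries) == "")) {
      stop("all ROI entries must be named", call. = FALSE)
    }
    if (anyDuplicated(names(entries))) stop("ROI names must be unique", call. = FALSE)
  }
  entries <- lapply(entries, function(ix) {
    ix <- as.integer(ix)
    if (length(ix) == 0) stop("ROI node lists must be non-empty", call. = FALSE)
    if (any(ix < 1)) stop("ROI node indices are 1-based and must be >= 1", call. = FALSE)
    if (!is.null(n) && any(ix > n)) stop("ROI node index out of range", call. = FALSE)
    ix
  })
  structure(entries, class = "roi_map")
}

#' Compute the metric vector for one graph
#'
#' Five global measures (characteristic path length, global efficiency, mean
#' clustering, mean local efficiency, mean betweenness) plus clustering,
#' local efficiency and betweenness for every ROI (multi-node ROIs are
#' averaged across their nodes). A disconnected (or empty) graph yields `NA`
#' for characteristic path length and sets `connected = FALSE`.
#'
#' @param g A [weighted_graph()].
#' @param roi A [roi_map()]; may be empty for a global-only vector.
#' @param subject_id,state Identifiers attached to the output rows.
#' @return A tibble with columns `subject_id`, `state`, `metric`, `value`
#'   and a logical `connected` attribute.
#' @export
metric_vector <- function(g, roi = roi_map(), subject_id = NA_character_,
                          state = NA_character_) {
  stopifnot(inherits(g, "weighted_graph"))
  cpl <- tryCatch(characteristic_path_length(g), error = function(e) {
    structure(NA_real_, connected = FALSE)
  })
  cc <- nodal_clustering(g)
  le <- nodal_local_efficiency(g)
  bc <- nodal_betweenness(g)
  vals <- c(
    characteristic_path_length = as.numeric(cpl),
    global_efficiency = global_efficiency(g),
    mean_clustering = mean(cc),
    mean_local_efficiency = mean(le),
    mean_betweenness = mean(bc)
  )
  for (nm in names(roi)) {
    ix <- roi[[nm]]
    vals[paste0(nm, "_clustering")] <- mean(cc[ix])
    vals[paste0(nm, "_local_efficiency")] <- mean(le[ix])
    vals[paste0(nm, "_betweenness")] <- mean(bc[ix])
  }
  out <- tibble::tibble(
    subject_id = subject_id, state = state,
    metric = names(vals), value = unname(vals)
  )
  attr(out, "connected") <- isTRUE(attr(cpl, "connected"))
  out
}

#' Compute metric vectors for a set of connectomes
#'
#' Convenience wrapper: applies [to_positive_graph()] and [metric_vector()]
#' to every connectome in a list and binds the long-format rows.
#'
#' @param connectomes A list of [connectome()] objects.
#' @param roi A [roi_map()].
#' @return A long tibble (`subject_id`, `state`, `metric`, `value`).
#' @export
connectome_metrics <- function(connectomes, roi = roi_map()) {
  purrr::map_dfr(connectomes, function(cz) {
    metric_vector(to_positive_graph(cz), roi = roi,
                  subject_id = cz$subject_id, state = cz$state)
  })
}
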