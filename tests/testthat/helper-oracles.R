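# Independent brute-force oracles for the graph measures. Deliberately
# naive (Floyd-Warshall distances, combinatorial geodesic counting, direct
# triangle products) and written against bare weight matrices so they share
# no code path with the package implementation.

oracle_lengths <- function(w) {
  l <- ifelse(w > 0, 1 / w, Inf)
  diag(l) <- 0
  l
}

oracle_floyd_warshall <- function(w) {
  d <- oracle_lengths(w)
  n <- nrow(w)
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_global_efficiency <- function(w) {
  d <- oracle_floyd_warshall(w)
  n <- nrow(w)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
  }
  tot / (n * (n - 1))
}

oracle_cpl <- function(w) {
  d <- oracle_floyd_warshall(w)
  vals <- d[upper.tri(d)]
  mean(vals[is.finite(vals)])
}

oracle_clustering <- function(w) {
  n <- nrow(w)
  wh <- if (max(w) > 0) w / max(w) else w
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (j in nb) for (h in nb) {
      if (j != h) s <- s + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
    }
    out[i] <- s / (k * (k - 1))
  }
  out
}

oracle_local_efficiency <- function(w) {
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) next
    out[i] <- oracle_global_efficiency(w[nb, nb, drop = FALSE])
  }
  out
}

# Number of shortest s->t paths, counted by dynamic programming over the
# shortest-path DAG implied by Floyd-Warshall distances.
oracle_sigma <- function(w, d, s) {
  l <- oracle_lengths(w)
  n <- nrow(w)
  ord <- order(d[s, ])
  sigma <- numeric(n)
  sigma[s] <- 1
  for (t in ord) {
    if (t == s || !is.finite(d[s, t])) next
    preds <- which(w[, t] > 0 & abs(d[s, ] + l[, t] - d[s, t]) < 1e-12)
    sigma[t] <- sum(sigma[preds])
  }
  sigma
}

oracle_betweenness <- function(w) {
  n <- nrow(w)
  if (n < 3) return(numeric(n))
  d <- oracle_floyd_warshall(w)
  sig <- t(sapply(seq_len(n), function(s) oracle_sigma(w, d, s)))
  raw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (abs(d[s, v] + d[v, t] - d[s, t]) < 1e-12) {
        raw[v] <- raw[v] + sig[s, v] * sig[t, v] / sig[s, t]
      }
    }
  }
  raw / ((n - 1) * (n - 2))
}

random_weight_matrix <- function(n, p = 0.5, wmax = 1) {
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  edges <- runif(sum(up)) < p
  vals <- ifelse(edges, runif(sum(up), 0.05, wmax), 0)
  w[up] <- vals
  w <- w + t(w)
  w
}
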