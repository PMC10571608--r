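path_graph <- function(n, w = 1) {
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) m[i, i + 1] <- m[i + 1, i] <- w
  weighted_graph(m)
}

complete_graph <- function(n, w = 1) {
  m <- matrix(w, n, n); diag(m) <- 0
  weighted_graph(m)
}

cycle_graph <- function(n, w = 1) {
  m <- matrix(0, n, n)
  for (i in seq_len(n)) { j <- i %% n + 1; m[i, j] <- m[j, i] <- w }
  weighted_graph(m)
}

test_that("shortest-path distances follow reciprocal-weight lengths", {
  g <- path_graph(4)
  d <- distance_matrix(g)
  expect_equal(d[1, 4], 3)
  expect_equal(unname(d), unname(oracle_floyd_warshall(g$w)))

  gc <- complete_graph(5)
  dc <- distance_matrix(gc)
  expect_true(all(dc[upper.tri(dc)] == 1))

  # weights {1-2: .5, 2-3: .5, 1-3: .2} -> lengths {2, 2, 5}; best 1-3 route is via 2
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.5; m[2, 3] <- m[3, 2] <- 0.5; m[1, 3] <- m[3, 1] <- 0.2
  d3 <- distance_matrix(weighted_graph(m))
  expect_equal(d3[1, 3], 4)
})

test_that("closed-form limits: complete and empty graphs", {
  for (n in c(3, 5, 7)) {
    g <- complete_graph(n)
    expect_equal(global_efficiency(g), 1)
    expect_equal(as.numeric(characteristic_path_length(g)), 1)
    expect_equal(unname(nodal_clustering(g)), rep(1, n))
    expect_equal(unname(nodal_local_efficiency(g)), rep(1, n))
    expect_equal(unname(nodal_betweenness(g)), rep(0, n))
  }
  empty <- weighted_graph(matrix(0, 3, 3))
  expect_equal(global_efficiency(empty), 0)
  expect_error(characteristic_path_length(empty), "no finite")
  expect_error(global_efficiency(weighted_graph(matrix(0, 1, 1))), "2 nodes")
})

test_that("path-graph metrics match hand-derived values", {
  g <- path_graph(4)
  # ordered pairs: 2*(1+1+1+1/2+1/2+1/3) / 12
  expect_equal(global_efficiency(g), (2 * (3 + 0.5 + 0.5 + 1 / 3)) / 12)
  cpl <- characteristic_path_length(g)
  expect_equal(as.numeric(cpl), 10 / 6)
  expect_true(attr(cpl, "connected"))

  # two disjoint unit edges: finite pairs only, flagged disconnected
  m <- matrix(0, 4, 4); m[1, 2] <- m[2, 1] <- 1; m[3, 4] <- m[4, 3] <- 1
  cpl2 <- characteristic_path_length(weighted_graph(m))
  expect_equal(as.numeric(cpl2), 1)
  expect_false(attr(cpl2, "connected"))

  # 3-node path: middle node carries its endpoints' single geodesic
  g3 <- path_graph(3)
  expect_equal(unname(nodal_betweenness(g3)), c(0, 0.5, 0))
  expect_equal(unname(nodal_local_efficiency(g3)), c(0, 0, 0))
})

test_that("tied geodesics split betweenness credit (4-cycle)", {
  g <- cycle_graph(4)
  expect_equal(unname(nodal_betweenness(g)), rep(0.5 / 6, 4), tolerance = 1e-12)
  expect_equal(unname(nodal_local_efficiency(g)), rep(0, 4))
})

test_that("weighted clustering uses max-normalized triangle geometric means", {
  # triangle with weights (1, 1, 0.5): node opposite the 0.5 edge sees (1*1*0.5)^(1/3)
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 1; m[1, 3] <- m[3, 1] <- 1; m[2, 3] <- m[3, 2] <- 0.5
  cc <- nodal_clustering(weighted_graph(m))
  expect_equal(unname(cc[1]), 0.5^(1 / 3), tolerance = 1e-12)
  expect_equal(unname(cc[1]), 0.7937, tolerance = 1e-4)

  # star graph: no triangles anywhere
  s <- matrix(0, 4, 4); s[1, 2:4] <- s[2:4, 1] <- 1
  expect_equal(unname(nodal_clustering(weighted_graph(s))), rep(0, 4))
})

test_that("all seven metric operations match brute-force oracles on random graphs", {
  set.seed(202)
  worst <- 0
  for (i in 1:200) {
    n <- sample(4:8, 1)
    w <- random_weight_matrix(n, p = runif(1, 0.3, 0.9))
    g <- weighted_graph(w)
    d <- distance_matrix(g)
    worst <- max(
      worst,
      max(abs(unname(d) - oracle_floyd_warshall(w)), na.rm = TRUE),
      abs(global_efficiency(g) - oracle_global_efficiency(w)),
      if (any(is.finite(oracle_floyd_warshall(w)[upper.tri(w)])))
        abs(as.numeric(characteristic_path_length(g)) - oracle_cpl(w)) else 0,
      max(abs(unname(nodal_clustering(g)) - oracle_clustering(w))),
      max(abs(unname(nodal_local_efficiency(g)) - oracle_local_efficiency(w))),
      max(abs(unname(nodal_betweenness(g)) - oracle_betweenness(w))),
      abs(mean_clustering(g) - mean(oracle_clustering(w))),
      abs(mean_betweenness(g) - mean(oracle_betweenness(w)))
    )
  }
  expect_lt(worst, 1e-9)
})

test_that("metrics scale correctly under uniform weight scaling", {
  set.seed(9)
  w <- random_weight_matrix(7, p = 0.7)
  g1 <- weighted_graph(w)
  g2 <- weighted_graph(3.5 * w)
  expect_equal(global_efficiency(g2), 3.5 * global_efficiency(g1), tolerance = 1e-12)
  expect_equal(as.numeric(characteristic_path_length(g2)),
               as.numeric(characteristic_path_length(g1)) / 3.5, tolerance = 1e-12)
  expect_equal(nodal_clustering(g2), nodal_clustering(g1), tolerance = 1e-12)
  expect_equal(nodal_betweenness(g2), nodal_betweenness(g1), tolerance = 1e-12)
})

test_that("adding a positive edge never decreases global efficiency", {
  set.seed(13)
  for (i in 1:20) {
    w <- random_weight_matrix(6, p = 0.4)
    zero <- which(w == 0 & upper.tri(w), arr.ind = TRUE)
    if (nrow(zero) == 0) next
    pick <- zero[sample(nrow(zero), 1), ]
    w2 <- w
    w2[pick[1], pick[2]] <- w2[pick[2], pick[1]] <- runif(1, 0.1, 1)
    expect_gte(global_efficiency(weighted_graph(w2)) + 1e-12,
               global_efficiency(weighted_graph(w)))
  }
})

test_that("mean metrics equal unweighted nodal averages", {
  set.seed(17)
  w <- random_weight_matrix(8, p = 0.6)
  g <- weighted_graph(w)
  expect_equal(mean_clustering(g), mean(nodal_clustering(g)))
  expect_equal(mean_local_efficiency(g), mean(nodal_local_efficiency(g)))
  expect_equal(mean_betweenness(g), mean(nodal_betweenness(g)))
})

test_that("metric_vector assembles globals plus averaged ROI values", {
  g <- complete_graph(5)
  mv <- metric_vector(g, roi_map(hub = 1), subject_id = "s1", state = "task")
  vals <- setNames(mv$value, mv$metric)
  expect_equal(unname(vals[c("characteristic_path_length", "global_efficiency",
                             "mean_clustering", "mean_local_efficiency",
                             "mean_betweenness")]),
               c(1, 1, 1, 1, 0))
  expect_equal(unname(vals[c("hub_clustering", "hub_local_efficiency",
                             "hub_betweenness")]), c(1, 1, 0))
  expect_true(attr(mv, "connected"))

  # multi-node ROI averages its nodes
  w <- random_weight_matrix(6, p = 0.8)
  g2 <- weighted_graph(w)
  mv2 <- metric_vector(g2, roi_map(pair = c(1, 2)))
  cc <- nodal_clustering(g2)
  expect_equal(mv2$value[mv2$metric == "pair_clustering"], mean(cc[1:2]))

  # empty graph: efficiencies zero, path length missing, disconnected flag
  mv3 <- metric_vector(weighted_graph(matrix(0, 4, 4)))
  v3 <- setNames(mv3$value, mv3$metric)
  expect_true(is.na(v3["characteristic_path_length"]))
  expect_equal(unname(v3["global_efficiency"]), 0)
  expect_false(attr(mv3, "connected"))

  # empty ROI map: global-only vector
  expect_equal(nrow(metric_vector(g)), 5)
})

test_that("roi_map validates names and indices", {
  expect_error(roi_map(a = integer(0)), "non-empty")
  expect_error(roi_map(a = 1, a = 2), "unique")
  expect_error(roi_map(a = 0), "1-based")
  expect_error(roi_map(a = 9, n = 8), "out of range")
})
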