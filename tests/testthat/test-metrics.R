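# Nodal and global topology metrics against closed forms and brute force.

star5 <- function() {
  g <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(g)$name <- paste0("V", 1:5)
  g
}

test_that("degree centrality normalizes by the maximum degree", {
  dc <- degree_centrality(star5())
  expect_equal(unname(dc), c(1, 0.25, 0.25, 0.25, 0.25))
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- paste0("V", 1:6)
  expect_equal(unname(degree_centrality(ring)), rep(1, 6))
  expect_equal(unname(degree_centrality(star5(), normalization = "classic")),
               c(1, 0.25, 0.25, 0.25, 0.25))  # star: max degree equals N - 1
})

test_that("complete graphs score 1 on clustering, closeness and efficiency", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("V", 1:5)
  expect_equal(unname(clustering_coefficient(k5)), rep(1, 5))
  expect_equal(unname(closeness_centrality(k5)), rep(1, 5))
  gm <- global_metrics(k5)
  expect_equal(gm$global_efficiency, 1)
  expect_equal(gm$average_path_length, 1)
  expect_equal(gm$average_clustering, 1)
})

test_that("path-graph closeness matches hand-computed shortest paths", {
  p4 <- igraph::make_graph(~ A - B, B - C, C - D)
  cl <- closeness_centrality(p4)
  expect_equal(unname(cl[c("A", "B")]), c(3 / 6, 3 / 4))
})

test_that("trees have zero clustering everywhere", {
  tr <- igraph::make_tree(10, children = 2, mode = "undirected")
  igraph::V(tr)$name <- paste0("V", 1:10)
  expect_equal(unname(clustering_coefficient(tr)), rep(0, 10))
})

test_that("nodal and global metrics agree with brute force on random graphs", {
  for (seed in 1:5) {
    n <- sample(8:20, 1)
    adj <- rand_connected_adj(n, 0.3, seed)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(unname(degree_centrality(g)),
                 unname(bf_degree(adj) / max(bf_degree(adj))))
    expect_equal(unname(clustering_coefficient(g)), unname(bf_clustering(adj)),
                 tolerance = 1e-12)
    expect_equal(unname(closeness_centrality(g)), unname(bf_closeness(adj)),
                 tolerance = 1e-12)
    gm <- global_metrics(g)
    expect_equal(gm$global_efficiency, bf_global_efficiency(adj), tolerance = 1e-12)
    expect_equal(gm$average_path_length, bf_path_length(adj), tolerance = 1e-12)
    expect_equal(gm$average_clustering, mean(bf_clustering(adj)), tolerance = 1e-12)
    expect_equal(gm$modularity,
                 bf_modularity(adj, gm$community_partition), tolerance = 1e-12)
  }
})

test_that("ring-of-6 efficiency matches the brute-force oracle", {
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- paste0("V", 1:6)
  adj <- igraph::as_adjacency_matrix(ring, sparse = FALSE)
  gm <- global_metrics(ring)
  expect_equal(gm$global_efficiency, bf_global_efficiency(adj))
})

test_that("adding an edge never lowers efficiency nor raises path length", {
  m <- rand_corr(15, 13)
  budgets <- c(14, 20, 30, 50, 80)
  effs <- pls <- numeric(length(budgets))
  for (i in seq_along(budgets)) {
    gm <- global_metrics(build_graph(m, budgets[i]))
    effs[i] <- gm$global_efficiency
    pls[i] <- gm$average_path_length
  }
  expect_true(all(diff(effs) >= -1e-12))
  expect_true(all(diff(pls) <= 1e-12))
})

test_that("two cliques joined by a bridge split into 2 communities with Q > 0.3", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5), igraph::make_full_graph(5))
  g <- igraph::add_edges(g, c(1, 6))
  igraph::V(g)$name <- paste0("V", 1:10)
  gm <- global_metrics(g)
  expect_equal(gm$n_communities, 2)
  expect_gt(gm$modularity, 0.3)
  expect_setequal(unname(gm$community_partition[1:5]),
                  rep(gm$community_partition[[1]], 5))
  # exhaustive check: no 2-partition beats the two-clique split
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  best <- max(vapply(1:(2^9), function(code) {
    mem <- c(1L, as.integer(intToBits(code))[1:9] + 1L)
    bf_modularity(adj, mem)
  }, numeric(1)))
  expect_equal(gm$modularity, best, tolerance = 1e-12)
  # between-community distance equals the brute-force mean over split pairs
  d <- bf_floyd(adj)
  between <- outer(gm$community_partition, gm$community_partition, "!=") & upper.tri(d)
  expect_equal(gm$avg_between_community_distance, mean(d[between]))
})

test_that("single-community partitions record a missing between-community distance", {
  # a complete graph has no community structure; the seeded Louvain option
  # returns the trivial one-community partition there
  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- paste0("V", 1:6)
  gm <- global_metrics(k6, community = "louvain", seed = 1)
  expect_equal(gm$n_communities, 1)
  expect_true(is.na(gm$avg_between_community_distance))
})

test_that("returned partitions always beat the trivial one-community partition", {
  for (seed in 6:8) {
    adj <- rand_connected_adj(12, 0.25, seed)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_gte(global_metrics(g)$modularity, 0)
  }
})

test_that("weighted degree modes behave per contract", {
  m0 <- diag(6)
  dimnames(m0) <- list(paste0("V", 1:6), paste0("V", 1:6))
  expect_equal(unname(weighted_degree(m0, mode = "all_pairs")), rep(0, 6))
  m1 <- matrix(1, 6, 6)
  dimnames(m1) <- dimnames(m0)
  expect_equal(unname(weighted_degree(m1, mode = "all_pairs")), rep(5, 6))
  # matrix where the MST forces a weak edge: node V6 attaches weakly
  m <- matrix(0.8, 6, 6)
  m[6, ] <- m[, 6] <- 0.1
  m[5, 6] <- m[6, 5] <- 0.15
  diag(m) <- 1
  dimnames(m) <- dimnames(m0)
  w_with <- weighted_degree(m, edge_budget = 8, mode = "with_mst")
  w_without <- weighted_degree(m, edge_budget = 8, mode = "without_mst")
  # without the MST constraint V6 is isolated; with it, its strongest link survives
  expect_equal(unname(w_without["V6"]), 0)
  expect_equal(unname(w_with["V6"]), 0.15)
  # both modes retain the same number of edges overall
  expect_equal(sum(w_with), sum(graph_edges(build_graph(m, 8))$weight) * 2)
})

test_that("stored correlation weights never leak into binarized metrics", {
  m <- rand_corr(15, 99)
  g <- build_graph(m, 40)       # carries |r| edge weights for export
  bare <- igraph::delete_edge_attr(g$graph, "weight")
  expect_identical(closeness_centrality(g), closeness_centrality(bare))
  gm_w <- global_metrics(g)
  gm_b <- global_metrics(bare)
  expect_identical(gm_w$global_efficiency, gm_b$global_efficiency)
  expect_identical(gm_w$average_path_length, gm_b$average_path_length)
  expect_identical(gm_w$modularity, gm_b$modularity)
  expect_gte(gm_w$average_path_length, 1)
  expect_lte(gm_w$global_efficiency, 1)
})

test_that("nodal metric matrices validate their shape and labels", {
  v <- matrix(1:6, 3, 2)
  mm <- nodal_metric_matrix(v, c("a", "b", "c"), c("RW", "TSD"), "S01", "degree")
  expect_equal(dim(mm$values), c(3, 2))
  expect_error(nodal_metric_matrix(v, c("a", "b"), c("RW", "TSD"), "S01", "degree"), "node ids")
  expect_error(nodal_metric_matrix(v, c("a", "a", "c"), c("RW", "TSD"), "S01", "degree"), "unique")
  v[1] <- NA
  expect_error(nodal_metric_matrix(v, c("a", "b", "c"), c("RW", "TSD"), "S01", "degree"), "finite")
})
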