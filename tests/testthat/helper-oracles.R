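# Independent brute-force oracles used to validate the graph machinery and
# statistics. These deliberately avoid igraph / p.adjust code paths.

# random symmetric correlation-like matrix with distinct |r| values
rand_corr <- function(n, seed) {
  set.seed(seed)
  w <- matrix(rnorm(n * 5), n)
  m <- cov2cor(tcrossprod(w) + diag(n))
  dimnames(m) <- list(sprintf("N%02d", 1:n), sprintf("N%02d", 1:n))
  m
}

# adjacency matrix of a random connected graph
rand_connected_adj <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    a <- matrix(0L, n, n)
    up <- which(upper.tri(a))
    a[up] <- as.integer(runif(length(up)) < p)
    a <- a + t(a)
    if (all(bf_floyd(a) < Inf)) break
  }
  dimnames(a) <- list(sprintf("N%02d", 1:n), sprintf("N%02d", 1:n))
  a
}

adj_from_brain_graph <- function(g) {
  a <- igraph::as_adjacency_matrix(g$graph, sparse = FALSE)
  dimnames(a) <- list(g$node_ids, g$node_ids)
  a
}

# all-pairs shortest paths, Floyd-Warshall on an unweighted adjacency matrix
bf_floyd <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

bf_degree <- function(adj) rowSums(adj > 0)

# explicit triangle counting
bf_clustering <- function(adj) {
  n <- nrow(adj)
  sapply(1:n, function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- sum(adj[nb, nb]) / 2
    tri / (k * (k - 1) / 2)
  })
}

bf_closeness <- function(adj) {
  d <- bf_floyd(adj)
  (nrow(adj) - 1) / rowSums(d)
}

bf_global_efficiency <- function(adj) {
  d <- bf_floyd(adj)
  mean(1 / d[upper.tri(d)])
}

bf_path_length <- function(adj) {
  d <- bf_floyd(adj)
  mean(d[upper.tri(d)])
}

# exhaustive minimum spanning tree: try every (n-1)-subset of edges
bf_mst_weight <- function(dist_mat) {
  n <- nrow(dist_mat)
  pairs <- which(upper.tri(dist_mat), arr.ind = TRUE)
  best <- Inf
  for (sel in utils::combn(nrow(pairs), n - 1, simplify = FALSE)) {
    a <- matrix(0L, n, n)
    for (e in sel) {
      a[pairs[e, 1], pairs[e, 2]] <- 1L
      a[pairs[e, 2], pairs[e, 1]] <- 1L
    }
    if (any(bf_floyd(a) == Inf)) next
    w <- sum(dist_mat[pairs[sel, , drop = FALSE]])
    if (w < best) best <- w
  }
  best
}

# Benjamini-Hochberg from the step-up definition
bf_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= seq_len(m) * q / m)
  k <- if (length(below)) max(below) else 0L
  rejected <- logical(m)
  if (k > 0) rejected[ord[seq_len(k)]] <- TRUE
  adj <- rev(cummin(rev(ps * m / seq_len(m))))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  list(p_adjusted = out, rejected = rejected)
}

# exhaustive sign-flip null of the mean difference
bf_signflip_p <- function(d) {
  n <- length(d)
  obs <- mean(d)
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null <- as.numeric(flips %*% d) / n
  mean(abs(null) >= abs(obs) - 1e-12)
}

# modularity of a partition from the definition Q = sum(e_ii - a_i^2)
bf_modularity <- function(adj, membership) {
  m2 <- sum(adj)
  q <- 0
  for (cmty in unique(membership)) {
    idx <- membership == cmty
    e_in <- sum(adj[idx, idx]) / m2
    a_i <- sum(adj[idx, ]) / m2
    q <- q + e_in - a_i^2
  }
  q
}

# quiet degree-sequence realization warnings from igraph in cohort helpers
quiet_cohort <- function(expr) suppressWarnings(expr)
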