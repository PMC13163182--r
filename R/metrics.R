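# Nodal and global topology metrics.
#
# Nodal: degree centrality (normalized by the maximum degree in the network,
# the convention of the hub-disruption literature, not the textbook N-1
# normalization), local clustering coefficient, closeness centrality.
# Global: global efficiency, average clustering (mean of nodal values),
# average shortest path length, modularity of a community partition, and the
# mean geodesic distance between nodes of different communities.

#' Degree centrality
#'
#' @param g A `brain_graph` or igraph object (connected).
#' @param normalization `"max"` divides each degree by the highest degree in
#'   the network (so the top hub scores exactly 1); `"classic"` divides by
#'   `N - 1`.
#' @return Named numeric vector over nodes.
#' @export
degree_centrality <- function(g, normalization = c("max", "classic")) {
  normalization <- match.arg(normalization)
  ig <- as_igraph(g)
  k <- igraph::degree(ig)
  denom <- if (normalization == "max") max(k) else igraph::vcount(ig) - 1
  if (denom == 0) stopf("degree_centrality: graph has no edges")
  k / denom
}

#' Local clustering coefficient
#'
#' Triangles through a node over the possible pairs among its neighbors;
#' nodes of degree < 2 get 0.
#'
#' @param g A `brain_graph` or igraph object.
#' @return Named numeric vector in \[0, 1\].
#' @export
clustering_coefficient <- function(g) {
  ig <- as_igraph(g)
  cc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  names(cc) <- igraph::V(ig)$name
  cc
}

#' Closeness centrality
#'
#' `(N - 1) / sum_j d(i, j)`: how efficiently information can spread from a
#' node to the rest of the network.
#'
#' @param g A connected `brain_graph` or igraph object.
#' @return Named numeric vector in (0, 1\].
#' @export
closeness_centrality <- function(g) {
  ig <- as_igraph(g)
  if (!igraph::is_connected(ig)) stopf("closeness_centrality: graph must be connected")
  # binarized topology: hop-count distances, ignoring any stored |r| weights
  d <- igraph::distances(ig, weights = NA)
  cl <- (nrow(d) - 1) / rowSums(d)
  names(cl) <- igraph::V(ig)$name
  cl
}

#' Weighted degree (nodal strength) of a correlation matrix
#'
#' Control-analysis variants of degree that keep edge magnitudes: the sum of
#' `|r|` over each node's retained pairs.
#'
#' @param cm A `wavelet_cor` object or symmetric correlation matrix.
#' @param edge_budget Edge budget used by the thresholded modes; ignored for
#'   `"all_pairs"`.
#' @param mode `"with_mst"` sums over the edges of [build_graph()] (MST
#'   anchoring included); `"without_mst"` sums over the `edge_budget` largest
#'   `|r|` pairs with no spanning-tree constraint; `"all_pairs"` sums `|r|`
#'   over every other node.
#' @return Named numeric vector of strengths.
#' @export
weighted_degree <- function(cm, edge_budget = NULL,
                            mode = c("with_mst", "without_mst", "all_pairs")) {
  mode <- match.arg(mode)
  m <- cm_matrix(cm)
  n <- nrow(m)
  ids <- rownames(m)
  a <- abs(m)
  diag(a) <- 0
  if (mode == "all_pairs") {
    out <- rowSums(a)
    names(out) <- ids
    return(out)
  }
  if (is.null(edge_budget)) stopf("weighted_degree: edge_budget required for mode '%s'", mode)
  if (mode == "with_mst") {
    el <- graph_edges(build_graph(m, edge_budget))
    ia <- match(el$node_a, ids); ib <- match(el$node_b, ids)
  } else {
    pairs <- upper_pairs(n)
    strength <- a[pairs]
    ord <- order(-strength, ids[pairs[, 1]], ids[pairs[, 2]])
    keep <- ord[seq_len(min(edge_budget, length(ord)))]
    ia <- pairs[keep, 1]; ib <- pairs[keep, 2]
  }
  out <- numeric(n)
  w <- a[cbind(ia, ib)]
  for (e in seq_along(w)) {
    out[ia[e]] <- out[ia[e]] + w[e]
    out[ib[e]] <- out[ib[e]] + w[e]
  }
  names(out) <- ids
  out
}

#' Community partition used for modularity
#'
#' @param g A `brain_graph` or igraph object.
#' @param method `"greedy"` (deterministic greedy modularity maximization,
#'   default) or `"louvain"` (seeded).
#' @param seed Seed for the stochastic `"louvain"` option.
#' @return Integer membership vector named by node.
#' @export
community_partition <- function(g, method = c("greedy", "louvain"), seed = 1L) {
  method <- match.arg(method)
  ig <- as_igraph(g)
  w1 <- rep(1, igraph::ecount(ig))
  comm <- if (method == "greedy") igraph::cluster_fast_greedy(ig, weights = w1)
          else with_seed(seed, igraph::cluster_louvain(ig, weights = w1))
  mem <- igraph::membership(comm)
  out <- as.integer(mem)
  names(out) <- igraph::V(ig)$name
  out
}

#' Global graph metrics
#'
#' @param g A connected `brain_graph` or igraph object.
#' @param community Community-detection method, see [community_partition()].
#' @param seed Seed used by the stochastic community option (logged in the
#'   output).
#' @return List of class `global_metrics`: `global_efficiency` (mean over
#'   node pairs of `1/d(i,j)`), `average_clustering` (mean of nodal clustering
#'   coefficients), `average_path_length` (mean over pairs of `d(i,j)`),
#'   `modularity`, `avg_between_community_distance` (mean geodesic distance
#'   over pairs in different communities; `NA` when the partition has a single
#'   community), `n_communities`, `community_partition`, `seed`.
#' @export
global_metrics <- function(g, community = c("greedy", "louvain"), seed = 1L) {
  community <- match.arg(community)
  ig <- as_igraph(g)
  if (!igraph::is_connected(ig)) stopf("global_metrics: graph must be connected")
  d <- igraph::distances(ig, weights = NA)
  up <- upper.tri(d)
  mem <- community_partition(ig, method = community, seed = seed)
  q <- igraph::modularity(ig, mem, weights = rep(1, igraph::ecount(ig)))
  between <- outer(mem, mem, "!=") & up
  avg_between <- if (max(mem) < 2) NA_real_ else mean(d[between])
  structure(list(
    subject_id = if (inherits(g, "brain_graph")) g$subject_id else NA_character_,
    condition = if (inherits(g, "brain_graph")) g$condition else NA_character_,
    global_efficiency = mean(1 / d[up]),
    average_clustering = mean(clustering_coefficient(ig)),
    average_path_length = mean(d[up]),
    modularity = q,
    avg_between_community_distance = avg_between,
    n_communities = max(mem),
    community_partition = mem,
    seed = seed
  ), class = "global_metrics")
}

#' Assemble a nodal metric matrix for one subject
#'
#' Houses per-node metric values across conditions: an `N x T` matrix over
#' nodes and condition labels, the unit of input to the hub disruption index.
#'
#' @param values `N x T` numeric matrix (nodes x conditions).
#' @param node_ids Node identifiers (length `N`).
#' @param condition_labels Condition labels (length `T`).
#' @param subject_id Subject identifier.
#' @param metric Metric name.
#' @return Object of class `nodal_metric_matrix`.
#' @export
nodal_metric_matrix <- function(values, node_ids, condition_labels,
                                subject_id, metric) {
  values <- as.matrix(values)
  if (anyNA(values) || any(!is.finite(values))) stopf("nodal_metric_matrix: values must be finite")
  if (nrow(values) != length(node_ids)) stopf("nodal_metric_matrix: %d rows but %d node ids",
                                              nrow(values), length(node_ids))
  if (ncol(values) != length(condition_labels)) stopf("nodal_metric_matrix: %d columns but %d condition labels",
                                                      ncol(values), length(condition_labels))
  if (anyDuplicated(node_ids)) stopf("nodal_metric_matrix: node ids must be unique")
  dimnames(values) <- list(node_ids, condition_labels)
  structure(list(values = values, node_ids = node_ids,
                 condition_labels = condition_labels,
                 subject_id = subject_id, metric = metric),
            class = "nodal_metric_matrix")
}

#' Nodal metric matrices for a cohort of graphs
#'
#' @param cohort_graphs Output of [generate_cohort_graphs()] (or any list of
#'   per-subject named lists of `brain_graph`s).
#' @param metric One of `"degree_centrality"` (max-normalized, the analysis
#'   default), `"degree"` (raw degree — the scale on which disruption is
#'   implanted, hence the one parameter-recovery checks use), `"closeness"`,
#'   `"clustering"`.
#' @return List of `nodal_metric_matrix`, one per subject.
#' @export
cohort_metric_matrices <- function(cohort_graphs,
                                   metric = c("degree_centrality", "degree",
                                              "closeness", "clustering")) {
  metric <- match.arg(metric)
  fun <- switch(metric,
                degree_centrality = degree_centrality,
                degree = function(g) igraph::degree(as_igraph(g)),
                closeness = closeness_centrality,
                clustering = clustering_coefficient)
  lapply(cohort_graphs, function(subj) {
    vals <- vapply(subj$graphs, fun, numeric(length(subj$graphs[[1]]$node_ids)))
    nodal_metric_matrix(vals, subj$graphs[[1]]$node_ids, names(subj$graphs),
                        subj$subject_id, metric)
  })
}
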