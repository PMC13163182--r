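# Graph construction: correlation matrix -> connected binarized graph with a
# fixed edge budget. The minimum spanning tree on the distance transform
# d = 1 - |r| is retained first so the network is connected at any budget;
# remaining edges are the strongest correlations, ranked by |r| (default) with
# lexicographic node-pair tie-breaking for bitwise reproducibility.

#' Number of possible edges of an undirected simple graph
#'
#' @param n_nodes Node count (>= 2).
#' @return `n_nodes * (n_nodes - 1) / 2`; 3916 for the 89-region parcellation.
#' @export
possible_edges <- function(n_nodes) {
  if (!is_count(n_nodes, min = 2)) stopf("possible_edges: n_nodes must be an integer >= 2")
  n_nodes * (n_nodes - 1) / 2
}

cm_matrix <- function(cm) {
  m <- if (inherits(cm, "wavelet_cor")) cm$values else as.matrix(cm)
  if (nrow(m) != ncol(m)) stopf("correlation matrix must be square")
  if (any(!is.finite(m))) stopf("correlation matrix must be finite")
  if (max(abs(m - t(m))) > 1e-8) stopf("correlation matrix must be symmetric")
  if (is.null(rownames(m))) dimnames(m) <- list(sprintf("R%03d", seq_len(nrow(m))),
                                                sprintf("R%03d", seq_len(nrow(m))))
  m
}

#' Minimum spanning tree of the correlation distance graph
#'
#' MST over the complete graph with distances `1 - |r|`, i.e. the spanning tree
#' maximizing total absolute correlation (up to ties).
#'
#' @param cm A `wavelet_cor` object or symmetric correlation matrix.
#' @return Two-column character matrix of node-id pairs (N - 1 rows).
#' @export
mst_edges <- function(cm) {
  m <- cm_matrix(cm)
  n <- nrow(m)
  pairs <- upper_pairs(n)
  d <- 1 - abs(m[pairs])
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- rownames(m)
  g <- igraph::add_edges(g, t(pairs))
  igraph::E(g)$weight <- d
  tree <- igraph::mst(g, weights = igraph::E(g)$weight)
  el <- igraph::as_edgelist(tree, names = TRUE)
  swap <- el[, 1] > el[, 2]
  el[swap, ] <- el[swap, 2:1]
  el[order(el[, 1], el[, 2]), , drop = FALSE]
}

#' Build a connected binarized brain graph at a fixed edge budget
#'
#' Keeps the MST of `1 - |r|` (connectedness at any budget), then adds the
#' strongest remaining correlations until exactly `edge_budget` edges are
#' retained. Ranking is by `|r|` descending by default (a signed-`r` mode is
#' provided since "strongest" is ambiguous for negative correlations); ties
#' break lexicographically on node-id pairs, so construction is deterministic.
#'
#' @param cm A `wavelet_cor` object or symmetric correlation matrix.
#' @param edge_budget Exact number of edges to retain
#'   (`N - 1 <= edge_budget <= possible_edges(N)`).
#' @param rank_by Rank non-tree candidates by `"abs"` (absolute correlation,
#'   default) or `"signed"` correlation.
#' @return Object of class `brain_graph`.
#' @export
build_graph <- function(cm, edge_budget, rank_by = c("abs", "signed")) {
  rank_by <- match.arg(rank_by)
  m <- cm_matrix(cm)
  n <- nrow(m)
  if (!is_count(edge_budget)) stopf("build_graph: edge_budget must be a positive integer")
  if (edge_budget < n - 1) stopf("build_graph: edge_budget %d cannot keep %d nodes connected (need >= %d)",
                                 edge_budget, n, n - 1)
  if (edge_budget > possible_edges(n)) stopf("build_graph: edge_budget %d exceeds the %d possible edges",
                                             edge_budget, possible_edges(n))
  ids <- rownames(m)
  pairs <- upper_pairs(n)
  key <- paste(ids[pairs[, 1]], ids[pairs[, 2]], sep = "\r")
  tree <- mst_edges(m)
  tree_key <- paste(tree[, 1], tree[, 2], sep = "\r")
  strength <- if (rank_by == "abs") abs(m[pairs]) else m[pairs]
  ord <- order(-strength, ids[pairs[, 1]], ids[pairs[, 2]])
  candidate <- ord[!(key[ord] %in% tree_key)]
  extra <- candidate[seq_len(edge_budget - nrow(tree))]
  sel <- rbind(tree, cbind(ids[pairs[extra, 1]], ids[pairs[extra, 2]]))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- ids
  g <- igraph::add_edges(g, t(matrix(match(sel, ids), ncol = 2)))
  igraph::E(g)$weight <- abs(m[cbind(match(sel[, 1], ids), match(sel[, 2], ids))])
  meta <- if (inherits(cm, "wavelet_cor")) cm[c("subject_id", "condition")] else
    list(subject_id = NA_character_, condition = NA_character_)
  new_brain_graph(g, ids, edge_budget, meta$subject_id, meta$condition)
}

new_brain_graph <- function(graph, node_ids, edge_budget,
                            subject_id = NA_character_, condition = NA_character_) {
  structure(list(
    graph = graph,
    node_ids = node_ids,
    edge_budget = edge_budget,
    subject_id = subject_id,
    condition = condition
  ), class = "brain_graph")
}

as_igraph <- function(g) {
  if (inherits(g, "brain_graph")) g$graph
  else if (igraph::is_igraph(g)) g
  else stopf("expected a brain_graph or igraph object")
}

#' @export
print.brain_graph <- function(x, ...) {
  cat(sprintf("brain graph: %d nodes, %d edges (cost %.2f%%)%s\n",
              length(x$node_ids), igraph::ecount(x$graph), graph_cost(x),
              if (!is.na(x$subject_id)) sprintf(" [%s/%s]", x$subject_id, x$condition) else ""))
  invisible(x)
}

#' Edge list of a brain graph
#'
#' @param g A `brain_graph`.
#' @return Data frame with columns `node_a`, `node_b`, `weight` (absolute
#'   correlation of the retained edge), lexicographically ordered.
#' @export
graph_edges <- function(g) {
  ig <- as_igraph(g)
  el <- igraph::as_edgelist(ig, names = TRUE)
  swap <- el[, 1] > el[, 2]
  el[swap, ] <- el[swap, 2:1]
  w <- if ("weight" %in% igraph::edge_attr_names(ig)) igraph::E(ig)$weight else rep(NA_real_, nrow(el))
  out <- data.frame(node_a = el[, 1], node_b = el[, 2], weight = w,
                    stringsAsFactors = FALSE)
  out[order(out$node_a, out$node_b), , drop = FALSE]
}

#' Graph cost (edge density as a percentage)
#'
#' @param g A `brain_graph` (or igraph object).
#' @return `100 * E / possible_edges(N)`: 200/400/600 edges on 89 nodes give
#'   ~5/10/15%, 2200 edges on 391 nodes ~3%.
#' @export
graph_cost <- function(g) {
  ig <- as_igraph(g)
  100 * igraph::ecount(ig) / possible_edges(igraph::vcount(ig))
}
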