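# Covariate-constrained manifold learning (CCML).
#
# An ISOMAP-style embedding in which the first coordinate of every record is
# clamped to alpha * covariate (here: the hub-disruption kappa), with alpha
# and the remaining coordinates free. The fit minimizes raw stress
#   sum_{i<j} (d_geo(i,j) - ||y_i - y_j||)^2
# over the free coordinates and the scalar alpha, where d_geo are geodesic
# (k-nearest-neighbor shortest-path) distances in feature space.

#' Geodesic distance matrix over a k-nearest-neighbor graph
#'
#' Euclidean k-NN graph (symmetrized union of neighborhoods) with edge
#' weights equal to Euclidean distance; geodesics are shortest paths. If the
#' graph is disconnected, k is incremented with a warning until it connects
#' (at `k = records - 1` the graph is complete, so this always terminates).
#'
#' @param features Records x features numeric matrix.
#' @param k Neighbor count (default 6).
#' @return List with `distances` (records x records symmetric matrix, zero
#'   diagonal) and `k` (the neighbor count actually used).
#' @export
geodesic_distances <- function(features, k = 6) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 3) stopf("geodesic_distances: need at least 3 records")
  if (!is_count(k) || k >= n) k <- min(max(1L, as.integer(k)), n - 1L)
  eu <- as.matrix(stats::dist(features))
  repeat {
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      nb <- order(eu[i, ])[2:(k + 1L)]
      adj[i, nb] <- TRUE
    }
    adj <- adj | t(adj)
    w <- eu
    w[!adj] <- 0
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected", weighted = TRUE)
    if (igraph::is_connected(g)) break
    if (k >= n - 1L) stopf("geodesic_distances: neighbor graph disconnected at k = records - 1")
    k <- k + 1L
    warnf("geodesic_distances: k-NN graph disconnected; escalating to k = %d", k)
  }
  d <- igraph::distances(g)
  dimnames(d) <- list(rownames(features), rownames(features))
  list(distances = d, k = as.integer(k))
}

embedding_stress <- function(D, Y) {
  sum((D[lower.tri(D)] - stats::dist(Y))^2)
}

cmdscale_init <- function(D, dim) {
  Y0 <- stats::cmdscale(D, k = dim)
  if (ncol(Y0) < dim) Y0 <- cbind(Y0, matrix(0, nrow(Y0), dim - ncol(Y0)))
  Y0
}

new_embedding <- function(coordinates, alpha, stress, stress_initial, D,
                          neighbor_k, seed, covariate, record_ids, method) {
  rownames(coordinates) <- record_ids
  colnames(coordinates) <- paste0("coord_", seq_len(ncol(coordinates)) - 1L)
  structure(list(
    coordinates = coordinates, alpha = alpha, stress = stress,
    stress_initial = stress_initial,
    stress_normalized = stress / sum(D[lower.tri(D)]^2),
    neighbor_k = neighbor_k, seed = seed, covariate = covariate,
    record_ids = record_ids, method = method
  ), class = "ccml_embedding")
}

#' @export
print.ccml_embedding <- function(x, ...) {
  cat(sprintf("%s embedding: %d records x %d dims; stress %.4g (normalized %.4g)%s\n",
              x$method, nrow(x$coordinates), ncol(x$coordinates), x$stress,
              x$stress_normalized,
              if (is.na(x$alpha)) "" else sprintf("; alpha = %.4g", x$alpha)))
  invisible(x)
}

#' Classical ISOMAP embedding
#'
#' Geodesic distances followed by classical multidimensional scaling; the
#' unconstrained baseline CCML is compared against.
#'
#' @param features Records x features numeric matrix.
#' @param dim Target dimension (>= 2).
#' @param k Neighbor count for the geodesic graph.
#' @return A `ccml_embedding` with `alpha = NA` and `method = "isomap"`.
#' @export
isomap_fit <- function(features, dim = 2, k = 6) {
  gd <- geodesic_distances(features, k)
  Y <- cmdscale_init(gd$distances, dim)
  s <- embedding_stress(gd$distances, Y)
  new_embedding(Y, NA_real_, s, s, gd$distances, gd$k, NA_integer_,
                covariate = rep(NA_real_, nrow(Y)),
                record_ids = rownames(features) %||% sprintf("rec%03d", seq_len(nrow(Y))),
                method = "isomap")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Covariate-constrained manifold embedding
#'
#' Fits an embedding whose first coordinate is exactly `alpha * covariate`
#' (a hard constraint), minimizing raw stress against geodesic feature-space
#' distances over the free coordinates and alpha jointly (BFGS), initialized
#' from classical MDS with alpha set by least-squares projection of
#' coordinate 0 onto the covariate.
#'
#' @param features Records x features numeric matrix (default feature: the
#'   per-node degree-centrality vector of each record).
#' @param covariate Scalar covariate per record (here: kappa).
#' @param dim Target dimension (>= 2).
#' @param k Neighbor count for the geodesic graph.
#' @param seed Seed (recorded; used by any stochastic restart).
#' @param allow_degenerate_features Permit feature columns that are constant
#'   zero (refused by default: a metric with structurally absent variation,
#'   like the clustering coefficient on sparse graphs, is not a usable
#'   embedding feature).
#' @param maxit BFGS iteration cap.
#' @return Object of class `ccml_embedding`; `coordinates[, 1]` equals
#'   `alpha * covariate` to machine precision. With an all-equal covariate
#'   alpha is unidentifiable and the fit falls back to classical ISOMAP with
#'   a warning.
#' @export
ccml_fit <- function(features, covariate, dim = 2, k = 6, seed = 1L,
                     allow_degenerate_features = FALSE, maxit = 500) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 4) stopf("ccml_fit: need at least 4 records")
  if (!is_count(dim, 2)) stopf("ccml_fit: dim must be an integer >= 2")
  if (length(covariate) != n) stopf("ccml_fit: covariate length must equal record count")
  if (anyNA(covariate) || any(!is.finite(covariate))) stopf("ccml_fit: covariate must be finite")
  degen <- apply(features, 2L, function(col) all(col == 0))
  if (any(degen) && !allow_degenerate_features)
    stopf("ccml_fit: %d feature column(s) are constant zero; refuse to embed (override with allow_degenerate_features = TRUE)",
          sum(degen))
  ids <- rownames(features) %||% sprintf("rec%03d", seq_len(n))
  gd <- geodesic_distances(features, k)
  D <- gd$distances
  if (stats::sd(covariate) == 0) {
    warnf("ccml_fit: covariate has no variance; alpha unidentifiable, falling back to classical ISOMAP")
    emb <- isomap_fit(features, dim = dim, k = gd$k)
    emb$record_ids <- ids
    rownames(emb$coordinates) <- ids
    return(emb)
  }
  Y0 <- cmdscale_init(D, dim)
  alpha0 <- sum(covariate * Y0[, 1]) / sum(covariate^2)
  if (!is.finite(alpha0) || alpha0 == 0) alpha0 <- 1e-3
  build_Y <- function(par) {
    cbind(par[1] * covariate,
          matrix(par[-1], n, dim - 1L))
  }
  par0 <- c(alpha0, as.numeric(Y0[, -1, drop = FALSE]))
  stress_initial <- embedding_stress(D, build_Y(par0))
  fn <- function(par) embedding_stress(D, build_Y(par))
  opt <- with_seed(seed,
    stats::optim(par0, fn, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-12)))
  Y <- build_Y(opt$par)
  new_embedding(Y, opt$par[1], opt$value, stress_initial, D, gd$k,
                as.integer(seed), covariate, ids, method = "ccml")
}

#' Centroid-distance permutation test on an embedding
#'
#' Euclidean distance between the centroids of two labeled groups in the
#' embedding, tested against a null of random label shuffles (upper-tailed:
#' larger distance = stronger separation).
#'
#' @param embedding A `ccml_embedding` (or a records x dim coordinate
#'   matrix).
#' @param labels Two-level grouping vector over records.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed RNG seed.
#' @return A `perm_test` object with `observed` the centroid distance.
#' @export
centroid_distance_test <- function(embedding, labels, n_perm = 10000, seed = 1L) {
  n_perm <- check_n_perm(n_perm)
  Y <- if (inherits(embedding, "ccml_embedding")) embedding$coordinates else as.matrix(embedding)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stopf("centroid_distance_test: exactly 2 label groups required")
  if (any(table(labels) < 2)) stopf("centroid_distance_test: each group needs at least 2 records")
  z <- as.integer(labels) == 1L
  n1 <- sum(z); n2 <- sum(!z)
  cdist <- function(zz) {
    sqrt(sum((colSums(Y[zz, , drop = FALSE]) / n1 -
              colSums(Y[!zz, , drop = FALSE]) / n2)^2))
  }
  observed <- cdist(z)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) cdist(sample(z)), numeric(1))
  })
  new_perm_result("centroid_distance", n_perm, null, observed, seed,
                  tail = "upper")
}

#' Leave-one-out stability of the centroid distance
#'
#' Two complementary diagnostics: `"fixed_embedding"` drops one record at a
#' time and recomputes the centroid distance inside the existing embedding
#' (fast path, no re-optimization); `"refit"` refits the whole embedding
#' without the record and recomputes the distance, probing structural
#' stability of the manifold.
#'
#' @param features Records x features matrix.
#' @param covariate Scalar covariate per record.
#' @param labels Two-level grouping vector.
#' @param mode `"fixed_embedding"` or `"refit"`.
#' @param dim,k,seed Passed to [ccml_fit()].
#' @return List with `distances` (one per left-out record, named),
#'   `full_distance`, `sd`, `range`.
#' @export
loo_centroid_stability <- function(features, covariate, labels,
                                   mode = c("fixed_embedding", "refit"),
                                   dim = 2, k = 6, seed = 1L) {
  mode <- match.arg(mode)
  features <- as.matrix(features)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stopf("loo_centroid_stability: exactly 2 label groups required")
  if (any(table(labels) < 5)) stopf("loo_centroid_stability: each group needs at least 5 records")
  n <- nrow(features)
  centroid_dist <- function(Y, lab) {
    g1 <- lab == levels(lab)[1]
    sqrt(sum((colMeans(Y[g1, , drop = FALSE]) - colMeans(Y[!g1, , drop = FALSE]))^2))
  }
  full <- ccml_fit(features, covariate, dim = dim, k = k, seed = seed)
  full_d <- centroid_dist(full$coordinates, labels)
  dists <- vapply(seq_len(n), function(i) {
    if (mode == "fixed_embedding") {
      centroid_dist(full$coordinates[-i, , drop = FALSE], droplevels(labels[-i]))
    } else {
      emb <- ccml_fit(features[-i, , drop = FALSE], covariate[-i],
                      dim = dim, k = k, seed = seed)
      centroid_dist(emb$coordinates, droplevels(labels[-i]))
    }
  }, numeric(1))
  names(dists) <- full$record_ids
  list(distances = dists, full_distance = full_d,
       sd = stats::sd(dists), range = range(dists), mode = mode)
}
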