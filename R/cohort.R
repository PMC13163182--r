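# Synthetic multi-subject, multi-condition cohort with implanted hub
# disruption.
#
# The generator emulates the study design this package targets: 28 subjects
# scanned under three conditions (reference first), 89 regions, 8-minute
# scans at TR = 1.25 s (384 volumes). Cross-regional covariance has a
# core-periphery structure (a minority of hub regions with elevated
# correlations), because the hub disruption index is only informative when
# the reference degree distribution is heterogeneous. Non-reference
# conditions implant a disruption of known strength kappa on the degree
# sequence of the reference graph, so the index is recoverable by
# construction.

#' Specification of a synthetic cohort
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param conditions Ordered condition labels, reference first.
#' @param n_regions Number of regions/nodes (>= 5).
#' @param n_volumes Time points per scan (default 384 = 8 min at TR 1.25 s).
#' @param tr_seconds Sampling interval in seconds.
#' @param hub_fraction Fraction of nodes designated hubs (default 0.15).
#' @param base_connectivity Named correlation levels `hub_hub`,
#'   `hub_periphery`, `periphery_periphery` in `[0, 1)`; must yield a
#'   positive-definite correlation matrix.
#' @param kappa_targets Named map condition -> target disruption slope; the
#'   reference condition must map to 0.
#' @param temporal_ar AR(1) coefficient of the temporal model in `[0, 1)`.
#' @param noise_sd Residual scale of the generated series.
#' @param edge_budget Edge budget of the reference graph on which disruption
#'   is implanted (default 400).
#' @param seed Master seed; every stream in the generator derives from it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 28,
                        conditions = c("RW", "TSD", "CSR"),
                        n_regions = 89,
                        n_volumes = 384,
                        tr_seconds = 1.25,
                        hub_fraction = 0.15,
                        base_connectivity = c(hub_hub = 0.50,
                                              hub_periphery = 0.25,
                                              periphery_periphery = 0.12),
                        kappa_targets = c(RW = 0, TSD = -0.5, CSR = -0.3),
                        temporal_ar = 0.3,
                        noise_sd = 1,
                        edge_budget = 400,
                        seed = 1L) {
  if (!is_count(n_subjects, 2)) stopf("cohort_spec: n_subjects must be an integer >= 2")
  if (!is_count(n_regions, 5)) stopf("cohort_spec: n_regions must be an integer >= 5")
  if (!is_count(n_volumes, 16)) stopf("cohort_spec: n_volumes must be an integer >= 16")
  if (anyDuplicated(conditions) || length(conditions) < 1) stopf("cohort_spec: conditions must be unique labels")
  if (!is_number(tr_seconds) || tr_seconds <= 0) stopf("cohort_spec: tr_seconds must be positive")
  if (!is_number(hub_fraction) || hub_fraction <= 0 || hub_fraction > 0.5)
    stopf("cohort_spec: hub_fraction must be in (0, 0.5]")
  need <- c("hub_hub", "hub_periphery", "periphery_periphery")
  if (!all(need %in% names(base_connectivity)))
    stopf("cohort_spec: base_connectivity needs levels %s", paste(need, collapse = ", "))
  bc <- base_connectivity[need]
  if (any(bc < 0 | bc >= 1)) stopf("cohort_spec: base_connectivity levels must lie in [0, 1)")
  if (!all(conditions %in% names(kappa_targets)))
    stopf("cohort_spec: kappa_targets must name every condition")
  kt <- kappa_targets[conditions]
  if (abs(kt[[1]]) > 1e-12) stopf("cohort_spec: reference condition '%s' must have kappa_target 0", conditions[1])
  if (any(kt < -1.5 | kt > 0.5)) stopf("cohort_spec: kappa_targets must lie in [-1.5, 0.5]")
  if (!is_number(temporal_ar) || temporal_ar < 0 || temporal_ar >= 1)
    stopf("cohort_spec: temporal_ar must be in [0, 1)")
  if (!is_number(noise_sd) || noise_sd <= 0) stopf("cohort_spec: noise_sd must be positive")
  if (!is_count(edge_budget, n_regions - 1)) stopf("cohort_spec: edge_budget must be an integer >= n_regions - 1")
  if (edge_budget > possible_edges(n_regions))
    stopf("cohort_spec: edge_budget exceeds possible edges for %d regions", n_regions)
  if (!is_count(seed, 0)) stopf("cohort_spec: seed must be a non-negative integer")
  spec <- structure(list(
    n_subjects = as.integer(n_subjects), conditions = conditions,
    n_regions = as.integer(n_regions), n_volumes = as.integer(n_volumes),
    tr_seconds = tr_seconds, hub_fraction = hub_fraction,
    base_connectivity = bc, kappa_targets = kt,
    temporal_ar = temporal_ar, noise_sd = noise_sd,
    edge_budget = as.integer(edge_budget), seed = as.integer(seed)
  ), class = "cohort_spec")
  # positive definiteness of the base correlation structure is part of spec
  # validity: fail at construction, not deep inside the simulator
  base <- base_correlation(spec)
  ev <- min(eigen(base, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10)
    stopf("cohort_spec: base_connectivity levels do not yield a positive-definite covariance (min eigenvalue %.3g)", ev)
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("cohort spec: %d subjects x %s; %d regions, %d volumes at TR %.3gs; seed %d\n",
              x$n_subjects, paste(x$conditions, collapse = "/"),
              x$n_regions, x$n_volumes, x$tr_seconds, x$seed))
  cat(sprintf("  kappa targets: %s\n",
              paste(sprintf("%s=%.2g", names(x$kappa_targets), x$kappa_targets), collapse = ", ")))
  invisible(x)
}

n_hubs <- function(spec) max(2L, round(spec$hub_fraction * spec$n_regions))

region_ids <- function(n) sprintf("R%03d", seq_len(n))

#' Core-periphery base correlation matrix of a spec
#' @noRd
base_correlation <- function(spec) {
  n <- spec$n_regions
  nh <- n_hubs(spec)
  bc <- spec$base_connectivity
  is_hub <- c(rep(TRUE, nh), rep(FALSE, n - nh))
  m <- matrix(bc[["periphery_periphery"]], n, n)
  m[is_hub, is_hub] <- bc[["hub_hub"]]
  m[is_hub, !is_hub] <- bc[["hub_periphery"]]
  m[!is_hub, is_hub] <- bc[["hub_periphery"]]
  diag(m) <- 1
  dimnames(m) <- list(region_ids(n), region_ids(n))
  m
}

#' Subject-specific reference correlation matrix
#'
#' Three sources of interindividual variability on top of the core-periphery
#' base: (i) two of the designated hub slots are swapped with two periphery
#' nodes (a node relabeling, so hub sets differ mildly across subjects),
#' (ii) per-node strength factors u_i ~ U(0.8, 1) scale the off-diagonal by
#' u_i u_j, and (iii) pairwise N(0, 0.04) jitter so edge orderings are not
#' block-deterministic (without it, thresholded graphs are near-unique
#' realizations of their degree sequence and carry no sampling variability).
#' Positive definiteness is restored by flooring eigenvalues at 0.05 and
#' renormalizing to unit diagonal.
#' @noRd
subject_correlation <- function(spec, subject_seed, pair_jitter_sd = 0.04) {
  base <- base_correlation(spec)
  n <- spec$n_regions
  nh <- n_hubs(spec)
  m <- with_seed(subject_seed, {
    u <- stats::runif(n, 0.8, 1.0)
    perm <- seq_len(n)
    if (nh > 2 && n - nh > 2) {
      hubs_out <- sample(seq_len(nh), 2L)
      periph_in <- sample((nh + 1L):n, 2L)
      perm[hubs_out] <- periph_in
      perm[periph_in] <- hubs_out
    }
    e <- matrix(stats::rnorm(n * n, 0, pair_jitter_sd), n, n)
    base[perm, perm] * outer(u, u) + (e + t(e)) / sqrt(2)
  })
  diag(m) <- 1
  es <- eigen(m, symmetric = TRUE)
  if (min(es$values) < 0.05) {
    m <- es$vectors %*% (pmax(es$values, 0.05) * t(es$vectors))
    m <- stats::cov2cor(m)
  }
  dimnames(m) <- list(region_ids(n), region_ids(n))
  m
}

# ---------------------------------------------------------------------------
# Disruption implant on degree sequences

erdos_gallai_ok <- function(d) {
  d <- sort(as.integer(d), decreasing = TRUE)
  n <- length(d)
  if (sum(d) %% 2 != 0 || any(d < 0) || any(d > n - 1)) return(FALSE)
  cs <- cumsum(d)
  for (k in seq_len(n)) {
    rhs <- k * (k - 1) + sum(pmin(d[-seq_len(k)], k))
    if (cs[k] > rhs) return(FALSE)
  }
  TRUE
}

#' Realize a graphical degree sequence as a random simple connected graph
#' @noRd
realize_degree_sequence <- function(degrees, seed) {
  degrees <- as.integer(degrees)
  g <- tryCatch(
    with_seed(seed, suppressWarnings(igraph::sample_degseq(degrees, method = "vl"))),
    error = function(e) NULL
  )
  if (is.null(g) || !igraph::is_connected(g)) {
    # deterministic Havel-Hakimi realization followed by degree-preserving
    # rewiring; retry until connected
    for (attempt in seq_len(25L)) {
      g <- igraph::realize_degseq(degrees, method = "smallest")
      g <- with_seed(seed + attempt,
                     igraph::rewire(g, igraph::keeping_degseq(niter = 20 * sum(degrees))))
      if (igraph::is_connected(g)) break
    }
    if (!igraph::is_connected(g)) stopf("realize_degree_sequence: could not realize a connected graph")
  }
  igraph::V(g)$name <- region_ids(length(degrees))
  g
}

#' Implant a hub disruption of known strength on a degree sequence
#'
#' Inverts the hub-disruption regression: given reference degrees `d` and a
#' target slope `kappa_target`, constructs target degrees
#' `d'_i = round((1 + kappa_target) d_i + c)` with the offset `c` chosen so
#' the total edge count is preserved, values clipped to `[1, N - 1]` and the
#' sum parity corrected, then realizes the sequence as a random simple
#' connected graph. Regressing `d' - d` on `d` recovers the implanted slope
#' up to rounding/clipping noise.
#'
#' @param reference_degrees Non-negative integer vector of reference degrees.
#' @param kappa_target Target disruption slope in `[-1.5, 0.5]`.
#' @param total_edges Edge count of the realized graph (`sum(d') = 2 * total_edges`).
#' @param seed Seed for the randomized realization.
#' @return List with `target_degrees`, `graph` (a `brain_graph`), and
#'   `kappa_realized` (the slope recovered from the constructed sequence).
#' @export
implant_disruption <- function(reference_degrees, kappa_target, total_edges, seed = 1L) {
  d <- reference_degrees
  if (anyNA(d) || any(d < 0) || any(d != round(d))) stopf("implant_disruption: reference degrees must be non-negative integers")
  if (!is_number(kappa_target) || kappa_target < -1.5 || kappa_target > 0.5)
    stopf("implant_disruption: kappa_target must lie in [-1.5, 0.5]")
  n <- length(d)
  if (!is_count(total_edges, n - 1)) stopf("implant_disruption: total_edges must be an integer >= N - 1")
  if (total_edges > n * (n - 1) / 2) stopf("implant_disruption: total_edges exceeds possible edges")
  target_sum <- 2L * as.integer(total_edges)

  clipped <- function(cc) pmin(pmax(round((1 + kappa_target) * d + cc), 1L), n - 1L)
  # offset c: sum(clipped(c)) is nondecreasing in c; bisect to hit target_sum
  lo <- -2 * n; hi <- 2 * n
  for (i in seq_len(80L)) {
    mid <- (lo + hi) / 2
    if (sum(clipped(mid)) < target_sum) lo <- mid else hi <- mid
  }
  dp <- as.integer(clipped(hi))
  # distribute any residual one unit at a time over seeded node order
  resid <- target_sum - sum(dp)
  ord <- with_seed(seed, sample.int(n))
  i <- 1L
  guard <- 0L
  while (resid != 0L && guard < 20L * n) {
    node <- ord[((i - 1L) %% n) + 1L]
    if (resid > 0L && dp[node] < n - 1L) { dp[node] <- dp[node] + 1L; resid <- resid - 1L }
    if (resid < 0L && dp[node] > 1L) { dp[node] <- dp[node] - 1L; resid <- resid + 1L }
    i <- i + 1L; guard <- guard + 1L
  }
  if (resid != 0L) stopf("implant_disruption: could not match the requested edge total")
  # iterative redistribution if the corrected sequence is not graphical
  guard <- 0L
  while (!erdos_gallai_ok(dp)) {
    hi_i <- which.max(dp); lo_i <- which.min(dp)
    if (dp[hi_i] - dp[lo_i] < 2L || guard > 10L * n)
      stopf("implant_disruption: degree sequence not graphical and redistribution failed")
    dp[hi_i] <- dp[hi_i] - 1L
    dp[lo_i] <- dp[lo_i] + 1L
    guard <- guard + 1L
  }
  g <- realize_degree_sequence(dp, seed)
  fit <- stats::lm.fit(cbind(1, d), dp - d)
  list(
    target_degrees = stats::setNames(dp, region_ids(n)),
    graph = new_brain_graph(g, region_ids(n), as.integer(total_edges)),
    kappa_realized = unname(fit$coefficients[2])
  )
}

# ---------------------------------------------------------------------------
# Cohort generation

subject_ids <- function(n) sprintf("S%02d", seq_len(n))

#' Generate a cohort of graph pairs with implanted disruption
#'
#' The direct graph-level path: for each subject, the reference degree
#' sequence comes from the graph built on that subject's generating
#' correlation matrix; the reference-condition graph and every disrupted
#' condition graph are then independent randomized realizations (the
#' disrupted ones after applying the degree-sequence implant for the
#' condition's kappa target). Because all condition graphs are drawn by the
#' same realization mechanism, a zero-kappa condition is exchangeable with
#' the reference — the property permutation-calibration studies rely on.
#'
#' @param spec A [cohort_spec()].
#' @param edge_budget Edge budget (defaults to `spec$edge_budget`).
#' @return List of subjects; each element has `subject_id`,
#'   `reference_degrees`, and `graphs` (named list of `brain_graph` per
#'   condition).
#' @export
generate_cohort_graphs <- function(spec, edge_budget = spec$edge_budget) {
  stopifnot(inherits(spec, "cohort_spec"))
  subj_seeds <- derive_seeds(spec$seed, spec$n_subjects)
  ids <- subject_ids(spec$n_subjects)
  out <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    cond_seeds <- derive_seeds(subj_seeds[s] + 1L, length(spec$conditions))
    sigma <- subject_correlation(spec, subj_seeds[s])
    g_ref <- build_graph(sigma, edge_budget)
    d <- igraph::degree(g_ref$graph)
    graphs <- vector("list", length(spec$conditions))
    names(graphs) <- spec$conditions
    for (t in seq_along(spec$conditions)) {
      cond <- spec$conditions[t]
      kap <- spec$kappa_targets[[cond]]
      gt <- if (abs(kap) < 1e-12) {
        new_brain_graph(realize_degree_sequence(d, cond_seeds[t]),
                        region_ids(spec$n_regions), edge_budget)
      } else {
        implant_disruption(d, kap, edge_budget, seed = cond_seeds[t])$graph
      }
      gt$subject_id <- ids[s]
      gt$condition <- cond
      graphs[[t]] <- gt
    }
    out[[s]] <- list(subject_id = ids[s],
                     reference_degrees = stats::setNames(d, region_ids(spec$n_regions)),
                     graphs = graphs)
  }
  names(out) <- ids
  out
}

#' Condition correlation matrix carrying an implanted adjacency
#'
#' Edge-level reweighting: pairs joined in the (possibly disrupted) condition
#' graph get correlation `edge_r`, everything else the periphery level; the
#' whole matrix is then uniformly shrunk toward the identity until its
#' smallest eigenvalue reaches `min_eigen`. Shrinking is a monotone transform
#' of the off-diagonal entries, so the rank order of correlations — and hence
#' the thresholded graph — is preserved.
#' @noRd
condition_correlation <- function(adj, base_level, edge_r = 0.5, min_eigen = 0.05) {
  m <- base_level * (1 - adj) + edge_r * adj
  diag(m) <- 1
  ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < min_eigen) {
    c0 <- min_eigen - ev
    m <- (m + diag(c0, nrow(m))) / (1 + c0)
  }
  m
}

#' Simulate an AR(1)-filtered multivariate Gaussian series
#'
#' Innovations e_t ~ N(0, Sigma); x_t = phi x_{t-1} + sqrt(1 - phi^2) e_t, so
#' the stationary cross-sectional covariance equals Sigma exactly.
#' @noRd
simulate_series <- function(sigma, n_volumes, phi, noise_sd, seed, burn_in = 50L) {
  n <- nrow(sigma)
  cf <- chol(sigma)
  total <- n_volumes + burn_in
  z <- with_seed(seed, matrix(stats::rnorm(total * n), total, n))
  eps <- z %*% cf
  if (phi > 0) {
    eps <- apply(eps * sqrt(1 - phi^2), 2L, function(e) stats::filter(e, phi, method = "recursive"))
  }
  t(eps[(burn_in + 1L):total, , drop = FALSE]) * noise_sd
}

#' Generate a synthetic cohort of regional time series
#'
#' For each subject x condition, draws an AR(1)-filtered multivariate
#' Gaussian series whose cross-regional correlation carries the condition's
#' implanted disruption (see [implant_disruption()]); the reference condition
#' uses the subject's core-periphery correlation matrix directly. Output is
#' fully reproducible from the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @return List of `regional_ts` objects (length
#'   `n_subjects * length(conditions)`), named `subject_condition`, with the
#'   spec attached as attribute `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  subj_seeds <- derive_seeds(spec$seed, spec$n_subjects)
  ids <- subject_ids(spec$n_subjects)
  base_level <- spec$base_connectivity[["periphery_periphery"]]
  out <- list()
  for (s in seq_len(spec$n_subjects)) {
    cond_seeds <- derive_seeds(subj_seeds[s] + 1L, length(spec$conditions))
    series_seeds <- derive_seeds(subj_seeds[s] + 2L, length(spec$conditions))
    sigma_ref <- subject_correlation(spec, subj_seeds[s])
    g_ref <- build_graph(sigma_ref, spec$edge_budget)
    d <- igraph::degree(g_ref$graph)
    for (t in seq_along(spec$conditions)) {
      cond <- spec$conditions[t]
      kap <- spec$kappa_targets[[cond]]
      sigma_t <- if (abs(kap) < 1e-12) {
        sigma_ref
      } else {
        imp <- implant_disruption(d, kap, spec$edge_budget, seed = cond_seeds[t])
        adj <- igraph::as_adjacency_matrix(imp$graph$graph, sparse = FALSE)
        condition_correlation(adj, base_level)
      }
      vals <- simulate_series(sigma_t, spec$n_volumes, spec$temporal_ar,
                              spec$noise_sd, series_seeds[t])
      rownames(vals) <- region_ids(spec$n_regions)
      out[[paste(ids[s], cond, sep = "_")]] <- structure(list(
        subject_id = ids[s], condition = cond, values = vals,
        region_ids = region_ids(spec$n_regions), tr_seconds = spec$tr_seconds
      ), class = "regional_ts")
    }
  }
  attr(out, "spec") <- spec
  out
}

#' @export
print.regional_ts <- function(x, ...) {
  cat(sprintf("regional time series: %s/%s, %d regions x %d volumes (TR %.3gs)\n",
              x$subject_id, x$condition, nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}
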