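# Permutation validation of the within-subject hub disruption index, plus
# generic paired/unpaired permutation comparisons.
#
# Conventions shared by all tests:
# * p-values use the add-one convention, (1 + #extreme) / (1 + n_perm), so
#   they never return 0;
# * two-tailed p is centered on the null-distribution mean (the HDI nulls
#   are not centered at 0 by construction); an uncentered option exists;
# * Cohen's d is (observed - mean(null)) / sd(null);
# * everything is reproducible bit-for-bit from (inputs, seed, n_perm).

new_perm_result <- function(test, n_perm, null, observed, seed,
                            tail = c("two_tailed_centered", "two_tailed", "upper"),
                            extra = list()) {
  tail <- match.arg(tail)
  mu <- mean(null)
  p <- switch(tail,
    two_tailed_centered = (1 + sum(abs(null - mu) >= abs(observed - mu))) / (1 + n_perm),
    two_tailed = (1 + sum(abs(null) >= abs(observed))) / (1 + n_perm),
    upper = (1 + sum(null >= observed)) / (1 + n_perm)
  )
  sd0 <- stats::sd(null)
  d <- if (sd0 > 0) (observed - mu) / sd0 else NA_real_
  structure(c(list(test = test, n_permutations = n_perm,
                   null_distribution = null, observed = observed,
                   p_value = p, tail = tail, cohens_d = d, seed = seed),
              extra), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation test '%s': observed %.4f, null %.4f +/- %.4f (%d perms)\n  p (%s) = %.4g, Cohen's d = %.2f\n",
              x$test, x$observed, mean(x$null_distribution),
              stats::sd(x$null_distribution), x$n_permutations,
              x$tail, x$p_value, x$cohens_d))
  invisible(x)
}

check_n_perm <- function(n_perm) {
  if (!is_count(n_perm)) stopf("n_perm must be a positive integer")
  if (n_perm < 100) warnf("n_perm = %d is low; p-values will be unstable", n_perm)
  as.integer(n_perm)
}

slope_on <- function(x) {
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) stopf("kappa slope: regressor has zero variance")
  list(xc = xc, sxx = sxx)
}

# slope of (y - x) on x with intercept, vectorized over columns of Y
slopes_vs_ref <- function(x, Y) {
  s <- slope_on(x)
  as.numeric(crossprod(Y - x, s$xc)) / s$sxx
}

#' First permutation test: node-label shuffles
#'
#' Evaluates whether the within-subject index is more sensitive than the
#' group-level index once anatomical correspondence is destroyed. Per
#' permutation, the deprived-condition metric vector of every subject is
#' independently shuffled over nodes (reference vectors and subject pairing
#' untouched); kappa_within (against the subject's own reference) and
#' kappa_group (against the group-averaged reference) are recomputed and the
#' statistic is `mean(kappa_within - kappa_group)`. Negative values indicate
#' stronger apparent disruption when the subject's own baseline is the
#' reference.
#'
#' @param metric_matrices List of [nodal_metric_matrix()] objects, one per
#'   subject, all with the same node ordering.
#' @param reference,condition Condition labels (reference and deprived).
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed.
#' @return A `perm_test` object; `observed` is the unpermuted mean
#'   difference.
#' @export
test_node_shuffle <- function(metric_matrices, reference, condition,
                              n_perm = 10000, seed = 1L) {
  n_perm <- check_n_perm(n_perm)
  refs <- lapply(metric_matrices, function(mm) mm$values[, reference])
  conds <- lapply(metric_matrices, function(mm) mm$values[, condition])
  group_mean <- Reduce(`+`, refs) / length(refs)
  n_nodes <- length(group_mean)
  kap_pair <- function(ref, Y) {
    cbind(within = slopes_vs_ref(ref, Y), group = slopes_vs_ref(group_mean, Y))
  }
  observed <- mean(vapply(seq_along(refs), function(s) {
    k <- kap_pair(refs[[s]], cbind(conds[[s]]))
    k[1, "within"] - k[1, "group"]
  }, numeric(1)))
  null <- with_seed(seed, {
    diffs <- matrix(0, n_perm, length(refs))
    for (s in seq_along(refs)) {
      perms <- replicate(n_perm, sample.int(n_nodes))
      Y <- matrix(conds[[s]][perms], n_nodes, n_perm)
      k <- kap_pair(refs[[s]], Y)
      diffs[, s] <- k[, "within"] - k[, "group"]
    }
    rowMeans(diffs)
  })
  new_perm_result("node_shuffle", n_perm, null, observed, seed)
}

#' Second permutation test: breaking subject pairing
#'
#' Per permutation, each deprived scan is re-paired with a uniformly drawn
#' subject's reference scan (self-pairing allowed with probability 1/n); the
#' statistic is the mean within-subject kappa under the broken pairing,
#' compared to the observed correctly-paired mean. Nulls centered below the
#' observed value indicate that comparing graphs from different brains
#' inflates apparent disruption.
#'
#' @inheritParams test_node_shuffle
#' @return A `perm_test` object.
#' @export
test_pair_break <- function(metric_matrices, reference, condition,
                            n_perm = 10000, seed = 1L) {
  n_perm <- check_n_perm(n_perm)
  n_subj <- length(metric_matrices)
  if (n_subj < 3) stopf("test_pair_break: need at least 3 subjects")
  refs <- lapply(metric_matrices, function(mm) mm$values[, reference])
  conds <- lapply(metric_matrices, function(mm) mm$values[, condition])
  Ymat <- do.call(cbind, conds)
  # K[i, j]: kappa of subject j's deprived scan against subject i's reference
  K <- t(vapply(refs, function(r) slopes_vs_ref(r, Ymat), numeric(n_subj)))
  observed <- mean(diag(K))
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      sigma <- sample.int(n_subj)
      mean(K[cbind(seq_len(n_subj), sigma)])
    }, numeric(1))
  })
  new_perm_result("pair_break", n_perm, null, observed, seed)
}

#' Third permutation test: within-subject condition-label swaps
#'
#' Condition labels are randomly switched within each subject while
#' preserving subject pairing; the statistic is the cohort mean
#' within-subject kappa. Swapping the two conditions of a comparison reverses
#' which scan is the reference, so both directed slopes are precomputed per
#' subject and each permutation picks one per subject.
#'
#' @inheritParams test_node_shuffle
#' @return A `perm_test` object; `observed` is the correctly-labeled mean
#'   kappa.
#' @export
test_condition_shuffle <- function(metric_matrices, reference, condition,
                                   n_perm = 10000, seed = 1L) {
  n_perm <- check_n_perm(n_perm)
  n_subj <- length(metric_matrices)
  fwd <- numeric(n_subj)
  rev_ <- numeric(n_subj)
  for (s in seq_len(n_subj)) {
    mm <- metric_matrices[[s]]
    r <- mm$values[, reference]; cnd <- mm$values[, condition]
    fwd[s] <- slopes_vs_ref(r, cbind(cnd))
    rev_[s] <- slopes_vs_ref(cnd, cbind(r))
  }
  observed <- mean(fwd)
  null <- with_seed(seed, {
    swap <- matrix(stats::runif(n_perm * n_subj) < 0.5, n_perm, n_subj)
    (swap %*% rev_ + (!swap) %*% fwd) / n_subj
  })
  new_perm_result("condition_shuffle", n_perm, as.numeric(null), observed, seed)
}

#' Paired permutation comparison (sign flips)
#'
#' Null distribution of the mean difference `mean(b - a)` under random sign
#' flips of the within-pair differences.
#'
#' @param values_a,values_b Equal-length paired numeric vectors.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return A `perm_test` object. All-zero differences give p = 1 by
#'   convention.
#' @export
paired_permutation_compare <- function(values_a, values_b, n_perm = 10000, seed = 1L) {
  n_perm <- check_n_perm(n_perm)
  if (length(values_a) != length(values_b))
    stopf("paired_permutation_compare: vectors must have equal length")
  d <- values_b - values_a
  observed <- mean(d)
  if (all(d == 0)) {
    return(new_perm_result("paired_compare", n_perm, rep(0, n_perm), 0, seed,
                           tail = "two_tailed"))
  }
  null <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * length(d), replace = TRUE),
                    n_perm, length(d))
    as.numeric(signs %*% d) / length(d)
  })
  new_perm_result("paired_compare", n_perm, null, observed, seed,
                  tail = "two_tailed")
}

#' Unpaired permutation comparison (full shuffles)
#'
#' Null distribution of the difference in group means after pooling all
#' values and reassigning them to the two groups at random, ignoring subject
#' identity.
#'
#' @inheritParams paired_permutation_compare
#' @return A `perm_test` object.
#' @export
unpaired_permutation_compare <- function(values_a, values_b, n_perm = 10000, seed = 1L) {
  n_perm <- check_n_perm(n_perm)
  pool <- c(values_a, values_b)
  na <- length(values_a)
  observed <- mean(values_b) - mean(values_a)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      idx <- sample.int(length(pool), na)
      mean(pool[-idx]) - mean(pool[idx])
    }, numeric(1))
  })
  new_perm_result("unpaired_compare", n_perm, null, observed, seed,
                  tail = "two_tailed")
}
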