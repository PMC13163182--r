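# Covariate-constrained manifold learning.

test_that("geodesic distances reduce to Euclidean on a line and complete graphs", {
  x <- matrix(seq(0, 10, length.out = 12), ncol = 1)
  gd <- geodesic_distances(x, k = 2)
  expect_equal(gd$distances, as.matrix(dist(x)), ignore_attr = TRUE, tolerance = 1e-12)
  set.seed(1)
  y <- matrix(rnorm(10 * 3), 10)
  gd2 <- geodesic_distances(y, k = 9)
  expect_equal(gd2$distances, as.matrix(dist(y)), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("geodesics on a circle exceed chords and approximate arc length", {
  th <- seq(0, 2 * pi, length.out = 61)[-61]
  xy <- cbind(cos(th), sin(th))
  gd <- geodesic_distances(xy, k = 2)$distances
  chord <- as.matrix(dist(xy))
  expect_true(all(gd - chord >= -1e-12))
  # opposite points: arc length pi vs chord 2
  expect_equal(gd[1, 31], pi, tolerance = 0.02)
})

test_that("geodesic matrices are symmetric, zero-diagonal and metric", {
  set.seed(3)
  x <- matrix(rnorm(15 * 4), 15)
  d <- geodesic_distances(x, k = 4)$distances
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 15))
  for (i in 1:15) for (j in 1:15) {
    expect_true(all(d[i, j] <= d[i, ] + d[, j] + 1e-9))
  }
})

test_that("disconnected neighbor graphs escalate k with a warning", {
  set.seed(4)
  x <- rbind(matrix(rnorm(10, 0, 0.1), 5), matrix(rnorm(10, 50, 0.1), 5))
  gd <- NULL
  warns <- testthat::capture_warnings(gd <- geodesic_distances(x, k = 2))
  expect_true(any(grepl("escalating", warns)))
  expect_true(all(is.finite(gd$distances)))
  expect_gt(gd$k, 2)
})

test_that("the first CCML coordinate equals alpha times the covariate exactly", {
  set.seed(5)
  feat <- matrix(rnorm(20 * 8), 20)
  cov <- rnorm(20)
  emb <- ccml_fit(feat, cov, dim = 2, k = 5, seed = 1)
  expect_identical(unname(emb$coordinates[, 1]), emb$alpha * cov)
  expect_gte(emb$stress, 0)
})

test_that("stress never exceeds its initialization value", {
  set.seed(6)
  feat <- matrix(rnorm(24 * 6), 24)
  cov <- rowMeans(feat) + rnorm(24, 0, 0.1)
  emb <- ccml_fit(feat, cov, dim = 3, k = 6, seed = 2)
  expect_lte(emb$stress, emb$stress_initial)
})

test_that("CCML with the first ISOMAP coordinate as covariate matches ISOMAP stress", {
  set.seed(7)
  feat <- rbind(matrix(rnorm(15 * 10, 0), 15), matrix(rnorm(15 * 10, 2), 15))
  iso <- isomap_fit(feat, dim = 2, k = 6)
  emb <- ccml_fit(feat, iso$coordinates[, 1], dim = 2, k = 6, seed = 1)
  expect_lt(emb$stress / iso$stress, 1.05)
})

test_that("group ordering along the constrained axis follows the covariate", {
  set.seed(8)
  n <- 20
  kapA <- rnorm(n, -0.6, 0.08)
  kapB <- rnorm(n, -0.2, 0.08)
  feat <- rbind(matrix(rnorm(n * 12, 0), n), matrix(rnorm(n * 12, 1), n))
  emb <- ccml_fit(feat, c(kapA, kapB), dim = 2, k = 6, seed = 3)
  coordA <- mean(emb$coordinates[1:n, 1])
  coordB <- mean(emb$coordinates[(n + 1):(2 * n), 1])
  expect_equal(sign(coordA - coordB), sign(emb$alpha * (mean(kapA) - mean(kapB))))
})

test_that("constant covariates fall back to classical ISOMAP with a warning", {
  set.seed(9)
  feat <- matrix(rnorm(12 * 5), 12)
  expect_warning(emb <- ccml_fit(feat, rep(1, 12), dim = 2, k = 4, seed = 1),
                 "unidentifiable")
  expect_true(is.na(emb$alpha))
  expect_equal(emb$method, "isomap")
})

test_that("degenerate all-zero feature columns are refused unless overridden", {
  set.seed(10)
  feat <- cbind(matrix(rnorm(12 * 4), 12), 0)
  cov <- rnorm(12)
  expect_error(ccml_fit(feat, cov, seed = 1), "constant zero")
  emb <- ccml_fit(feat, cov, seed = 1, allow_degenerate_features = TRUE)
  expect_s3_class(emb, "ccml_embedding")
})

test_that("the centroid-distance test is saturated for well-separated clouds", {
  set.seed(11)
  Y <- rbind(matrix(rnorm(20 * 2, 0, 0.5), 20), matrix(rnorm(20 * 2, 10, 0.5), 20))
  lab <- rep(c("A", "B"), each = 20)
  r <- centroid_distance_test(Y, lab, n_perm = 1000, seed = 2)
  expect_equal(r$p_value, 1 / 1001, tolerance = 1e-12)
  expect_gt(r$observed, 10)
  expect_error(centroid_distance_test(Y, rep(c("A", "B", "C"), length.out = 40), 100, 1),
               "2 label groups")
  expect_error(centroid_distance_test(Y[1:4, ], c("A", "A", "A", "B"), 100, 1),
               "at least 2")
})

test_that("centroid-distance p-values are roughly uniform for a single cloud", {
  set.seed(12)
  ps <- replicate(40, {
    Y <- matrix(rnorm(24 * 2), 24)
    centroid_distance_test(Y, rep(c("A", "B"), 12), n_perm = 200,
                           seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(mean(ps > 0.5), 0.25)   # not systematically significant
  expect_lt(mean(ps < 0.05), 0.2)
})

test_that("leave-one-out distances are stable for separated groups and flag outliers", {
  set.seed(13)
  n <- 10
  feat <- rbind(matrix(rnorm(n * 6, 0, 0.3), n), matrix(rnorm(n * 6, 3, 0.3), n))
  cov <- c(rnorm(n, -0.6, 0.05), rnorm(n, -0.2, 0.05))
  lab <- rep(c("T", "C"), each = n)
  # k = 5 on two tight 10-record clusters escalates k to connect the graph;
  # that is expected behavior here, not the property under test
  loo <- suppressWarnings(
    loo_centroid_stability(feat, cov, lab, mode = "fixed_embedding", k = 5, seed = 1))
  expect_length(loo$distances, 2 * n)
  expect_true(all(abs(loo$distances - loo$full_distance) / loo$full_distance < 0.1))
  # an extreme outlier moves the distance most when removed
  feat_out <- feat
  feat_out[1, ] <- feat_out[1, ] + 25
  cov_out <- cov; cov_out[1] <- -3
  loo2 <- suppressWarnings(
    loo_centroid_stability(feat_out, cov_out, lab, mode = "fixed_embedding",
                           k = 5, seed = 1))
  shifts <- abs(loo2$distances - loo2$full_distance)
  expect_equal(unname(which.max(shifts)), 1)
  # refit mode re-optimizes and still returns one distance per record
  loo3 <- suppressWarnings(
    loo_centroid_stability(feat, cov, lab, mode = "refit", k = 5, seed = 1))
  expect_length(loo3$distances, 2 * n)
  expect_true(all(is.finite(loo3$distances)))
})
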