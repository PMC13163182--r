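# Within-subject hub disruption index: exact slopes, alignment, tables.

test_that("kappa is exact on affine transforms", {
  set.seed(1)
  m <- runif(89, 0, 1)
  expect_equal(kappa_within(m, m)$kappa, 0, tolerance = 1e-12)
  f15 <- kappa_within(m, 1.5 * m)
  expect_equal(f15$kappa, 0.5, tolerance = 1e-12)
  expect_lt(max(abs(f15$residuals)), 1e-12)
  f <- kappa_within(m, 0.2 * m + 0.1)
  expect_equal(f$kappa, -0.8, tolerance = 1e-12)
  expect_equal(f$intercept, 0.1, tolerance = 1e-12)
  # through-origin flag matches the equation literally on proportional data
  f0 <- kappa_within(m, 0.6 * m, fit_intercept = FALSE)
  expect_equal(f0$kappa, -0.4, tolerance = 1e-12)
  expect_equal(f0$intercept, 0)
})

test_that("kappa is invariant to common rescaling of both conditions", {
  set.seed(2)
  m_ref <- runif(50)
  m_cond <- 0.7 * m_ref + rnorm(50, 0, 0.05)
  k1 <- kappa_within(m_ref, m_cond)$kappa
  k2 <- kappa_within(10 * m_ref, 10 * m_cond)$kappa
  expect_equal(k1, k2, tolerance = 1e-12)
})

test_that("residuals average to zero when an intercept is fitted", {
  set.seed(3)
  m_ref <- runif(30)
  f <- kappa_within(m_ref, 0.5 * m_ref + rnorm(30, 0, 0.1))
  expect_lt(abs(mean(f$residuals)), 1e-10)
})

test_that("degenerate or misaligned inputs raise explicit errors", {
  expect_error(kappa_within(rep(1, 10), runif(10)), "zero variance")
  expect_error(kappa_within(runif(5), runif(6)), "length")
  expect_error(kappa_within(c(a = 1, b = 2, c = 3), c(a = 1, b = 2, d = 3)), "node ids")
})

test_that("named vectors are aligned by node id, not position", {
  m_ref <- c(a = 0.1, b = 0.5, c = 0.9, d = 0.3)
  m_cond <- 1.5 * m_ref
  shuffled <- m_cond[c("d", "a", "c", "b")]
  expect_equal(kappa_within(m_ref, shuffled)$kappa, 0.5, tolerance = 1e-12)
})

test_that("group-level kappa matches the within-subject fit for one subject", {
  set.seed(4)
  m_ref <- runif(40)
  m_cond <- 0.8 * m_ref + rnorm(40, 0, 0.02)
  expect_equal(kappa_group(m_cond, m_ref)$kappa,
               kappa_within(m_ref, m_cond)$kappa, tolerance = 1e-12)
  expect_equal(kappa_group(m_ref, m_ref)$kappa, 0, tolerance = 1e-12)
  expect_equal(kappa_group(m_ref, m_ref)$mode, "group_level")
})

test_that("hdi_table produces one fit per subject, comparison and metric", {
  set.seed(5)
  mats <- lapply(1:4, function(s) {
    base <- runif(20)
    nodal_metric_matrix(cbind(RW = base, TSD = 0.5 * base + 0.01,
                              CSR = 0.8 * base),
                        sprintf("n%02d", 1:20), c("RW", "TSD", "CSR"),
                        sprintf("S%02d", s), "degree")
  })
  kt <- hdi_table(mats)
  expect_s3_class(kt, "kappa_table")
  expect_equal(nrow(kt), 4 * 3)
  expect_setequal(unique(kt$comparison), c("TSD vs RW", "CSR vs RW", "CSR vs TSD"))
  expect_equal(kt$kappa[kt$comparison == "TSD vs RW"], rep(-0.5, 4), tolerance = 1e-12)
  sm <- summary(kt)
  expect_equal(sm$mean_kappa[sm$comparison == "CSR vs RW"], -0.2, tolerance = 1e-12)
  # both deprived-vs-reference contrasts are uniformly negative; the direct
  # CSR-vs-TSD contrast is positive for this fixture (CSR closer to baseline)
  expect_equal(sm$frac_negative[sm$comparison != "CSR vs TSD"], rep(1, 2))
  expect_equal(sm$frac_negative[sm$comparison == "CSR vs TSD"], 0)
})

test_that("identical conditions give a kappa table of exact zeros", {
  base <- runif(15)
  mm <- nodal_metric_matrix(cbind(RW = base, TSD = base), sprintf("n%02d", 1:15),
                            c("RW", "TSD"), "S01", "closeness")
  kt <- hdi_table(list(mm))
  expect_equal(kt$kappa, 0, tolerance = 1e-12)
})

test_that("subjects missing a condition are excluded with a warning", {
  base <- runif(10)
  full <- nodal_metric_matrix(cbind(RW = base, TSD = 0.5 * base),
                              sprintf("n%02d", 1:10), c("RW", "TSD"), "S01", "degree")
  partial <- nodal_metric_matrix(cbind(RW = base), sprintf("n%02d", 1:10),
                                 c("RW"), "S02", "degree")
  expect_warning(kt <- hdi_table(list(full, partial), comparisons = list(c("TSD", "RW"))),
                 "S02")
  expect_equal(nrow(kt), 1)
  expect_equal(kt$subject_id, "S01")
})

test_that("node-label shuffles push kappa toward -1 on heterogeneous degrees", {
  spec <- cohort_spec(n_subjects = 2, seed = 17)
  sigma <- hdinet:::subject_correlation(spec, 55)
  d <- unname(igraph::degree(build_graph(sigma, 400)$graph))
  set.seed(99)
  kaps <- replicate(300, kappa_within(d, d[sample.int(length(d))])$kappa)
  expect_lt(abs(mean(kaps) + 1), 0.1)
})

test_that("the within-subject reference recovers implanted disruption more accurately than the group reference", {
  spec <- cohort_spec(n_subjects = 10, kappa_targets = c(RW = 0, TSD = -0.5, CSR = -0.3),
                      seed = 23)
  cg <- quiet_cohort(generate_cohort_graphs(spec))
  mm <- cohort_metric_matrices(cg, "degree")
  refs <- lapply(mm, function(m) m$values[, "RW"])
  err_w <- err_g <- numeric(length(mm))
  for (s in seq_along(mm)) {
    loo_mean <- Reduce(`+`, refs[-s]) / (length(refs) - 1)
    err_w[s] <- abs(kappa_within(refs[[s]], mm[[s]]$values[, "TSD"])$kappa + 0.5)
    err_g[s] <- abs(kappa_group(mm[[s]]$values[, "TSD"], loo_mean)$kappa + 0.5)
  }
  expect_lt(mean(err_w), mean(err_g))
})
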