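# Within-subject Hub Disruption Index.
#
# For a nodal metric m, the index kappa is the OLS slope of the per-node
# change (condition minus reference) regressed on the reference value:
#
#   m_i(cond) - m_i(ref) = kappa * m_i(ref) + eps_i
#
# kappa ~ 0 means preserved topology; kappa < 0 means former hubs lost
# centrality while peripheral nodes gained it. The within-subject variant
# uses each subject's own reference scan as the regressor; the group-level
# variant uses the group-averaged reference metric instead.

align_by_node <- function(m_ref, m_cond) {
  if (length(m_ref) != length(m_cond))
    stopf("kappa: metric vectors differ in length (%d vs %d)", length(m_ref), length(m_cond))
  if (length(m_ref) < 3) stopf("kappa: need at least 3 nodes")
  if (!is.null(names(m_ref)) && !is.null(names(m_cond))) {
    if (!setequal(names(m_ref), names(m_cond)))
      stopf("kappa: node ids of the two vectors do not match")
    m_cond <- m_cond[names(m_ref)]
  }
  list(ref = unname(m_ref), cond = unname(m_cond),
       ids = if (is.null(names(m_ref))) NULL else names(m_ref))
}

kappa_fit <- function(m_ref, m_cond, fit_intercept, mode,
                      subject_id = NA_character_, comparison = NA_character_,
                      metric = NA_character_) {
  al <- align_by_node(m_ref, m_cond)
  x <- al$ref
  y <- al$cond - al$ref
  if (stats::sd(x) == 0) stopf("kappa: reference metric has zero variance; slope undefined")
  X <- if (fit_intercept) cbind(intercept = 1, slope = x) else cbind(slope = x)
  fit <- stats::lm.fit(X, y)
  kap <- unname(fit$coefficients[["slope"]])
  intercept <- if (fit_intercept) unname(fit$coefficients[["intercept"]]) else 0
  res <- unname(fit$residuals)
  tss <- if (fit_intercept) sum((y - mean(y))^2) else sum(y^2)
  r2 <- if (tss == 0) 1 else 1 - sum(res^2) / tss
  structure(list(
    subject_id = subject_id, comparison = comparison, metric = metric,
    kappa = kap, intercept = intercept, residuals = stats::setNames(res, al$ids),
    r_squared = r2, n_nodes = length(x), fit_intercept = fit_intercept,
    mode = mode
  ), class = "kappa_fit")
}

#' @export
print.kappa_fit <- function(x, ...) {
  cat(sprintf("kappa fit (%s): kappa = %.4f, intercept = %.4f, R2 = %.3f, N = %d\n",
              x$mode, x$kappa, x$intercept, x$r_squared, x$n_nodes))
  invisible(x)
}

#' Within-subject hub disruption index
#'
#' @param m_ref Per-node metric values in the reference condition.
#' @param m_cond Per-node metric values in the condition of interest. When
#'   both vectors are named, alignment is by node id (a mismatch is an
#'   error); unnamed vectors are taken as already aligned.
#' @param fit_intercept Fit an intercept (default TRUE); FALSE forces the
#'   regression through the origin, matching the index equation literally.
#' @param subject_id,comparison,metric Optional identifiers carried into the
#'   result.
#' @return Object of class `kappa_fit` with elements `kappa`, `intercept`,
#'   `residuals`, `r_squared`, `n_nodes`, `mode`.
#' @export
kappa_within <- function(m_ref, m_cond, fit_intercept = TRUE,
                         subject_id = NA_character_, comparison = NA_character_,
                         metric = NA_character_) {
  kappa_fit(m_ref, m_cond, fit_intercept, mode = "within_subject",
            subject_id = subject_id, comparison = comparison, metric = metric)
}

#' Group-level hub disruption index
#'
#' Same regression as [kappa_within()] but with the group-averaged reference
#' metric as the regressor — the classical cross-sectional formulation, kept
#' for the node-shuffle permutation comparison.
#'
#' @param m_cond Per-node metric values in the condition of interest.
#' @param group_ref_mean Per-node reference metric averaged over subjects.
#' @inheritParams kappa_within
#' @return Object of class `kappa_fit` with `mode = "group_level"`.
#' @export
kappa_group <- function(m_cond, group_ref_mean, fit_intercept = TRUE,
                        subject_id = NA_character_, comparison = NA_character_,
                        metric = NA_character_) {
  kappa_fit(group_ref_mean, m_cond, fit_intercept, mode = "group_level",
            subject_id = subject_id, comparison = comparison, metric = metric)
}

#' Hub disruption index table over a cohort
#'
#' One kappa fit per subject, ordered condition comparison and metric.
#' Subjects missing a condition required by a comparison are excluded from
#' that comparison with a warning.
#'
#' @param metric_matrices List of [nodal_metric_matrix()] objects (possibly
#'   several metrics per subject).
#' @param comparisons List of `c(condition, reference)` character pairs;
#'   default: every later condition against every earlier one, in spec order
#'   (for RW/TSD/CSR: TSD vs RW, CSR vs RW, CSR vs TSD).
#' @param fit_intercept Passed to [kappa_within()].
#' @return Data frame of class `kappa_table` with columns `subject_id`,
#'   `comparison`, `condition`, `reference`, `metric`, `kappa`, `intercept`,
#'   `r_squared`, `n_nodes`.
#' @export
hdi_table <- function(metric_matrices, comparisons = NULL, fit_intercept = TRUE) {
  stopifnot(length(metric_matrices) > 0)
  conds <- metric_matrices[[1]]$condition_labels
  if (is.null(comparisons)) {
    comparisons <- list()
    for (j in seq_along(conds)) for (i in seq_len(j - 1)) {
      comparisons[[length(comparisons) + 1L]] <- c(conds[j], conds[i])
    }
  }
  rows <- list()
  for (mm in metric_matrices) {
    stopifnot(inherits(mm, "nodal_metric_matrix"))
    for (cmp in comparisons) {
      cond <- cmp[1]; ref <- cmp[2]
      if (!all(c(cond, ref) %in% mm$condition_labels)) {
        warnf("hdi_table: subject %s lacks condition %s or %s; excluded",
              mm$subject_id, cond, ref)
        next
      }
      label <- paste(cond, "vs", ref)
      fit <- kappa_within(mm$values[, ref], mm$values[, cond],
                          fit_intercept = fit_intercept,
                          subject_id = mm$subject_id, comparison = label,
                          metric = mm$metric)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = mm$subject_id, comparison = label,
        condition = cond, reference = ref, metric = mm$metric,
        kappa = fit$kappa, intercept = fit$intercept,
        r_squared = fit$r_squared, n_nodes = fit$n_nodes,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("kappa_table", "data.frame")
  out
}

#' Group mean kappa per comparison and metric
#'
#' @param object A `kappa_table`.
#' @param ... Unused.
#' @return Data frame with `comparison`, `metric`, `mean_kappa`, `sd_kappa`,
#'   `n_subjects`, `frac_negative`.
#' @export
summary.kappa_table <- function(object, ...) {
  agg <- stats::aggregate(kappa ~ comparison + metric, data = object,
                          FUN = function(k) c(mean = mean(k), sd = stats::sd(k),
                                              n = length(k), neg = mean(k < 0)))
  data.frame(comparison = agg$comparison, metric = agg$metric,
             mean_kappa = agg$kappa[, "mean"], sd_kappa = agg$kappa[, "sd"],
             n_subjects = agg$kappa[, "n"], frac_negative = agg$kappa[, "neg"],
             stringsAsFactors = FALSE)
}
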