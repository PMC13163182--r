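# Multiple-comparison control, effect sizes and result aggregation.

#' Benjamini-Hochberg false discovery rate control
#'
#' Standard linear step-up procedure: with ordered p-values p_(1) <= ... <=
#' p_(m), reject the smallest k hypotheses where k is the largest index with
#' p_(k) <= k q / m. Adjusted p-values come from [stats::p.adjust()]
#' (method "BH"); a hypothesis is rejected iff its adjusted value is <= q.
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @param q FDR level (conventionally 0.05 for global-metric families, 0.1
#'   for nodal families).
#' @return List with `p_adjusted` and logical `rejected`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) return(list(p_adjusted = numeric(0), rejected = logical(0)))
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1))
    stopf("bh_fdr: p-values must lie in (0, 1]")
  if (!is_number(q) || q <= 0 || q >= 1) stopf("bh_fdr: q must be in (0, 1)")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, rejected = adj <= q)
}

#' Cohen's d of an observed statistic against a permutation null
#'
#' @param observed Observed statistic.
#' @param null_distribution Numeric vector of permuted statistics.
#' @return `(observed - mean(null)) / sd(null)`.
#' @export
cohens_d_null <- function(observed, null_distribution) {
  if (!is_number(observed)) stopf("cohens_d_null: observed must be a finite number")
  s <- stats::sd(null_distribution)
  if (!is.finite(s) || s == 0) stopf("cohens_d_null: null distribution has zero variance; d undefined")
  (observed - mean(null_distribution)) / s
}

#' Aggregate test results with per-family FDR control
#'
#' Combines result tables into one tidy table, applying Benjamini-Hochberg
#' control within each family at that family's q level.
#'
#' @param families Named list of data frames, each with columns `unit` (node
#'   id or "GLOBAL"), `comparison`, `statistic`, `p_raw`.
#' @param q Named numeric vector of FDR levels per family; unnamed families
#'   default to `q_default`.
#' @param q_default Default FDR level (0.05).
#' @param config Optional list recorded verbatim in the run manifest
#'   (seeds, thresholds, atlas, edge budgets).
#' @return List with `results` (one data frame: `family`, `unit`,
#'   `comparison`, `statistic`, `p_raw`, `p_adjusted`, `significant_at_q`,
#'   `q`) and `manifest`.
#' @export
aggregate_results <- function(families, q = c(global = 0.05, nodal = 0.1),
                              q_default = 0.05, config = list()) {
  stopifnot(is.list(families))
  if (length(families) == 0) {
    empty <- data.frame(family = character(0), unit = character(0),
                        comparison = character(0), statistic = numeric(0),
                        p_raw = numeric(0), p_adjusted = numeric(0),
                        significant_at_q = logical(0), q = numeric(0),
                        stringsAsFactors = FALSE)
    return(list(results = empty,
                manifest = run_manifest(config, families = character(0))))
  }
  if (is.null(names(families)) || any(names(families) == ""))
    stopf("aggregate_results: every family must be named")
  out <- lapply(names(families), function(fam) {
    tab <- families[[fam]]
    need <- c("unit", "comparison", "statistic", "p_raw")
    if (!all(need %in% names(tab)))
      stopf("aggregate_results: family '%s' lacks column(s) %s", fam,
            paste(setdiff(need, names(tab)), collapse = ", "))
    key <- paste(tab$unit, tab$comparison)
    if (anyDuplicated(key))
      stopf("aggregate_results: duplicate (unit, comparison) keys in family '%s'", fam)
    qf <- if (fam %in% names(q)) q[[fam]] else q_default
    fdr <- bh_fdr(tab$p_raw, qf)
    data.frame(family = fam, unit = tab$unit, comparison = tab$comparison,
               statistic = tab$statistic, p_raw = tab$p_raw,
               p_adjusted = fdr$p_adjusted, significant_at_q = fdr$rejected,
               q = qf, stringsAsFactors = FALSE)
  })
  list(results = do.call(rbind, out),
       manifest = run_manifest(config, families = names(families)))
}

run_manifest <- function(config, families) {
  list(
    package = "hdinet",
    version = as.character(utils::packageVersion("hdinet")),
    format_version = 1L,
    families = families,
    config = config,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}
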