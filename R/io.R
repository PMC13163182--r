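# Readers and writers for the pipeline's on-disk formats.
#
# Time series: TSV, first column region_id, remaining columns
# volume_0001... ; one file per subject x condition, with a JSON sidecar
# (tr_seconds, condition, subject, seed). Correlation matrices: CSV with a
# region_id header row/column plus a JSON sidecar (scale, band_hz,
# effective_df). Edge lists: TSV node_a/node_b/weight. Node tables and
# kappa tables: CSV. Round trips are identity up to float formatting at
# 1e-12.

sidecar_path <- function(path) paste0(sub("\\.[^.]+$", "", path), ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write a regional time-series set as TSV (+ JSON sidecar)
#'
#' @param ts A `regional_ts` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "regional_ts"))
  df <- data.frame(region_id = ts$region_ids,
                   ts$values, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("region_id", sprintf("volume_%04d", seq_len(ncol(ts$values))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  write_sidecar(path, list(subject_id = ts$subject_id, condition = ts$condition,
                           tr_seconds = ts$tr_seconds, n_regions = nrow(ts$values),
                           n_volumes = ncol(ts$values), format_version = 1L))
  invisible(path)
}

#' Read a regional time-series TSV written by [write_timeseries_tsv()]
#'
#' @param path TSV path (JSON sidecar read automatically when present).
#' @param tr_seconds Sampling interval; overridden by the sidecar.
#' @return A `regional_ts` object.
#' @export
read_timeseries_tsv <- function(path, tr_seconds = NA_real_) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "region_id") stopf("read_timeseries_tsv: first column must be 'region_id' (got '%s')", names(df)[1])
  ids <- as.character(df$region_id)
  if (anyDuplicated(ids)) stopf("read_timeseries_tsv: duplicate region ids")
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(vals)) stopf("read_timeseries_tsv: missing values in series")
  rownames(vals) <- ids
  meta <- read_sidecar(path)
  structure(list(
    subject_id = meta$subject_id %||% NA_character_,
    condition = meta$condition %||% NA_character_,
    values = vals, region_ids = ids,
    tr_seconds = meta$tr_seconds %||% tr_seconds
  ), class = "regional_ts")
}

#' Write a correlation matrix as CSV (+ JSON sidecar)
#'
#' @param cm A `wavelet_cor` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(cm, path) {
  stopifnot(inherits(cm, "wavelet_cor"))
  df <- data.frame(region_id = cm$region_ids, cm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  write_sidecar(path, list(scale = cm$scale, band_hz = as.numeric(cm$band_hz),
                           effective_df = cm$effective_df,
                           subject_id = cm$subject_id, condition = cm$condition,
                           filter = cm$filter, format_version = 1L))
  invisible(path)
}

#' Read a correlation CSV written by [write_correlation_csv()]
#'
#' @param path CSV path.
#' @return A `wavelet_cor` object.
#' @export
read_correlation_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "region_id") stopf("read_correlation_csv: first column must be 'region_id'")
  ids <- as.character(df$region_id)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(m), ids)) stopf("read_correlation_csv: header region ids do not match the region_id column")
  dimnames(m) <- list(ids, ids)
  meta <- read_sidecar(path)
  structure(list(
    values = m, scale = meta$scale %||% NA_integer_,
    band_hz = stats::setNames(meta$band_hz %||% c(NA_real_, NA_real_), c("low", "high")),
    effective_df = meta$effective_df %||% NA_integer_,
    n_coefficients = NA_integer_, region_ids = ids,
    subject_id = meta$subject_id %||% NA_character_,
    condition = meta$condition %||% NA_character_,
    filter = meta$filter %||% NA_character_, flagged_regions = character(0)
  ), class = "wavelet_cor")
}

#' Write a brain graph's edge list as TSV
#'
#' @param g A `brain_graph`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- graph_edges(g)
  utils::write.table(el, path, sep = "\t", row.names = FALSE, quote = FALSE)
  write_sidecar(path, list(subject_id = g$subject_id, condition = g$condition,
                           edge_budget = g$edge_budget,
                           n_nodes = length(g$node_ids),
                           node_ids = g$node_ids, format_version = 1L))
  invisible(path)
}

#' Read an edge-list TSV written by [write_edge_list()]
#'
#' @param path TSV path.
#' @param node_table Optional node table (data frame with `region_id`) for a
#'   referential-integrity check: edges naming unknown nodes are an error.
#' @return A `brain_graph`.
#' @export
read_edge_list <- function(path, node_table = NULL) {
  el <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("node_a", "node_b")
  if (!all(need %in% names(el))) stopf("read_edge_list: missing column(s) %s",
                                       paste(setdiff(need, names(el)), collapse = ", "))
  meta <- read_sidecar(path)
  ids <- meta$node_ids %||% sort(unique(c(el$node_a, el$node_b)))
  if (!is.null(node_table)) {
    if (!"region_id" %in% names(node_table)) stopf("read_edge_list: node table lacks 'region_id'")
    unknown <- setdiff(unique(c(el$node_a, el$node_b)), node_table$region_id)
    if (length(unknown)) stopf("read_edge_list: edge list references node(s) absent from the node table: %s",
                               paste(utils::head(unknown, 5), collapse = ", "))
  }
  g <- igraph::make_empty_graph(length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  g <- igraph::add_edges(g, t(cbind(match(el$node_a, ids), match(el$node_b, ids))))
  if ("weight" %in% names(el)) igraph::E(g)$weight <- el$weight
  new_brain_graph(g, ids, meta$edge_budget %||% nrow(el),
                  meta$subject_id %||% NA_character_,
                  meta$condition %||% NA_character_)
}

node_table_columns <- c("region_id", "region_name", "mni_x", "mni_y", "mni_z", "network")

#' Read a node table (region_id, region_name, MNI centroid, network label)
#'
#' @param path CSV path.
#' @return Data frame with the validated schema; MNI coordinates are in
#'   millimeters.
#' @export
read_node_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(node_table_columns, names(df))
  if (length(missing_cols)) stopf("read_node_table: missing column(s): %s",
                                  paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$region_id)) stopf("read_node_table: region_id values must be unique")
  df
}

#' The bundled 89-region node table
#'
#' The modified-AAL-sized parcellation used by the package's examples: 19
#' regions carry published MNI centroids; the remaining 70 rows are
#' synthetic placeholders (generic names, interpolated coordinates, network
#' label "unassigned") standing in for the rest of the parcellation, which
#' is why the fixture file is named `aal89_nodes_synthetic.csv`.
#'
#' @return Data frame with 89 rows and the node-table schema.
#' @export
aal89_nodes <- function() {
  read_node_table(system.file("extdata", "aal89_nodes_synthetic.csv",
                              package = "hdinet", mustWork = TRUE))
}

#' Generate a synthetic node table of arbitrary size
#'
#' For robustness-style runs at other parcellation sizes (e.g. 391 regions):
#' entirely synthetic names and coordinates, generated in code rather than
#' shipped.
#'
#' @param n_regions Number of rows.
#' @param seed RNG seed for the synthetic coordinates.
#' @return Data frame with the node-table schema.
#' @export
synthetic_node_table <- function(n_regions = 391, seed = 1L) {
  coords <- with_seed(seed, matrix(stats::runif(n_regions * 3, -70, 70), ncol = 3))
  data.frame(
    region_id = sprintf("R%03d", seq_len(n_regions)),
    region_name = sprintf("Synthetic Region %03d", seq_len(n_regions)),
    mni_x = round(coords[, 1], 1), mni_y = round(coords[, 2], 1),
    mni_z = round(coords[, 3], 1),
    network = "unassigned", stringsAsFactors = FALSE
  )
}

#' Write / read a kappa table as CSV
#'
#' @param x A `kappa_table` (see [hdi_table()]).
#' @param path CSV path.
#' @return `path` (write) or the `kappa_table` (read).
#' @export
write_kappa_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kappa_table
#' @export
read_kappa_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "comparison", "metric", "kappa")
  if (!all(need %in% names(out))) stopf("read_kappa_table: missing column(s) %s",
                                        paste(setdiff(need, names(out)), collapse = ", "))
  class(out) <- c("kappa_table", "data.frame")
  out
}

#' Write a run manifest (or any summary list) as JSON
#'
#' @param x List to serialize.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export Fig-2-style scatter data for a kappa fit
#'
#' Per-node `(m_ref, m_cond - m_ref)` pairs, the coordinates of the
#' hub-disruption regression scatter plot.
#'
#' @param m_ref,m_cond Aligned per-node metric vectors.
#' @return Data frame with `node_id`, `m_ref`, `delta`.
#' @export
kappa_scatter_data <- function(m_ref, m_cond) {
  al <- align_by_node(m_ref, m_cond)
  data.frame(node_id = al$ids %||% seq_along(al$ref),
             m_ref = al$ref, delta = al$cond - al$ref,
             stringsAsFactors = FALSE)
}
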