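#' Read a dense expression matrix (CSV/TSV)
#'
#' Dialect: first column holds cell identifiers, remaining column names are
#' gene symbols, one row per cell. Separator is inferred from the file
#' extension (`.csv` comma, otherwise tab).
#'
#' @param path file path.
#' @param cell_type_label cell type label to attach.
#' @return An [expression_matrix()].
#' @export
read_expression_dense <- function(path, cell_type_label) {
  dt <- data.table::fread(path, header = TRUE,
                          sep = if (grepl("\\.csv$", path)) "," else "\t")
  cells <- as.character(dt[[1]])
  vals <- as.matrix(dt[, -1, with = FALSE])
  expression_matrix(vals, gene_ids = colnames(vals), cell_ids = cells,
                    cell_type_label = cell_type_label)
}

#' Read a sparse expression matrix (MatrixMarket + sidecar lists)
#'
#' Expects an `.mtx` file with genes in rows and cells in columns (the usual
#' single-cell convention), a gene list and a barcode list, one symbol per
#' line.
#'
#' @param mtx_path path to the MatrixMarket file.
#' @param genes_path path to the gene list.
#' @param barcodes_path path to the cell barcode list.
#' @param cell_type_label cell type label to attach.
#' @return An [expression_matrix()] (cells x genes, dense).
#' @export
read_expression_mtx <- function(mtx_path, genes_path, barcodes_path,
                                cell_type_label) {
  m <- Matrix::readMM(mtx_path)
  genes <- readLines(genes_path)
  genes <- genes[nzchar(genes)]
  cells <- readLines(barcodes_path)
  cells <- cells[nzchar(cells)]
  if (nrow(m) != length(genes))
    stop("MTX row count (", nrow(m), ") != gene list length (",
         length(genes), ")")
  if (ncol(m) != length(cells))
    stop("MTX column count (", ncol(m), ") != barcode list length (",
         length(cells), ")")
  expression_matrix(t(as.matrix(m)), gene_ids = genes, cell_ids = cells,
                    cell_type_label = cell_type_label)
}

#' Write an expression matrix in the dense dialect
#' @param m an [expression_matrix()].
#' @param path output path (`.csv` comma-separated, otherwise tab).
#' @export
write_expression_dense <- function(m, path) {
  stopifnot(inherits(m, "expression_matrix"))
  dt <- data.table::data.table(cell_id = m$cell_ids)
  dt <- cbind(dt, data.table::as.data.table(m$values))
  data.table::fwrite(dt, path,
                     sep = if (grepl("\\.csv$", path)) "," else "\t")
  invisible(path)
}

#' Read a transcription factor list (one symbol per line)
#' @param path file path.
#' @return Character vector of symbols (blank lines and `#` comments dropped).
#' @export
read_tf_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write the gene-universe manifest as JSON
#'
#' Records the selected genes, the regulator subset and the provenance of
#' each selection rule so a run can be audited.
#'
#' @param u a [gene_universe()].
#' @param path output path.
#' @param provenance optional named list describing filter settings.
#' @export
write_gene_universe <- function(u, path, provenance = list()) {
  stopifnot(inherits(u, "gene_universe"))
  jsonlite::write_json(
    list(genes = u$genes, regulators = u$regulators, provenance = provenance),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a gene-universe manifest written by [write_gene_universe()]
#' @param path JSON path.
#' @return A [gene_universe()].
#' @export
read_gene_universe <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gene_universe(x$genes, x$regulators)
}

#' Write one cell type's edge scores as TSV
#'
#' Dialect: header `regulator target score`, one row per non-missing edge.
#'
#' @param scores numeric vector aligned to `u`'s edges (NA = missing).
#' @param u an edge universe ([build_edge_universe()]).
#' @param path output path.
#' @param value_col column name for the value (`"score"` or `"std"`).
#' @export
write_edge_scores <- function(scores, u, path, value_col = "score") {
  stopifnot(length(scores) == u$n_edges)
  dt <- data.table::data.table(regulator = u$edges$regulator,
                               target = u$edges$target,
                               value = scores)
  data.table::setnames(dt, "value", value_col)
  dt <- dt[!is.na(dt[[value_col]])]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Import an external edge-score table and align it to the edge universe
#'
#' Adapter for third-party network inference output (e.g. GENIE3- or
#' PIDC-style rankings) saved as TSV with columns `regulator`, `target` and
#' a value column. Edges absent from the file become missing (NA); rows
#' whose genes are not in the universe are skipped with a message.
#'
#' @param path TSV path.
#' @param u an edge universe.
#' @param value_col name of the value column (default `"score"`).
#' @return Numeric vector of length `u$n_edges`, NA where missing.
#' @export
import_external_scores <- function(path, u, value_col = "score") {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  out <- rep(NA_real_, u$n_edges)
  if (nrow(dt) == 0) return(out)
  need <- c("regulator", "target", value_col)
  if (!all(need %in% names(dt)))
    stop("expected columns ", paste(need, collapse = ", "), " in ", path)
  if (anyNA(dt[[value_col]]) || !is.numeric(dt[[value_col]]))
    stop("malformed ", value_col, " column in ", path, " at line ",
         which(is.na(suppressWarnings(as.numeric(dt[[value_col]]))))[1] + 1L)
  key_file <- paste(dt$regulator, dt$target, sep = "->")
  if (anyDuplicated(key_file))
    stop("duplicate edge rows in ", path, ": ",
         key_file[which(duplicated(key_file))[1]])
  keys <- edge_keys(u)
  idx <- match(key_file, keys)
  unknown <- sum(is.na(idx))
  if (unknown > 0)
    message(unknown, " row(s) with genes outside the edge universe skipped")
  out[idx[!is.na(idx)]] <- dt[[value_col]][!is.na(idx)]
  out
}

#' Write a per-cell-type file manifest as JSON
#'
#' Maps each cell type label to its score/noise/expression file paths so a
#' multi-file run can be described by a single document.
#'
#' @param files named list: cell type label -> named list of paths.
#' @param path output JSON path.
#' @param extra optional named list merged in at the top level (seed,
#'   scorer, ...).
#' @export
write_manifest <- function(files, path, extra = list()) {
  jsonlite::write_json(c(list(cell_types = files), extra), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a manifest written by [write_manifest()]
#' @param path JSON path.
#' @return Named list with at least `cell_types`.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
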