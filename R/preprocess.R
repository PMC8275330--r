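#' Construct an expression matrix container
#'
#' A light container for one cell type's expression data: a cells x genes
#' numeric matrix plus identifier vectors. Values are expected to be
#' CPM-like (non-negative) before [log_transform()] and log-scale after.
#'
#' @param values numeric matrix, cells in rows, genes in columns.
#' @param gene_ids character vector of unique gene symbols (length = ncol).
#' @param cell_ids character vector of unique cell identifiers (length = nrow).
#' @param cell_type_label single string naming the cell type.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids, cell_ids, cell_type_label) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(gene_ids) != ncol(values))
    stop("gene_ids length (", length(gene_ids), ") != ncol(values) (",
         ncol(values), ")")
  if (length(cell_ids) != nrow(values))
    stop("cell_ids length (", length(cell_ids), ") != nrow(values) (",
         nrow(values), ")")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  if (!is.character(cell_type_label) || length(cell_type_label) != 1L)
    stop("cell_type_label must be a single string")
  dimnames(values) <- list(as.character(cell_ids), as.character(gene_ids))
  structure(
    list(values = values,
         gene_ids = as.character(gene_ids),
         cell_ids = as.character(cell_ids),
         cell_type_label = cell_type_label),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> cell type:", x$cell_type_label, "-",
      nrow(x$values), "cells x", ncol(x$values), "genes\n")
  invisible(x)
}

#' Log-transform CPM-like expression values
#'
#' Applies the elementwise transform `log(1 + x/100)` to CPM-scale counts.
#' The transform is monotone and invertible; [inverse_log_transform()]
#' recovers the original values.
#'
#' @param m an [expression_matrix()].
#' @return The transformed `expression_matrix` (ids unchanged).
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  neg <- which(m$values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative expression value at cell '%s', gene '%s': %g",
                 m$cell_ids[neg[1, 1]], m$gene_ids[neg[1, 2]],
                 m$values[neg[1, , drop = FALSE]]))
  }
  m$values <- log1p(m$values / 100)
  m
}

#' Invert the CPM log transform
#'
#' Computes `100 * (exp(x) - 1)`, clipped at zero to guard against tiny
#' negative values from floating point round-off.
#'
#' @param m an [expression_matrix()] on the transformed scale.
#' @return `expression_matrix` on the CPM scale.
#' @export
inverse_log_transform <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  m$values <- pmax(100 * expm1(m$values), 0)
  m
}

#' Filter genes by minimum expressed-cell fraction
#'
#' Keeps gene `g` if, in at least one cell type, the fraction of cells with
#' a nonzero value for `g` is at least `min_fraction`. A gene absent from a
#' cell type's matrix counts as all-zero there (a message is emitted).
#'
#' @param mats list of [expression_matrix()] objects, one per cell type.
#' @param min_fraction minimum expressed fraction in (0, 1]; default 0.10.
#' @return Character vector of retained gene symbols, in lexicographic order.
#' @export
filter_genes <- function(mats, min_fraction = 0.10) {
  if (length(mats) == 0) stop("empty matrix list")
  stopifnot(all(vapply(mats, inherits, logical(1), "expression_matrix")))
  if (!(min_fraction > 0 && min_fraction <= 1))
    stop("min_fraction must be in (0, 1]")
  all_genes <- sort(unique(unlist(lapply(mats, `[[`, "gene_ids"))))
  keep <- rep(FALSE, length(all_genes))
  names(keep) <- all_genes
  missing_any <- character(0)
  for (m in mats) {
    absent <- setdiff(all_genes, m$gene_ids)
    if (length(absent) > 0) missing_any <- union(missing_any, absent)
    frac <- colMeans(m$values > 0)
    ok <- names(frac)[frac >= min_fraction]
    keep[ok] <- TRUE
  }
  if (length(missing_any) > 0)
    message(length(missing_any),
            " gene(s) absent from at least one cell type; treated as zero there")
  all_genes[keep]
}

#' Dispersion statistic for highly-variable-gene ranking
#'
#' Fano factor (variance / mean) of transformed expression, either pooled
#' across all cells of all cell types or the per-cell-type maximum.
#'
#' @param mats list of [expression_matrix()] objects (transformed scale).
#' @param genes gene symbols to score.
#' @param per_type if `TRUE`, return the max Fano factor over cell types
#'   instead of the pooled statistic.
#' @return Named numeric vector of dispersions (0 for constant or absent
#'   genes).
#' @export
gene_dispersion <- function(mats, genes, per_type = FALSE) {
  disp_one <- function(v) {
    mu <- mean(v)
    if (mu <= 0) return(0)
    stats::var(v) / mu
  }
  if (per_type) {
    d <- vapply(genes, function(g) {
      vals <- vapply(mats, function(m) {
        if (!g %in% m$gene_ids) return(0)
        disp_one(m$values[, g])
      }, numeric(1))
      max(vals)
    }, numeric(1))
  } else {
    d <- vapply(genes, function(g) {
      pooled <- unlist(lapply(mats, function(m) {
        if (!g %in% m$gene_ids) return(NULL)
        m$values[, g]
      }))
      if (is.null(pooled) || length(pooled) < 2) return(0)
      disp_one(pooled)
    }, numeric(1))
  }
  d[!is.finite(d)] <- 0
  d
}

#' Select the gene universe: transcription factors plus top-dispersion genes
#'
#' The working gene set is the union of (i) the supplied TF list restricted
#' to the filtered genes and (ii) the `top_n_dispersion` genes with highest
#' dispersion. Ties in dispersion are broken lexicographically by symbol.
#'
#' @param mats list of filtered, transformed [expression_matrix()] objects.
#' @param tf_list character vector of regulator (TF) symbols.
#' @param top_n_dispersion number of high-dispersion genes to add
#'   (default 1000).
#' @param genes optional pre-filtered gene set; defaults to
#'   `filter_genes(mats)`.
#' @param per_type_dispersion compute dispersion per cell type (max) instead
#'   of pooled.
#' @return A `gene_universe`: list with `genes` (ordered set) and
#'   `regulators` (subset flagged as TFs).
#' @export
select_gene_universe <- function(mats, tf_list, top_n_dispersion = 1000,
                                 genes = NULL, per_type_dispersion = FALSE) {
  if (length(tf_list) == 0) stop("tf_list is empty: no regulators available")
  if (is.null(genes)) genes <- filter_genes(mats)
  tfs <- sort(intersect(unique(tf_list), genes))
  if (length(tfs) == 0)
    stop("no transcription factor from tf_list survives gene filtering")
  top <- character(0)
  if (top_n_dispersion > 0) {
    d <- gene_dispersion(mats, genes, per_type = per_type_dispersion)
    ord <- order(-d, names(d))
    top <- names(d)[ord][seq_len(min(top_n_dispersion, length(d)))]
  }
  gene_universe(genes = union(tfs, top), regulators = tfs)
}

#' Construct a gene universe
#'
#' @param genes character vector of gene symbols.
#' @param regulators character vector, subset of `genes`, flagged as TFs.
#' @return Object of class `gene_universe` with lexicographically ordered
#'   members.
#' @export
gene_universe <- function(genes, regulators) {
  genes <- sort(unique(as.character(genes)))
  regulators <- sort(unique(as.character(regulators)))
  if (!all(regulators %in% genes))
    stop("regulators must be a subset of genes; offending: ",
         paste(utils::head(setdiff(regulators, genes), 3), collapse = ", "))
  structure(list(genes = genes, regulators = regulators),
            class = "gene_universe")
}

#' @export
print.gene_universe <- function(x, ...) {
  cat("<gene_universe>", length(x$genes), "genes,",
      length(x$regulators), "regulators\n")
  invisible(x)
}

#' Enumerate the directed edge universe
#'
#' All (regulator, target) pairs with regulator != target, in deterministic
#' order: regulators in lexicographic order, targets in lexicographic order
#' within each regulator.
#'
#' @param u a [gene_universe()].
#' @return Object of class `edge_universe`: data.frame `edges` with columns
#'   `regulator`, `target`, plus `n_edges` and the parent universe.
#' @export
build_edge_universe <- function(u) {
  stopifnot(inherits(u, "gene_universe"))
  if (length(u$genes) == 0 || length(u$regulators) == 0)
    stop("gene universe is empty")
  reg <- rep(u$regulators, each = length(u$genes))
  tgt <- rep(u$genes, times = length(u$regulators))
  keep <- reg != tgt
  edges <- data.frame(regulator = reg[keep], target = tgt[keep],
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, n_edges = nrow(edges), universe = u),
            class = "edge_universe")
}

#' @export
print.edge_universe <- function(x, ...) {
  cat("<edge_universe>", x$n_edges, "directed edges (",
      length(x$universe$regulators), "regulators x",
      length(x$universe$genes), "genes )\n")
  invisible(x)
}

#' Edge keys "regulator->target" for an edge universe
#' @param u an [build_edge_universe()] result.
#' @return Character vector of length `n_edges`.
#' @export
edge_keys <- function(u) {
  paste(u$edges$regulator, u$edges$target, sep = "->")
}
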