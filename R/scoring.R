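#' Construct an edge-score stack
#'
#' Holds observed edge scores for N edges x C cell types, with a logical
#' missingness mask (an edge can be unscored in a cell type, e.g. when one
#' of its genes is constant there).
#'
#' @param scores numeric N x C matrix (columns = cell types).
#' @param universe an edge universe ([build_edge_universe()]) or NULL.
#' @param cell_types character vector of C labels.
#' @param missing logical N x C mask; defaults to `is.na(scores)`.
#' @return Object of class `edge_score_stack`.
#' @export
edge_score_stack <- function(scores, universe = NULL, cell_types = NULL,
                             missing = NULL) {
  scores <- as.matrix(scores)
  if (is.null(cell_types)) cell_types <- colnames(scores)
  if (is.null(cell_types)) cell_types <- paste0("ct", seq_len(ncol(scores)))
  if (length(cell_types) != ncol(scores))
    stop("cell_types length != number of score columns")
  if (is.null(missing)) missing <- is.na(scores)
  missing <- missing | is.na(scores)
  if (!identical(dim(missing), dim(scores)))
    stop("missing mask shape != score shape")
  if (!is.null(universe) && universe$n_edges != nrow(scores))
    stop("score rows (", nrow(scores), ") != edge universe size (",
         universe$n_edges, ")")
  if (any(!is.finite(scores[!missing])))
    stop("non-finite score at a non-missing entry")
  colnames(scores) <- cell_types
  structure(list(scores = scores, missing = missing,
                 cell_types = cell_types, universe = universe),
            class = "edge_score_stack")
}

#' @export
print.edge_score_stack <- function(x, ...) {
  cat("<edge_score_stack>", nrow(x$scores), "edges x",
      ncol(x$scores), "cell types;", sum(x$missing), "missing entries\n")
  invisible(x)
}

#' Construct a noise (standard deviation) stack
#'
#' @param std non-negative N x C matrix of per-edge score standard
#'   deviations, aligned with an [edge_score_stack()].
#' @param floor_value positive floor that was applied to degenerate (zero)
#'   standard deviations.
#' @param missing logical mask, defaults to `is.na(std)`.
#' @return Object of class `noise_stack`.
#' @export
noise_stack <- function(std, floor_value, missing = NULL) {
  std <- as.matrix(std)
  if (is.null(missing)) missing <- is.na(std)
  missing <- missing | is.na(std)
  if (any(std[!missing] <= 0))
    stop("noise std must be strictly positive after flooring")
  structure(list(std = std, floor_value = floor_value, missing = missing),
            class = "noise_stack")
}

#' Pearson edge scorer for one cell type
#'
#' Scores each directed edge (r -> t) by the Pearson correlation of the two
#' genes' transformed expression across cells; by default the absolute value
#' is used so that scores are comparable with non-negative rankings from
#' tree- or information-based methods. Edges touching a constant or absent
#' gene get score 0 and are flagged missing.
#'
#' @param m an [expression_matrix()] (transformed scale).
#' @param u an edge universe.
#' @param absolute use `|r|` (default) rather than signed correlation.
#' @return List with numeric `scores` and logical `missing`, both of length
#'   `u$n_edges`.
#' @export
pearson_scores <- function(m, u, absolute = TRUE) {
  stopifnot(inherits(m, "expression_matrix"))
  if (nrow(m$values) < 3)
    stop("need at least 3 cells to score correlations, got ", nrow(m$values))
  genes <- unique(c(u$edges$regulator, u$edges$target))
  present <- intersect(genes, m$gene_ids)
  sub <- m$values[, present, drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  usable <- present[sds > 0]
  cm <- if (length(usable) >= 2)
    stats::cor(sub[, usable, drop = FALSE]) else NULL
  n <- u$n_edges
  scores <- numeric(n)
  missing <- rep(TRUE, n)
  ri <- match(u$edges$regulator, usable)
  ti <- match(u$edges$target, usable)
  ok <- !is.na(ri) & !is.na(ti)
  if (any(ok) && !is.null(cm)) {
    v <- cm[cbind(ri[ok], ti[ok])]
    scores[ok] <- if (absolute) abs(v) else v
    missing[ok] <- FALSE
  }
  list(scores = scores, missing = missing)
}

#' Bootstrap configuration
#'
#' @param n_trials number of bootstrap resamples M (default 5, the point at
#'   which per-edge standard deviation estimates typically stabilise).
#' @param seed master RNG seed.
#' @param scorer scoring function with signature `(m, u) -> list(scores,
#'   missing)`; default [pearson_scores()].
#' @return Object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_trials = 5, seed = 1, scorer = pearson_scores) {
  if (n_trials < 2) stop("n_trials must be >= 2")
  structure(list(n_trials = as.integer(n_trials), seed = as.integer(seed),
                 scorer = scorer),
            class = "bootstrap_config")
}

#' Derive a child seed from a master seed and a string key
#'
#' Deterministic, platform-independent; result stays below 2^31.
#' @param seed master integer seed.
#' @param key string (e.g. a cell type label).
#' @return Integer seed.
#' @export
derive_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629 + 1)
}

#' Bootstrap estimate of per-edge score noise
#'
#' For one cell type: resample cells with replacement (same number of cells
#' as observed), re-run the scorer, and take the sample standard deviation
#' of each edge's score across the M trials. Zero standard deviations are
#' degenerate in the observation model, so a floor of
#' `max(1e-6, 1st percentile of positive stds)` is applied.
#'
#' Each cell type gets its own RNG stream derived from the master seed via
#' [derive_seed()], so per-type results do not depend on processing order.
#'
#' @param m an [expression_matrix()] (transformed scale).
#' @param u an edge universe.
#' @param cfg a [bootstrap_config()].
#' @return List with `std` (length `n_edges`, NA where the full-data score is
#'   missing), `missing`, and `floor_value`.
#' @export
bootstrap_edge_std <- function(m, u, cfg = bootstrap_config()) {
  stopifnot(inherits(cfg, "bootstrap_config"))
  M <- cfg$n_trials
  base <- cfg$scorer(m, u)
  n_cells <- nrow(m$values)
  draws <- matrix(NA_real_, u$n_edges, M)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$seed, m$cell_type_label))
  for (t in seq_len(M)) {
    idx <- sample.int(n_cells, n_cells, replace = TRUE)
    mb <- m
    mb$values <- m$values[idx, , drop = FALSE]
    mb$cell_ids <- paste0("bs", seq_len(n_cells))
    rownames(mb$values) <- mb$cell_ids
    sc <- cfg$scorer(mb, u)
    draws[, t] <- ifelse(sc$missing, NA, sc$scores)
  }
  std <- apply(draws, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(0)
    stats::sd(v)
  })
  std[base$missing] <- NA_real_
  pos <- std[!is.na(std) & std > 0]
  floor_value <- max(1e-6,
                     if (length(pos) > 0) stats::quantile(pos, 0.01, names = FALSE) else 0)
  std[!is.na(std)] <- pmax(std[!is.na(std)], floor_value)
  list(std = std, missing = base$missing, floor_value = floor_value)
}

#' Constant-std fallback for externally imported scores
#'
#' When third-party scores come without bootstrap replicates, every edge of
#' a cell type is assigned the sample standard deviation of that cell type's
#' non-missing scores (floored at 1e-6).
#'
#' @param scores numeric vector (NA = missing) for one cell type.
#' @return List with `std`, `missing`, `floor_value`.
#' @export
constant_std_fallback <- function(scores) {
  missing <- is.na(scores)
  s <- stats::sd(scores[!missing])
  if (!is.finite(s) || s <= 0) s <- 1e-6
  std <- ifelse(missing, NA_real_, s)
  message("constant-std fallback applied: std = ", signif(s, 4),
          " for all edges of this cell type")
  list(std = std, missing = missing, floor_value = 1e-6)
}

# Save/restore the global RNG state so scoring utilities do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
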