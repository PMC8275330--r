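#' Construct a reference network
#'
#' @param edges data.frame with columns `regulator`, `target` (directed).
#' @param covered_regulators regulators the reference has assay data for;
#'   defaults to the regulators occurring in `edges`.
#' @return Object of class `reference_network`.
#' @export
reference_network <- function(edges, covered_regulators = NULL) {
  edges <- unique(data.frame(regulator = as.character(edges$regulator),
                             target = as.character(edges$target),
                             stringsAsFactors = FALSE))
  if (is.null(covered_regulators)) covered_regulators <- unique(edges$regulator)
  covered_regulators <- unique(as.character(covered_regulators))
  if (!all(edges$regulator %in% covered_regulators))
    stop("reference edges contain regulators outside covered_regulators")
  structure(list(edges = edges, covered_regulators = covered_regulators),
            class = "reference_network")
}

#' Read a reference network from a 2-column TSV
#' @param path TSV with columns `regulator`, `target` (header required).
#' @param covered_path optional plain-text covered-regulator list.
#' @return A [reference_network()].
#' @export
read_reference_network <- function(path, covered_path = NULL) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  covered <- if (!is.null(covered_path)) read_tf_list(covered_path) else NULL
  reference_network(as.data.frame(dt), covered)
}

#' Build a ChIP-derived reference network from peak and TSS tables
#'
#' An edge (TF, gene) is called when the TF has a peak with q-value strictly
#' below `q_max` whose summit lies within `window` bases of the gene's
#' transcription start site on the same chromosome. Coordinates are 1-based
#' points (peak summit, TSS). Covered regulators are all TFs present in the
#' peak table (regardless of whether any peak passes the filters).
#'
#' @param peaks data.frame with columns `tf`, `chrom`, `summit`, `qvalue`.
#' @param tss data.frame with columns `gene`, `chrom`, `tss`.
#' @param q_max strict q-value cutoff (default 1e-5).
#' @param window maximum |summit - TSS| distance in bp (default 5000,
#'   inclusive).
#' @return A [reference_network()].
#' @export
build_chip_reference <- function(peaks, tss, q_max = 1e-5, window = 5000) {
  need_p <- c("tf", "chrom", "summit", "qvalue")
  need_t <- c("gene", "chrom", "tss")
  if (!all(need_p %in% names(peaks)))
    stop("peaks must have columns ", paste(need_p, collapse = ", "))
  if (!all(need_t %in% names(tss)))
    stop("tss must have columns ", paste(need_t, collapse = ", "))
  shared <- intersect(unique(peaks$chrom), unique(tss$chrom))
  if (length(shared) == 0)
    warning("no shared chromosome names between peak and TSS tables (",
            length(unique(peaks$chrom)), " vs ",
            length(unique(tss$chrom)), ")")
  covered <- unique(as.character(peaks$tf))
  pk <- peaks[peaks$qvalue < q_max, , drop = FALSE]
  hits <- list()
  if (nrow(pk) > 0) {
    pk_dt <- data.table::as.data.table(pk)
    tss_dt <- data.table::as.data.table(tss)
    joined <- merge(pk_dt, tss_dt, by = "chrom", allow.cartesian = TRUE)
    joined <- joined[abs(joined$summit - joined$tss) <= window]
    if (nrow(joined) > 0)
      hits <- unique(data.frame(regulator = as.character(joined$tf),
                                target = as.character(joined$gene),
                                stringsAsFactors = FALSE))
  }
  if (length(hits) == 0)
    hits <- data.frame(regulator = character(0), target = character(0))
  reference_network(hits, covered)
}

#' Area under the precision-recall curve for a ranked edge column
#'
#' Positives are the reference edges; the evaluated universe is restricted
#' to edges whose regulator is covered by the reference when
#' `restrict_to_covered = TRUE` (the convention when comparing against
#' ChIP-derived references). The area uses the average-precision (step)
#' convention: precision summed over recall increments, with tied scores
#' collapsed into single threshold groups. Missing scores rank below all
#' observed scores (a method that does not score an edge cannot claim it).
#'
#' @param scores numeric vector aligned to the edge universe (NA = missing).
#' @param u the edge universe ([build_edge_universe()]).
#' @param ref a [reference_network()].
#' @param restrict_to_covered restrict evaluation to covered regulators.
#' @return List of class `pr_result`: `auprc`, `prevalence`, `ratio`
#'   (auprc/prevalence), `n_eval_edges`.
#' @export
auprc <- function(scores, u, ref, restrict_to_covered = TRUE) {
  stopifnot(inherits(ref, "reference_network"))
  if (length(scores) != u$n_edges)
    stop("scores length != edge universe size")
  keep <- if (restrict_to_covered)
    u$edges$regulator %in% ref$covered_regulators
  else rep(TRUE, u$n_edges)
  if (!any(keep))
    stop("no evaluated edges: reference covers no regulator in the universe")
  keys <- paste(u$edges$regulator, u$edges$target, sep = "->")
  pos_keys <- paste(ref$edges$regulator, ref$edges$target, sep = "->")
  y <- as.integer(keys %in% pos_keys)[keep]
  s <- scores[keep]
  s[is.na(s)] <- -Inf
  n_pos <- sum(y)
  n_neg <- sum(1 - y)
  if (n_pos == 0 || n_neg == 0)
    stop("reference yields ", n_pos, " positives and ", n_neg,
         " negatives among evaluated edges")
  # group tied scores into single thresholds, descending
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; y <- y[ord]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(rep(1L, length(y)), grp, sum)
  tp <- cumsum(tp_g)
  nn <- cumsum(n_g)
  precision <- tp / nn
  recall <- tp / n_pos
  d_recall <- diff(c(0, recall))
  area <- sum(precision * d_recall)
  prevalence <- n_pos / length(y)
  structure(list(auprc = area, prevalence = prevalence,
                 ratio = area / prevalence, n_eval_edges = length(y)),
            class = "pr_result")
}

#' @export
print.pr_result <- function(x, ...) {
  cat(sprintf("<pr_result> AUPRC %.4f | prevalence %.4f | ratio %.3f | %d edges\n",
              x$auprc, x$prevalence, x$ratio, x$n_eval_edges))
  invisible(x)
}

#' One-sided Wilcoxon signed-rank test for paired metrics
#'
#' Tests the alternative that `a` tends to exceed `b` across paired
#' observations (e.g. per-cell-type AUPRC ratios with and without sharing).
#' Zero differences are dropped. Exact null distribution when n <= 25 and
#' there are no ties in |differences|; otherwise the normal approximation
#' with continuity correction (and tie correction) is used.
#'
#' @param a,b numeric vectors of equal length >= 5, paired in order.
#' @return List: `p_value`, `statistic` (W+ for a - b), `n_used`, `exact`.
#' @export
paired_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 5) stop("need at least 5 pairs")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero: the test is undefined")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0
  if (n <= 25 && !has_ties) {
    # exact distribution of W+ by convolution over ranks 1..n
    counts <- 1
    for (k in seq_len(n)) {
      new <- c(counts, rep(0, k))
      new[(k + 1):(k + length(counts))] <-
        new[(k + 1):(k + length(counts))] + counts
      counts <- new
    }
    total <- 2^n
    p <- sum(counts[(floor(W) + 1):length(counts)]) / total
    list(p_value = p, statistic = W, n_used = n, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - 0.5) / sqrt(sig2)
    list(p_value = stats::pnorm(z, lower.tail = FALSE), statistic = W,
         n_used = n, exact = FALSE)
  }
}

#' Evaluate score columns against reference networks
#'
#' Convenience wrapper producing the results table dialect: one row per
#' (cell type, reference) with AUPRC, prevalence, ratio and edge count.
#'
#' @param stack an [edge_score_stack()] with a universe attached.
#' @param refs named list of [reference_network()] objects.
#' @param restrict_to_covered see [auprc()].
#' @return data.frame with columns `cell_type`, `reference`, `auprc`,
#'   `prevalence`, `ratio`, `n_eval_edges`.
#' @export
evaluate_networks <- function(stack, refs, restrict_to_covered = TRUE) {
  stopifnot(inherits(stack, "edge_score_stack"))
  if (is.null(stack$universe)) stop("score stack carries no edge universe")
  rows <- list()
  for (c in seq_along(stack$cell_types)) {
    s <- ifelse(stack$missing[, c], NA, stack$scores[, c])
    for (rn in names(refs)) {
      pr <- auprc(s, stack$universe, refs[[rn]], restrict_to_covered)
      rows[[length(rows) + 1]] <- data.frame(
        cell_type = stack$cell_types[c], reference = rn,
        auprc = pr$auprc, prevalence = pr$prevalence, ratio = pr$ratio,
        n_eval_edges = pr$n_eval_edges, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
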