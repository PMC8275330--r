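#' Binarize score columns by retaining the top fraction of edges
#'
#' Per cell type, the `ceiling(fraction * N)` highest-scoring edges are
#' marked active. Ties at the cut are resolved deterministically by edge
#' universe order (earlier edges win). Missing scores rank below everything.
#'
#' @param stack an [edge_score_stack()].
#' @param fraction fraction of edges to activate, in (0, 1].
#' @return Object of class `binary_network_chain`: logical `activity`
#'   matrix (N x T), `order` (cell type labels), `top_fraction`.
#' @export
binarize_top_fraction <- function(stack, fraction) {
  stopifnot(inherits(stack, "edge_score_stack"))
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  N <- nrow(stack$scores)
  k <- ceiling(fraction * N)
  if (fraction * N < 1)
    stop("fraction * N = ", fraction * N, " < 1: no edge would be retained")
  act <- matrix(FALSE, N, ncol(stack$scores))
  for (c in seq_len(ncol(stack$scores))) {
    s <- ifelse(stack$missing[, c], -Inf, stack$scores[, c])
    ord <- order(s, seq_len(N), decreasing = c(TRUE, FALSE),
                 method = "radix")
    act[ord[seq_len(k)], c] <- TRUE
  }
  colnames(act) <- stack$cell_types
  structure(list(activity = act, order = stack$cell_types,
                 top_fraction = fraction),
            class = "binary_network_chain")
}

#' Construct a binary network chain directly
#' @param activity logical N x T matrix, columns in trajectory order.
#' @param order cell type labels along the chain.
#' @param top_fraction fraction used to binarize (metadata).
#' @return Object of class `binary_network_chain`.
#' @export
binary_network_chain <- function(activity, order = colnames(activity),
                                 top_fraction = NA_real_) {
  activity <- as.matrix(activity)
  if (ncol(activity) < 2) stop("a chain needs at least 2 cell types")
  if (is.null(order)) order <- paste0("ct", seq_len(ncol(activity)))
  structure(list(activity = activity > 0, order = order,
                 top_fraction = top_fraction),
            class = "binary_network_chain")
}

#' Classify edge dynamics along an ordered chain of networks
#'
#' Labels per edge:
#' * `stably_added` — inactive at the start, flips exactly once to active
#'   and stays active to the end (pattern `0...0 1...1`);
#' * `stably_removed` — the mirror pattern `1...1 0...0`;
#' * `unstable` — activity status changes more than `max_flips_stable`
#'   times along the chain;
#' * `other` — anything else.
#'
#' One-flip patterns can never exceed a threshold >= 2, so the labels are
#' mutually exclusive.
#'
#' @param chain a [binary_network_chain()].
#' @param max_flips_stable flip count above which an edge is unstable
#'   (default 4, matching a ten-step chain).
#' @return data.frame with columns `label` (factor) and `n_flips`.
#' @export
classify_dynamics <- function(chain, max_flips_stable = 4) {
  stopifnot(inherits(chain, "binary_network_chain"))
  A <- chain$activity
  T_ <- ncol(A)
  flips <- rowSums(A[, -1, drop = FALSE] != A[, -T_, drop = FALSE])
  label <- rep("other", nrow(A))
  label[flips > max_flips_stable] <- "unstable"
  if (T_ >= 3) {
    one_flip <- flips == 1
    label[one_flip & !A[, 1]] <- "stably_added"
    label[one_flip & A[, 1]] <- "stably_removed"
  }
  data.frame(label = factor(label, levels = c("stably_added",
                                              "stably_removed",
                                              "unstable", "other")),
             n_flips = as.integer(flips))
}

#' Summarise dynamics calls and extract normalized score trajectories
#'
#' @param calls result of [classify_dynamics()].
#' @param stack optional [edge_score_stack()] whose columns follow the chain
#'   order, used to extract per-edge score trajectories.
#' @param label which label's trajectories to extract (default
#'   `"stably_added"`).
#' @return List: `counts` (data.frame label/count for the three dynamic
#'   labels) and `trajectories` (min-max normalized score matrix for the
#'   selected label, or NULL). A constant trajectory normalizes to all-0.5.
#' @export
dynamics_counts <- function(calls, stack = NULL, label = "stably_added") {
  tab <- table(calls$label)
  counts <- data.frame(
    label = c("stably_added", "stably_removed", "unstable"),
    count = as.integer(tab[c("stably_added", "stably_removed", "unstable")]),
    stringsAsFactors = FALSE)
  traj <- NULL
  if (!is.null(stack)) {
    idx <- which(calls$label == label)
    if (length(idx) > 0) {
      traj <- stack$scores[idx, , drop = FALSE]
      traj <- t(apply(traj, 1, function(v) {
        rng <- range(v)
        if (rng[2] - rng[1] < .Machine$double.eps) {
          message("constant trajectory min-max normalized to 0.5")
          return(rep(0.5, length(v)))
        }
        (v - rng[1]) / (rng[2] - rng[1])
      }))
      colnames(traj) <- stack$cell_types
    }
  }
  list(counts = counts, trajectories = traj)
}
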