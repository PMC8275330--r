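#' Simulate edge scores from the sharing model's own generative process
#'
#' Draws component assignments uniformly, latent score vectors from the
#' component Gaussians, and observed scores as the latent scores plus
#' heteroscedastic Gaussian noise. Component means are drawn i.i.d.
#' `N(0, (separation * sigma_w)^2 I)` where `sigma_w` is the average
#' within-component standard deviation, so `separation` measures distance
#' between component means in within-component standard deviation units.
#'
#' Within-component cell-type correlation is exchangeable at `rho`, or block
#' structured when `blocks` is given (a list of cell-type index vectors;
#' correlation `rho` within a block, 0 between blocks).
#'
#' The reported noise standard deviations are the exact generating values
#' (oracle mode). A pipeline-style re-estimate of the noise is obtained by
#' composing [simulate_expression()], [pearson_scores()] and
#' [bootstrap_edge_std()] instead.
#'
#' @param N number of edges.
#' @param C number of cell types.
#' @param K number of mixture components.
#' @param separation mean separation in within-component SD units
#'   (default 3).
#' @param noise_levels scalar or length-C base noise SD (default 0.5); the
#'   per-entry SD is Uniform(0.5, 1.5) times this value. Zero gives exact
#'   observations.
#' @param missing_rate completely-at-random missingness rate (default 0).
#' @param rho within-component (or within-block) cell-type correlation.
#' @param blocks optional list of cell-type index vectors for block
#'   covariance.
#' @param seed RNG seed.
#' @return List: `stack` ([edge_score_stack()]), `noise` (list `std`,
#'   `missing`, `floor_value`), and `truth` (`z_true`, `assignments`,
#'   `mu_true`, `sigma_true`, `noise_std`).
#' @export
simulate_sharing <- function(N, C, K, separation = 3, noise_levels = 0.5,
                             missing_rate = 0, rho = 0.5, blocks = NULL,
                             seed = 1) {
  if (K < 1) stop("K must be >= 1")
  if (separation < 0) stop("separation must be >= 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  R <- matrix(0, C, C)
  if (is.null(blocks)) {
    R[] <- rho
  } else {
    for (b in blocks) R[b, b] <- rho
  }
  diag(R) <- 1
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("requested correlation structure is not positive-definite")
  sigma_true <- replicate(K, R, simplify = FALSE)
  sigma_w <- 1  # unit within-component variances
  mu_true <- matrix(stats::rnorm(K * C, sd = separation * sigma_w), K, C)
  if (K == 1) mu_true[] <- 0
  assignments <- sample.int(K, N, replace = TRUE)
  ch <- chol(R)
  z <- matrix(stats::rnorm(N * C), N, C) %*% ch + mu_true[assignments, , drop = FALSE]
  noise_levels <- rep(noise_levels, length.out = C)
  std <- matrix(stats::runif(N * C, 0.5, 1.5), N, C) *
    matrix(noise_levels, N, C, byrow = TRUE)
  e <- z + matrix(stats::rnorm(N * C), N, C) * std
  missing <- matrix(stats::runif(N * C) < missing_rate, N, C)
  # never leave an edge with all cell types missing (it carries no data)
  all_mis <- rowSums(!missing) == 0
  missing[all_mis, 1] <- FALSE
  std_rep <- std
  std_rep[std_rep <= 0] <- 1e-6
  std_rep[missing] <- NA_real_
  e_obs <- e
  e_obs[missing] <- NA_real_
  cts <- paste0("ct", seq_len(C))
  colnames(e_obs) <- cts
  list(stack = edge_score_stack(e_obs, cell_types = cts, missing = missing),
       noise = list(std = std_rep, missing = missing, floor_value = 1e-6),
       truth = list(z_true = z, assignments = assignments, mu_true = mu_true,
                    sigma_true = sigma_true, noise_std = std))
}

#' Simulate a regression ground truth (supports and coefficients)
#'
#' Builds the spike-and-slab ground truth used by [simulate_expression()]:
#' per cell type inclusion indicators over all (regulator, target) pairs
#' and coefficient values that are zero exactly where the indicator is zero.
#' With `shared_support = TRUE` all cell types share one support and one set
#' of coefficient values (the regime where cross-cell-type sharing helps).
#'
#' @param universe a [gene_universe()]; targets are the non-regulator genes.
#' @param C number of cell types.
#' @param density probability a (regulator, target) pair is active.
#' @param beta_sd coefficient scale for active pairs.
#' @param noise_var observation noise variance of the linear model.
#' @param shared_support share the support and coefficients across cell
#'   types (default TRUE).
#' @param seed RNG seed.
#' @return List of class `regression_sim_truth`: `gamma_true`, `beta_true`
#'   (regulators x targets x C arrays), `regulators`, `targets`,
#'   `noise_var`, `shared_support`.
#' @export
simulate_regression_truth <- function(universe, C, density = 0.2,
                                      beta_sd = 1, noise_var = 1,
                                      shared_support = TRUE, seed = 1) {
  stopifnot(inherits(universe, "gene_universe"))
  regulators <- universe$regulators
  targets <- setdiff(universe$genes, regulators)
  if (length(targets) == 0) stop("universe has no non-regulator targets")
  p <- length(regulators); q <- length(targets)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  gamma <- array(0L, dim = c(p, q, C))
  beta <- array(0, dim = c(p, q, C))
  if (shared_support) {
    g <- matrix(stats::rbinom(p * q, 1, density), p, q)
    b <- matrix(stats::rnorm(p * q, sd = beta_sd), p, q) * g
    for (c in seq_len(C)) { gamma[, , c] <- g; beta[, , c] <- b }
  } else {
    for (c in seq_len(C)) {
      g <- matrix(stats::rbinom(p * q, 1, density), p, q)
      gamma[, , c] <- g
      beta[, , c] <- matrix(stats::rnorm(p * q, sd = beta_sd), p, q) * g
    }
  }
  structure(list(gamma_true = gamma, beta_true = beta,
                 regulators = regulators, targets = targets,
                 noise_var = noise_var, shared_support = shared_support),
            class = "regression_sim_truth")
}

#' Simulate expression matrices from a regression ground truth
#'
#' Regulator expression is standard Gaussian on the transformed
#' (log) scale; each target is the linear combination of its regulators
#' plus Gaussian noise. With `counts_scale = TRUE` the matrices are
#' back-transformed to CPM-like counts via `100 * (exp(x) - 1)`, clipped at
#' zero (so [log_transform()] round-trips where counts are positive).
#'
#' @param n_cells integer vector (length C or 1) of cells per cell type.
#' @param universe the [gene_universe()] used to build `truth`.
#' @param truth a [simulate_regression_truth()] result.
#' @param seed RNG seed.
#' @param counts_scale return CPM-like counts instead of transformed values.
#' @return Named list of [expression_matrix()] objects, one per cell type.
#' @export
simulate_expression <- function(n_cells, universe, truth, seed = 1,
                                counts_scale = FALSE) {
  stopifnot(inherits(truth, "regression_sim_truth"))
  C <- dim(truth$gamma_true)[3]
  n_cells <- rep(n_cells, length.out = C)
  regulators <- truth$regulators
  targets <- truth$targets
  genes <- universe$genes
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  out <- vector("list", C)
  names(out) <- paste0("ct", seq_len(C))
  for (c in seq_len(C)) {
    set.seed(derive_seed(seed, paste0("expr", c)))
    n <- n_cells[c]
    X <- matrix(stats::rnorm(n * length(regulators)), n, length(regulators))
    colnames(X) <- regulators
    B <- truth$beta_true[, , c] * truth$gamma_true[, , c]
    Y <- X %*% B +
      matrix(stats::rnorm(n * length(targets), sd = sqrt(truth$noise_var)),
             n, length(targets))
    colnames(Y) <- targets
    vals <- matrix(0, n, length(genes),
                   dimnames = list(NULL, genes))
    vals[, regulators] <- X
    vals[, targets] <- Y
    if (counts_scale) vals <- pmax(100 * expm1(vals), 0)
    out[[c]] <- expression_matrix(vals, gene_ids = genes,
                                  cell_ids = sprintf("c%d_%d", c, seq_len(n)),
                                  cell_type_label = names(out)[c])
  }
  out
}

#' Simulate a binary activity chain with planted dynamics labels
#'
#' Generates edge activity patterns along a T-step chain: `n_added` edges
#' with a single 0->1 flip, `n_removed` with a single 1->0 flip,
#' `n_unstable` with more than `max_flips_stable` flips, and the remainder
#' constant (alternating all-active / all-inactive).
#'
#' @param N total number of edges.
#' @param T_ chain length (>= 3 for added/removed; `T_ - 1 >
#'   max_flips_stable` required when planting unstable edges).
#' @param n_added,n_removed,n_unstable planted counts (sum <= N).
#' @param max_flips_stable the instability threshold (default 4).
#' @param seed RNG seed.
#' @return List: `chain` ([binary_network_chain()]) and `truth` (character
#'   labels per edge).
#' @export
simulate_chain <- function(N, T_, n_added = 0, n_removed = 0, n_unstable = 0,
                           max_flips_stable = 4, seed = 1) {
  if (n_added + n_removed + n_unstable > N)
    stop("planted counts exceed N")
  if ((n_added > 0 || n_removed > 0) && T_ < 3)
    stop("added/removed patterns require T >= 3")
  if (n_unstable > 0 && (T_ - 1) <= max_flips_stable)
    stop("cannot plant > ", max_flips_stable, " flips in a chain of length ",
         T_)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  A <- matrix(FALSE, N, T_)
  labels <- rep("other", N)
  row <- 1
  for (i in seq_len(n_added)) {
    t <- sample(seq_len(T_ - 1), 1)
    A[row, ] <- c(rep(FALSE, t), rep(TRUE, T_ - t))
    labels[row] <- "stably_added"; row <- row + 1
  }
  for (i in seq_len(n_removed)) {
    t <- sample(seq_len(T_ - 1), 1)
    A[row, ] <- c(rep(TRUE, t), rep(FALSE, T_ - t))
    labels[row] <- "stably_removed"; row <- row + 1
  }
  for (i in seq_len(n_unstable)) {
    f <- sample((max_flips_stable + 1):(T_ - 1), 1)
    flips_at <- sort(sample(seq_len(T_ - 1), f))
    pat <- logical(T_)
    pat[1] <- stats::runif(1) < 0.5
    for (t in 2:T_) pat[t] <- if ((t - 1) %in% flips_at) !pat[t - 1] else pat[t - 1]
    A[row, ] <- pat
    labels[row] <- "unstable"; row <- row + 1
  }
  if (row <= N) {
    rest <- row:N
    A[rest, ] <- rep(c(TRUE, FALSE), length.out = length(rest))
  }
  list(chain = binary_network_chain(A, order = paste0("t", seq_len(T_))),
       truth = labels)
}
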