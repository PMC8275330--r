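#' Normal-Wishart prior over a sharing pattern's mean and precision
#'
#' Each mixture component k carries a cell-type mean vector and a cell-type
#' x cell-type precision matrix with conjugate prior
#' `(mu_k, Lambda_k) ~ NW(mu0, beta0, Psi, nu)`, parameterised so that the
#' prior expectation of the covariance is `Psi / (nu - C - 1)`.
#'
#' @param mu0 length-C prior mean.
#' @param beta0 positive scalar mean-precision scale.
#' @param Psi C x C symmetric positive-definite inverse scale.
#' @param nu degrees of freedom, must exceed C - 1.
#' @return Object of class `nw_prior`.
#' @export
nw_prior <- function(mu0, beta0, Psi, nu) {
  Psi <- as.matrix(Psi)
  C <- length(mu0)
  stopifnot(nrow(Psi) == C, ncol(Psi) == C)
  if (max(abs(Psi - t(Psi))) > 1e-8 * max(1, max(abs(Psi))))
    stop("Psi must be symmetric")
  ev <- eigen((Psi + t(Psi)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Psi must be positive-definite")
  if (beta0 <= 0) stop("beta0 must be positive")
  if (nu <= C - 1) stop("nu must exceed C - 1 = ", C - 1)
  structure(list(mu0 = as.numeric(mu0), beta0 = beta0,
                 Psi = (Psi + t(Psi)) / 2, nu = nu),
            class = "nw_prior")
}

#' Data-driven default Normal-Wishart prior
#'
#' Weakly informative empirical default: the prior mean is the per-cell-type
#' mean of the observed scores; `beta0 = 1e-3` (near-flat on the mean);
#' `nu = C + 2` (lightest proper choice with a finite covariance
#' expectation); `Psi = (nu - C - 1) * diag(per-cell-type variances)`, so by
#' the inverse-Wishart identity `E[Sigma] = Psi/(nu - C - 1)` the prior
#' expected covariance equals the empirical diagonal exactly.
#'
#' @param stack an [edge_score_stack()].
#' @return An [nw_prior()].
#' @export
default_nw_prior <- function(stack) {
  stopifnot(inherits(stack, "edge_score_stack"))
  C <- ncol(stack$scores)
  n_obs <- colSums(!stack$missing)
  if (any(n_obs == 0))
    stop("cell type with no observed scores: ",
         stack$cell_types[which(n_obs == 0)[1]])
  if (sum(rowSums(!stack$missing) > 0) < C + 2)
    stop("need at least C + 2 = ", C + 2, " non-missing edges")
  mu0 <- vapply(seq_len(C), function(c)
    mean(stack$scores[!stack$missing[, c], c]), numeric(1))
  v <- vapply(seq_len(C), function(c)
    stats::var(stack$scores[!stack$missing[, c], c]), numeric(1))
  v[!is.finite(v) | v <= 0] <- 1e-6
  nu <- C + 2
  nw_prior(mu0 = mu0, beta0 = 1e-3, Psi = (nu - C - 1) * diag(v, C), nu = nu)
}

#' Model configuration for the sharing model
#'
#' @param K number of mixture components (sharing patterns); default 10.
#' @param max_iter maximum coordinate-ascent sweeps (default 500).
#' @param rel_tol relative ELBO change declaring convergence (default 1e-6).
#' @param seed RNG seed controlling initialisation.
#' @param init `"kmeans"` (default) or `"random"` responsibilities.
#' @param link mean link for the observation layer; only `"identity"` is
#'   supported in the score-sharing model (the sigmoid link is used by the
#'   variable-selection extension, see [fit_bvs()]).
#' @return Object of class `model_config`.
#' @export
model_config <- function(K = 10, max_iter = 500, rel_tol = 1e-6, seed = 1,
                         init = c("kmeans", "random"),
                         link = c("identity", "sigmoid")) {
  init <- match.arg(init)
  link <- match.arg(link)
  if (K < 1) stop("K must be >= 1")
  if (rel_tol <= 0) stop("rel_tol must be positive")
  if (link == "sigmoid")
    stop("sigmoid link is only available through the BVS model")
  structure(list(K = as.integer(K), max_iter = as.integer(max_iter),
                 rel_tol = rel_tol, seed = as.integer(seed),
                 init = init, link = link),
            class = "model_config")
}

# ---- internal helpers -------------------------------------------------------

# Cholesky-based SPD inverse + log-determinant; errors carry context.
.spd_inv_logdet <- function(A, what = "matrix") {
  R <- tryCatch(chol(A), error = function(e)
    stop("non-SPD ", what, ": ", conditionMessage(e), call. = FALSE))
  list(inv = chol2inv(R), logdet = 2 * sum(log(diag(R))))
}

# E[log |Lambda_k|] under Wishart with inverse scale B and dof nu.
.elogdet_lambda <- function(logdetB, nu, C) {
  sum(digamma((nu + 1 - seq_len(C)) / 2)) + C * log(2) - logdetB
}

# log of the Wishart normalising constant B(W, nu) written in terms of the
# inverse scale matrix (W = B^{-1}), so log|W| = -log|B|.
.log_wishart_B <- function(logdetB, nu, C) {
  (nu / 2) * logdetB - (nu * C / 2) * log(2) -
    (C * (C - 1) / 4) * log(pi) -
    sum(lgamma((nu + 1 - seq_len(C)) / 2))
}

# Per-edge observation precision matrix entries: 1/sigma^2, 0 where missing.
.obs_precision <- function(noise) {
  prec <- 1 / noise$std^2
  prec[noise$missing | is.na(noise$std)] <- 0
  prec
}

# Component summaries reused by edge updates and responsibilities:
# ELam (K x C x C stack flattened K x C^2), ELam_a (K x C), Binv list,
# elogdet (K), logdetB (K).
.component_expectations <- function(comp) {
  K <- length(comp)
  C <- length(comp[[1]]$a)
  EL_flat <- matrix(0, K, C * C)
  ELa <- matrix(0, K, C)
  Binv <- vector("list", K)
  elogdet <- numeric(K)
  for (k in seq_len(K)) {
    ck <- comp[[k]]
    d <- .spd_inv_logdet(ck$B, paste0("component ", k, " scale B"))
    Binv[[k]] <- d$inv
    ELam <- ck$nu * d$inv
    EL_flat[k, ] <- as.numeric(ELam)
    ELa[k, ] <- as.numeric(ELam %*% ck$a)
    elogdet[k] <- .elogdet_lambda(d$logdet, ck$nu, C)
  }
  list(EL_flat = EL_flat, ELa = ELa, Binv = Binv, elogdet = elogdet)
}

# Expected log-density matrix: logrho[n, k] = E_q[log N(z_n | mu_k, Sigma_k)]
# with expectations over q(z_n) and q(mu_k, Lambda_k).
.expected_log_density <- function(state) {
  M <- state$M
  S_flat <- state$S_flat
  comp <- state$components
  K <- length(comp)
  C <- ncol(M)
  N <- nrow(M)
  ce <- state$comp_exp
  logrho <- matrix(0, N, K)
  for (k in seq_len(K)) {
    ck <- comp[[k]]
    Binv <- ce$Binv[[k]]
    Mc <- sweep(M, 2, ck$a)
    quad <- rowSums((Mc %*% Binv) * Mc)
    trS <- as.numeric(S_flat %*% as.numeric(Binv))
    logrho[, k] <- 0.5 * ce$elogdet[k] - (C / 2) * log(2 * pi) -
      0.5 * (C / ck$beta + ck$nu * (quad + trS))
  }
  logrho
}

# ---- variational state ------------------------------------------------------

#' Initialise the variational state
#'
#' Responsibilities come from k-means (K clusters) on the score rows with
#' missing entries imputed by the cell-type mean; the edge posterior mean is
#' initialised at the (imputed) observed scores with zero covariance; one
#' component-update pass then produces valid Normal-Wishart posteriors.
#'
#' @param stack an [edge_score_stack()].
#' @param noise a matching noise object (list with `std`, `missing`).
#' @param cfg a [model_config()].
#' @param prior an [nw_prior()]; default [default_nw_prior()].
#' @return A `share_fit` state (iteration 0).
#' @export
init_state <- function(stack, noise, cfg, prior = default_nw_prior(stack)) {
  N <- nrow(stack$scores)
  C <- ncol(stack$scores)
  K <- cfg$K
  if (K > N) stop("K (", K, ") exceeds number of edges (", N, ")")
  E <- stack$scores
  for (c in seq_len(C)) {
    mis <- stack$missing[, c]
    E[mis, c] <- mean(E[!mis, c])
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  assign_k <- if (K == 1) {
    rep(1L, N)
  } else if (cfg$init == "random") {
    sample.int(K, N, replace = TRUE)
  } else {
    km <- tryCatch(
      stats::kmeans(E, centers = K, nstart = 5, iter.max = 50),
      error = function(e) NULL)
    if (is.null(km)) sample.int(K, N, replace = TRUE) else km$cluster
  }
  phi <- matrix(0, N, K)
  phi[cbind(seq_len(N), assign_k)] <- 1
  state <- structure(
    list(components = vector("list", K),
         M = E,
         S_flat = matrix(0, N, C * C),
         logdetS = rep(-Inf, N),
         phi = phi,
         prior = prior, config = cfg,
         cell_types = stack$cell_types,
         elbo_trace = numeric(0)),
    class = "share_fit")
  state <- update_components(state, stack)
  state
}

#' Edge-posterior coordinate update
#'
#' For each edge n the optimal Gaussian factor has precision
#' `Lambda_n = sum_k phi_nk E[Lambda_k] + D_n^{-1}` with
#' `D_n = diag(sigma_n^2)` (missing cell types contribute zero precision)
#' and mean `m_n = S_n (sum_k phi_nk E[Lambda_k mu_k] + D_n^{-1} e_n)`.
#'
#' @param state a `share_fit` state.
#' @param stack the observed [edge_score_stack()].
#' @param noise matching noise object (`std`, `missing`).
#' @return Updated state.
#' @export
update_edges <- function(state, stack, noise) {
  N <- nrow(stack$scores)
  C <- ncol(stack$scores)
  prec <- .obs_precision(noise)
  e0 <- stack$scores
  e0[stack$missing] <- 0
  ce <- state$comp_exp
  if (is.null(ce)) ce <- .component_expectations(state$components)
  W <- state$phi %*% ce$EL_flat        # N x C^2 weighted E[Lambda]
  Bvec <- state$phi %*% ce$ELa + prec * e0   # N x C natural mean parameter
  S_flat <- matrix(0, N, C * C)
  M <- matrix(0, N, C)
  logdetS <- numeric(N)
  diag_idx <- (seq_len(C) - 1) * C + seq_len(C)
  for (n in seq_len(N)) {
    Lam <- matrix(W[n, ], C, C)
    Lam[diag_idx] <- Lam[diag_idx] + prec[n, ]
    R <- tryCatch(chol(Lam), error = function(e)
      stop("non-SPD edge precision at edge ", n,
           " (component scales may be degenerate): ",
           conditionMessage(e), call. = FALSE))
    Sn <- chol2inv(R)
    S_flat[n, ] <- Sn
    M[n, ] <- Sn %*% Bvec[n, ]
    logdetS[n] <- -2 * sum(log(diag(R)))
  }
  state$M <- M
  state$S_flat <- S_flat
  state$logdetS <- logdetS
  state
}

#' Responsibility coordinate update
#'
#' `phi_nk` is proportional to `exp(E_q[log N(z_n | mu_k, Sigma_k)])`
#' (the uniform categorical prior adds no tilt); rows are normalised with
#' log-sum-exp.
#'
#' @inheritParams update_edges
#' @return Updated state.
#' @export
update_responsibilities <- function(state, stack) {
  if (is.null(state$comp_exp))
    state$comp_exp <- .component_expectations(state$components)
  logrho <- .expected_log_density(state)
  mx <- apply(logrho, 1, max)
  if (any(!is.finite(mx)))
    stop("all responsibilities vanished for edge ", which(!is.finite(mx))[1],
         "; log-sum-exp invariant violated (implementation bug)")
  ex <- exp(logrho - mx)
  state$phi <- ex / rowSums(ex)
  state
}

#' Component (Normal-Wishart) coordinate update
#'
#' Standard weighted conjugate update driven by the responsibilities and the
#' edge posteriors' first two moments. A component receiving no mass is
#' reset to the prior (with a message), keeping K fixed.
#'
#' @inheritParams update_edges
#' @return Updated state (component expectations cached).
#' @export
update_components <- function(state, stack) {
  prior <- state$prior
  K <- ncol(state$phi)
  C <- ncol(state$M)
  comp <- vector("list", K)
  for (k in seq_len(K)) {
    w <- state$phi[, k]
    Nk <- sum(w)
    if (Nk < 1e-12) {
      message("component ", k, " is empty; reset to prior")
      comp[[k]] <- list(a = prior$mu0, beta = prior$beta0, B = prior$Psi,
                        nu = prior$nu, weight_mass = 0)
      next
    }
    zbar <- colSums(w * state$M) / Nk
    S_sum <- matrix(colSums(w * state$S_flat), C, C)
    Mc <- sweep(state$M, 2, zbar)
    scatter <- crossprod(Mc, w * Mc) + S_sum
    beta_k <- prior$beta0 + Nk
    dv <- zbar - prior$mu0
    B_k <- prior$Psi + scatter +
      (prior$beta0 * Nk / beta_k) * tcrossprod(dv)
    comp[[k]] <- list(a = (prior$beta0 * prior$mu0 + Nk * zbar) / beta_k,
                      beta = beta_k,
                      B = (B_k + t(B_k)) / 2,
                      nu = prior$nu + Nk,
                      weight_mass = Nk)
  }
  state$components <- comp
  state$comp_exp <- .component_expectations(comp)
  state
}

#' Evidence lower bound of the current variational state
#'
#' All expectations are analytic (Gaussian/Wishart/categorical). The value
#' is finite by construction; a NaN or Inf names the offending term.
#'
#' @inheritParams update_edges
#' @return A single finite numeric value.
#' @export
compute_elbo <- function(state, stack, noise) {
  M <- state$M; S_flat <- state$S_flat; phi <- state$phi
  prior <- state$prior
  N <- nrow(M); C <- ncol(M); K <- ncol(phi)
  prec <- .obs_precision(noise)
  obs <- prec > 0
  diag_idx <- (seq_len(C) - 1) * C + seq_len(C)
  Sdiag <- S_flat[, diag_idx, drop = FALSE]
  # E[log p(e | z)] over observed entries
  resid2 <- (stack$scores - M)^2
  resid2[!obs] <- 0
  ll_obs <- sum(ifelse(obs,
                       0.5 * log(prec / (2 * pi)) -
                         0.5 * prec * (resid2 + Sdiag), 0))
  if (is.null(state$comp_exp))
    state$comp_exp <- .component_expectations(state$components)
  logrho <- .expected_log_density(state)
  e_pz <- sum(phi * logrho)
  e_pu <- -N * log(K)
  h_u <- -sum(phi[phi > 0] * log(phi[phi > 0]))
  h_z <- sum(0.5 * (C * log(2 * pi * exp(1)) + state$logdetS))
  # Normal-Wishart prior cross-entropy and entropy, per component
  pd <- .spd_inv_logdet(prior$Psi, "prior Psi")
  logB_prior <- .log_wishart_B(pd$logdet, prior$nu, C)
  nw_term <- 0
  for (k in seq_len(K)) {
    ck <- state$components[[k]]
    Binv <- state$comp_exp$Binv[[k]]
    eld <- state$comp_exp$elogdet[k]
    logdetB <- -determinant_from_inv(Binv)
    dv <- ck$a - prior$mu0
    e_logp <- 0.5 * (C * log(prior$beta0 / (2 * pi)) + eld -
                       C * prior$beta0 / ck$beta -
                       prior$beta0 * ck$nu * sum(dv * (Binv %*% dv))) +
      logB_prior + ((prior$nu - C - 1) / 2) * eld -
      0.5 * ck$nu * sum(prior$Psi * Binv)
    logB_q <- .log_wishart_B(logdetB, ck$nu, C)
    h_wish <- -logB_q - ((ck$nu - C - 1) / 2) * eld + ck$nu * C / 2
    e_logq <- 0.5 * eld + (C / 2) * log(ck$beta / (2 * pi)) - C / 2 - h_wish
    nw_term <- nw_term + e_logp - e_logq
  }
  terms <- c(obs_likelihood = ll_obs, prior_z = e_pz, prior_u = e_pu,
             entropy_u = h_u, entropy_z = h_z, normal_wishart = nw_term)
  bad <- !is.finite(terms)
  if (any(bad))
    stop("non-finite ELBO term(s): ", paste(names(terms)[bad], collapse = ", "))
  sum(terms)
}

# log|B| from its inverse via Cholesky (B SPD => Binv SPD).
determinant_from_inv <- function(Binv) {
  2 * sum(log(diag(chol(Binv))))
}

#' Fit the sharing model by coordinate-ascent variational inference
#'
#' Sweeps edge updates, responsibility updates and component updates until
#' the relative ELBO change drops below `cfg$rel_tol` or `cfg$max_iter`
#' sweeps are reached. Deterministic under a fixed `cfg$seed`.
#'
#' @param stack an [edge_score_stack()].
#' @param noise matching noise object (list with `std`, `missing`, e.g. from
#'   [bootstrap_edge_std()] columns bound into matrices).
#' @param cfg a [model_config()].
#' @param prior an [nw_prior()]; default [default_nw_prior()].
#' @return A fitted `share_fit` with `elbo_trace` recorded.
#' @export
fit_share_model <- function(stack, noise, cfg = model_config(),
                            prior = default_nw_prior(stack)) {
  stopifnot(inherits(stack, "edge_score_stack"))
  if (!identical(dim(noise$std), dim(stack$scores)))
    stop("noise and score stacks have different shapes")
  state <- init_state(stack, noise, cfg, prior)
  elbo_prev <- -Inf
  trace <- numeric(0)
  for (it in seq_len(cfg$max_iter)) {
    state <- update_edges(state, stack, noise)
    state <- update_responsibilities(state, stack)
    state <- update_components(state, stack)
    elbo <- compute_elbo(state, stack, noise)
    trace <- c(trace, elbo)
    if (is.finite(elbo_prev) &&
        abs(elbo - elbo_prev) < cfg$rel_tol * abs(elbo_prev)) {
      elbo_prev <- elbo
      break
    }
    elbo_prev <- elbo
  }
  state$elbo_trace <- trace
  state$converged <- length(trace) < cfg$max_iter
  state
}

#' @export
print.share_fit <- function(x, ...) {
  cat("<share_fit>", nrow(x$M), "edges x", ncol(x$M), "cell types,",
      ncol(x$phi), "components;", length(x$elbo_trace), "sweeps",
      if (isTRUE(x$converged)) "(converged)" else "", "\n")
  if (length(x$elbo_trace) > 0)
    cat("  final ELBO:", format(utils::tail(x$elbo_trace, 1)), "\n")
  invisible(x)
}

#' Revised edge scores from a fitted sharing model
#'
#' The posterior means of the latent true scores replace the noisy observed
#' scores; missing entries are filled with their conditional prior-informed
#' posterior mean (never NA).
#'
#' @param fit a fitted `share_fit`.
#' @param stack the original [edge_score_stack()] (for universe/labels).
#' @return An [edge_score_stack()] of revised scores (no missing entries).
#' @export
revised_scores <- function(fit, stack = NULL) {
  stopifnot(inherits(fit, "share_fit"))
  scores <- fit$M
  colnames(scores) <- fit$cell_types
  edge_score_stack(scores,
                   universe = if (!is.null(stack)) stack$universe else NULL,
                   cell_types = fit$cell_types,
                   missing = matrix(FALSE, nrow(scores), ncol(scores)))
}

#' Map each edge to its most probable sharing component
#' @param fit a fitted `share_fit`.
#' @return Integer vector of MAP component indices (length N).
#' @export
map_components <- function(fit) {
  max.col(fit$phi, ties.method = "first")
}

#' Cell-type correlation matrix of a sharing component
#'
#' Converts the posterior expected covariance `E[Sigma_k] =
#' B_k / (nu_k - C - 1)` into a correlation matrix, with rows and columns
#' ordered by average-linkage hierarchical clustering on `1 - correlation`.
#' By default the component with the largest responsibility mass is used.
#'
#' @param fit a fitted `share_fit`.
#' @param k component index; default: component with highest weight mass.
#' @return List with `correlation` (reordered C x C matrix), `order`
#'   (integer permutation), `component`, and `weight_mass`.
#' @export
component_correlation <- function(fit, k = NULL) {
  masses <- vapply(fit$components, `[[`, numeric(1), "weight_mass")
  if (is.null(k)) k <- which.max(masses)
  if (k < 1 || k > length(fit$components)) stop("component index out of range")
  ck <- fit$components[[k]]
  C <- length(ck$a)
  if (ck$nu <= C + 1)
    stop("nu (", ck$nu, ") <= C + 1: covariance expectation undefined")
  Sig <- ck$B / (ck$nu - C - 1)
  corr <- stats::cov2cor(Sig)
  dimnames(corr) <- list(fit$cell_types, fit$cell_types)
  ord <- seq_len(C)
  if (C > 2) {
    hc <- stats::hclust(stats::as.dist(1 - corr), method = "average")
    ord <- hc$order
  }
  list(correlation = corr[ord, ord, drop = FALSE], order = ord,
       component = k, weight_mass = masses[k])
}

#' Serialize a fitted sharing model to JSON
#'
#' Stores prior, config, component posteriors, and the ELBO trace in a
#' plain-text document; edge posteriors are omitted (revised scores are
#' exported separately as TSV).
#'
#' @param fit a fitted `share_fit`.
#' @param path output JSON path.
#' @export
write_fitted_model <- function(fit, path) {
  comps <- lapply(fit$components, function(ck)
    list(a = ck$a, beta = ck$beta, B = ck$B, nu = ck$nu,
         weight_mass = ck$weight_mass))
  jsonlite::write_json(
    list(cell_types = fit$cell_types,
         prior = list(mu0 = fit$prior$mu0, beta0 = fit$prior$beta0,
                      Psi = fit$prior$Psi, nu = fit$prior$nu),
         config = unclass(fit$config)[c("K", "max_iter", "rel_tol", "seed",
                                        "init", "link")],
         components = comps,
         elbo_trace = fit$elbo_trace,
         converged = isTRUE(fit$converged)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
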