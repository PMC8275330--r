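#' Configuration for the Bayesian variable-selection model
#'
#' @param sigma_eps2 observation noise variance; `NULL` (default) estimates
#'   it per target by method of moments (residual variance of the best
#'   single-regulator fit, floored at 10% of the target variance).
#' @param sigma_beta2 slab variance of included coefficients (default 1);
#'   scalar or one value per regulator (recycled).
#' @param pi prior inclusion probability used without sharing (default 0.1).
#' @param max_iter maximum outer sweeps (default 200).
#' @param rel_tol relative objective change declaring convergence.
#' @param seed RNG seed (controls sharing-layer initialisation).
#' @return Object of class `bvs_config`.
#' @export
bvs_config <- function(sigma_eps2 = NULL, sigma_beta2 = 1, pi = 0.1,
                       max_iter = 200, rel_tol = 1e-8, seed = 1) {
  if (!is.null(sigma_eps2) && sigma_eps2 <= 0) stop("sigma_eps2 must be > 0")
  if (any(sigma_beta2 <= 0)) stop("sigma_beta2 must be > 0")
  if (pi <= 0 || pi >= 1) stop("pi must be in (0, 1)")
  structure(list(sigma_eps2 = sigma_eps2, sigma_beta2 = sigma_beta2, pi = pi,
                 max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 seed = as.integer(seed)),
            class = "bvs_config")
}

# Jaakkola-Jordan variational bound coefficient for the logistic sigmoid.
.jj_lambda <- function(xi) {
  out <- xi
  out[] <- 0.125
  nz <- abs(xi) > 1e-8
  out[nz] <- tanh(xi[nz] / 2) / (4 * xi[nz])
  out
}

# One coordinate-ascent sweep over the p spike-and-slab coefficients of a
# single regression. `L` is the prior log-odds per coefficient. `Xw` is the
# current fitted vector X %*% (alpha * v); it is updated in place and
# returned. Coefficients are cycled in fixed index order (determinism).
.bvs_sweep <- function(X, y, d, alpha, v, s2, L, Xw, se2, sb2) {
  p <- ncol(X)
  for (i in seq_len(p)) {
    w_old <- alpha[i] * v[i]
    r <- sum(X[, i] * y) - sum(X[, i] * Xw) + d[i] * w_old
    s2[i] <- se2 / (d[i] + se2 / sb2[i])
    v[i] <- s2[i] * r / se2
    logit_a <- L[i] + 0.5 * log(s2[i] / sb2[i]) + v[i]^2 / (2 * s2[i])
    alpha[i] <- stats::plogis(logit_a)
    w_new <- alpha[i] * v[i]
    if (w_new != w_old) Xw <- Xw + X[, i] * (w_new - w_old)
  }
  list(alpha = alpha, v = v, s2 = s2, Xw = Xw)
}

# Variational objective of one regression given prior log-odds L
# (fixed-prior case: includes Bernoulli prior cross-entropy; sharing case:
# the gamma-prior term is accounted for in the z-layer bound instead, so
# `prior_term = FALSE` drops it here).
.bvs_elbo_regression <- function(X, y, d, alpha, v, s2, L, Xw, se2, sb2,
                                 prior_term = TRUE) {
  n <- length(y)
  rss <- sum((y - Xw)^2)
  var_infl <- sum(d * (alpha * (s2 + v^2) - (alpha * v)^2))
  ll <- -n / 2 * log(2 * pi * se2) - (rss + var_infl) / (2 * se2)
  slab <- sum(alpha * (1 + log(s2 / sb2) - (s2 + v^2) / sb2)) / 2
  ent <- -sum(ifelse(alpha > 0, alpha * log(alpha), 0) +
                ifelse(alpha < 1, (1 - alpha) * log(1 - alpha), 0))
  # fixed-prior cross-entropy: E[log p(gamma)] = alpha*L + log(1 - pi)
  # with L = logit(pi); log(1 - pi) = -(max(L,0) + log1p(exp(-|L|)))
  pri <- if (prior_term)
    sum(alpha * L - (pmax(L, 0) + log1p(exp(-abs(L))))) else 0
  ll + slab + ent + pri
}

# Jaakkola-bound expectation of log p(gamma | z) summed over entries:
# alpha*m - m/2 - lambda(xi)*(m^2 + Szz - xi^2) - log(1+e^xi) + xi/2
.jj_bound_term <- function(alpha, m, szz, xi) {
  lam <- .jj_lambda(xi)
  sum(alpha * m - m / 2 - lam * (m^2 + szz - xi^2) -
        log1p(exp(-abs(xi))) - pmax(xi, 0) + xi / 2)
}

#' Fit the spike-and-slab variable-selection model
#'
#' Models each (centred) target as a sparse linear combination of (centred)
#' regulators: `y = sum_i X_i beta_i gamma_i + eps`. Coefficients are
#' updated by coordinate-ascent variational inference. The inclusion prior
#' is either a fixed Bernoulli(`pi`) or — with `prior = "sharing"` — a
#' sigmoid-linked latent logit shared across cell types through the same
#' Normal-Wishart mixture used for edge-score sharing; the non-conjugate
#' sigmoid is handled with the Jaakkola-Jordan quadratic bound, which keeps
#' the joint objective a proper lower bound with monotone updates.
#'
#' @param data named list, one element per cell type, each a list with `X`
#'   (cells x regulators) and `Y` (cells x targets; a vector is treated as
#'   one target). Regulator/target counts must agree across cell types.
#' @param cfg a [bvs_config()].
#' @param prior `"fixed"` or `"sharing"`.
#' @param share_K mixture components for the sharing layer (default 1).
#' @return Object of class `bvs_fit` with per-cell-type `alpha`, `v`, `s2`
#'   (regulators x targets), `sigma_eps2`, the objective trace, and (for the
#'   sharing prior) the sharing-layer state.
#' @export
fit_bvs <- function(data, cfg = bvs_config(), prior = c("fixed", "sharing"),
                    share_K = 1) {
  prior <- match.arg(prior)
  C <- length(data)
  if (C == 0) stop("no cell types supplied")
  cts <- names(data)
  if (is.null(cts)) cts <- paste0("ct", seq_len(C))
  data <- lapply(data, function(d) {
    if (is.vector(d$Y)) d$Y <- matrix(d$Y, ncol = 1)
    d$X <- as.matrix(d$X); d$Y <- as.matrix(d$Y)
    if (nrow(d$X) != nrow(d$Y)) stop("X and Y row counts differ")
    if (nrow(d$X) < 2) stop("need at least 2 cells per cell type")
    if (!all(is.finite(d$X)) || !all(is.finite(d$Y)))
      stop("non-finite values in design or response")
    d$X <- scale(d$X, center = TRUE, scale = FALSE)
    d$Y <- scale(d$Y, center = TRUE, scale = FALSE)
    d
  })
  p <- ncol(data[[1]]$X)
  q <- ncol(data[[1]]$Y)
  if (!all(vapply(data, function(d) ncol(d$X) == p && ncol(d$Y) == q,
                  logical(1))))
    stop("regulator/target counts differ across cell types")
  sb2 <- rep(cfg$sigma_beta2, length.out = p)
  # per-(cell type, target) noise variance by method of moments
  se2 <- matrix(0, C, q)
  for (c in seq_len(C)) for (j in seq_len(q)) {
    if (!is.null(cfg$sigma_eps2)) { se2[c, j] <- cfg$sigma_eps2; next }
    y <- data[[c]]$Y[, j]
    vy <- stats::var(y)
    if (vy <= 0) { se2[c, j] <- 1e-6; next }
    X <- data[[c]]$X
    dX <- colSums(X^2)
    r2 <- ifelse(dX > 0, (crossprod(X, y)^2) / (dX * sum(y^2)), 0)
    se2[c, j] <- max(vy * (1 - max(r2)), 0.1 * vy)
  }
  N <- p * q                    # sharing-layer edges: (regulator, target)
  alpha <- array(cfg$pi, dim = c(p, q, C))
  v <- array(0, dim = c(p, q, C))
  s2 <- array(sb2, dim = c(p, q, C))  # recycles per regulator
  Xw <- lapply(seq_len(C), function(c) matrix(0, nrow(data[[c]]$X), q))
  dlist <- lapply(data, function(d) colSums(d$X^2))
  L_fixed <- stats::qlogis(cfg$pi)

  share <- NULL
  xi <- NULL
  if (prior == "sharing") {
    xi <- matrix(1, N, C)
    sp <- nw_prior(mu0 = rep(L_fixed, C), beta0 = 1e-3,
                   Psi = (C + 2) * diag(1, C), nu = C + 2)
    scfg <- model_config(K = share_K, max_iter = 1, seed = cfg$seed)
    pseudo <- .jj_pseudo_data(alpha, xi)
    share <- init_state(pseudo$stack, pseudo$noise, scfg, sp)
    share <- update_edges(share, pseudo$stack, pseudo$noise)
  }

  obj_prev <- -Inf
  trace <- numeric(0)
  for (it in seq_len(cfg$max_iter)) {
    # (1) coefficient updates given current prior log-odds
    for (c in seq_len(C)) for (j in seq_len(q)) {
      L <- if (prior == "sharing")
        share$M[(j - 1) * p + seq_len(p), c] else rep(L_fixed, p)
      up <- .bvs_sweep(data[[c]]$X, data[[c]]$Y[, j], dlist[[c]],
                       alpha[, j, c], v[, j, c], s2[, j, c], L,
                       Xw[[c]][, j], se2[c, j], sb2)
      alpha[, j, c] <- up$alpha; v[, j, c] <- up$v; s2[, j, c] <- up$s2
      Xw[[c]][, j] <- up$Xw
    }
    # (2) sharing-layer updates given inclusion probabilities
    if (prior == "sharing") {
      diag_idx <- (seq_len(C) - 1) * C + seq_len(C)
      pseudo <- .jj_pseudo_data(alpha, xi)
      share <- update_edges(share, pseudo$stack, pseudo$noise)
      share <- update_responsibilities(share, pseudo$stack)
      share <- update_components(share, pseudo$stack)
      xi <- sqrt(share$M^2 + share$S_flat[, diag_idx, drop = FALSE])
      # refresh edge posteriors under the new xi so prior log-odds for the
      # next coefficient sweep reflect the tightened bound
      pseudo <- .jj_pseudo_data(alpha, xi)
      share <- update_edges(share, pseudo$stack, pseudo$noise)
    }
    obj <- .bvs_objective(data, dlist, alpha, v, s2, Xw, se2, sb2,
                          prior, L_fixed, share, xi)
    trace <- c(trace, obj)
    if (is.finite(obj_prev) && abs(obj - obj_prev) <
        cfg$rel_tol * max(1, abs(obj_prev))) break
    obj_prev <- obj
  }
  structure(list(alpha = alpha, v = v, s2 = s2, sigma_eps2 = se2,
                 sigma_beta2 = sb2, cell_types = cts, prior = prior,
                 objective_trace = trace, share = share, config = cfg,
                 p = p, q = q),
            class = "bvs_fit")
}

# Pseudo edge-score stack/noise encoding the Jaakkola bound: each (edge,
# cell type) contributes a Gaussian pseudo-observation on z with precision
# 2*lambda(xi) and natural mean (alpha - 1/2).
.jj_pseudo_data <- function(alpha, xi) {
  p <- dim(alpha)[1]; q <- dim(alpha)[2]; C <- dim(alpha)[3]
  amat <- matrix(aperm(alpha, c(1, 2, 3)), p * q, C)
  prec <- 2 * .jj_lambda(xi)
  e <- (amat - 0.5) / prec
  stack <- edge_score_stack(e, cell_types = paste0("ct", seq_len(C)))
  noise <- list(std = 1 / sqrt(prec),
                missing = matrix(FALSE, p * q, C))
  list(stack = stack, noise = noise)
}

# Joint variational objective (a proper lower bound in both prior modes).
.bvs_objective <- function(data, dlist, alpha, v, s2, Xw, se2, sb2,
                           prior, L_fixed, share, xi) {
  C <- length(data); q <- ncol(data[[1]]$Y); p <- dim(alpha)[1]
  total <- 0
  for (c in seq_len(C)) for (j in seq_len(q)) {
    L <- if (prior == "sharing")
      share$M[(j - 1) * p + seq_len(p), c] else rep(L_fixed, p)
    total <- total + .bvs_elbo_regression(
      data[[c]]$X, data[[c]]$Y[, j], dlist[[c]],
      alpha[, j, c], v[, j, c], s2[, j, c], L, Xw[[c]][, j],
      se2[c, j], sb2, prior_term = (prior == "fixed"))
  }
  if (prior == "sharing") {
    N <- p * q
    diag_idx <- (seq_len(C) - 1) * ncol(share$M) + seq_len(ncol(share$M))
    amat <- matrix(alpha, N, C)
    szz <- share$S_flat[, diag_idx, drop = FALSE]
    total <- total + .jj_bound_term(amat, share$M, szz, xi)
    # sharing-layer prior/entropy terms (everything except the
    # pseudo-likelihood, which the bound term above replaces)
    logrho <- .expected_log_density(share)
    phi <- share$phi
    K <- ncol(phi)
    total <- total + sum(phi * logrho) - N * log(K) -
      sum(phi[phi > 0] * log(phi[phi > 0])) +
      sum(0.5 * (C * log(2 * pi * exp(1)) + share$logdetS)) +
      .nw_kl_term(share)
  }
  total
}

# Sum over components of E[log p(mu,Lambda)] - E[log q(mu,Lambda)].
.nw_kl_term <- function(state) {
  prior <- state$prior
  C <- length(prior$mu0)
  pd <- .spd_inv_logdet(prior$Psi, "prior Psi")
  logB_prior <- .log_wishart_B(pd$logdet, prior$nu, C)
  out <- 0
  for (k in seq_along(state$components)) {
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
    out <- out + e_logp - e_logq
  }
  out
}

#' Posterior inclusion probabilities as edge scores
#'
#' Exports the fitted inclusion probabilities in the same layout as an
#' [edge_score_stack()] column set: one row per (regulator, target) pair
#' (regulator index moving fastest), one column per cell type.
#'
#' @param fit a [fit_bvs()] result.
#' @return Numeric matrix, `p*q` rows x C columns.
#' @export
posterior_inclusion <- function(fit) {
  stopifnot(inherits(fit, "bvs_fit"))
  out <- matrix(fit$alpha, fit$p * fit$q, length(fit$cell_types))
  colnames(out) <- fit$cell_types
  out
}

#' Holdout log likelihood under the posterior predictive
#'
#' For each (cell type, target), the mean per-cell log density of the
#' moment-matched Gaussian predictive: mean `X_test (alpha * v)`, variance
#' `sigma_eps2 + sum_i X_i^2 (alpha_i (s2_i + v_i^2) - (alpha_i v_i)^2)`.
#' Test columns are centred with the training means implicitly (the model
#' was fitted on centred data, so the caller passes test data on the same
#' scale; `center` recentres using the test set itself when TRUE).
#'
#' @param fit a [fit_bvs()] result.
#' @param test named list matching `fit$cell_types`: each a list with `X`
#'   and `Y` for held-out cells.
#' @param center centre test X and Y columns (default TRUE).
#' @return data.frame with columns `cell_type`, `target`, `n_test`,
#'   `mean_loglik`.
#' @export
holdout_log_likelihood <- function(fit, test, center = TRUE) {
  stopifnot(inherits(fit, "bvs_fit"))
  rows <- list()
  for (c in seq_along(fit$cell_types)) {
    d <- test[[c]]
    if (is.vector(d$Y)) d$Y <- matrix(d$Y, ncol = 1)
    X <- as.matrix(d$X); Y <- as.matrix(d$Y)
    if (nrow(X) == 0) stop("empty test set for cell type ",
                           fit$cell_types[c])
    if (center) {
      X <- scale(X, center = TRUE, scale = FALSE)
      Y <- scale(Y, center = TRUE, scale = FALSE)
    }
    X2 <- X^2
    for (j in seq_len(fit$q)) {
      a <- fit$alpha[, j, c]; vv <- fit$v[, j, c]; ss <- fit$s2[, j, c]
      w <- a * vv
      mu <- as.numeric(X %*% w)
      pv <- fit$sigma_eps2[c, j] +
        as.numeric(X2 %*% (a * (ss + vv^2) - w^2))
      ll <- stats::dnorm(Y[, j], mean = mu, sd = sqrt(pv), log = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        cell_type = fit$cell_types[c], target = j, n_test = nrow(X),
        mean_loglik = mean(ll), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
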