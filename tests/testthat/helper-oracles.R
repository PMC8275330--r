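# Independent oracles and small fixture builders shared across tests.
# These deliberately use naive loops / enumeration, not the package's own
# code paths.

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Brute-force average-precision PR area: walk every distinct threshold.
pr_area_oracle <- function(scores, labels) {
  scores[is.na(scores)] <- -Inf
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels)
  prev_recall <- 0
  area <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel])
    precision <- tp / sum(sel)
    recall <- tp / n_pos
    area <- area + precision * (recall - prev_recall)
    prev_recall <- recall
  }
  area
}

# Direct re-statement of the verbal edge-dynamics definitions.
dynamics_oracle <- function(pattern, max_flips = 4) {
  T_ <- length(pattern)
  flips <- sum(pattern[-1] != pattern[-T_])
  if (flips > max_flips) return("unstable")
  if (T_ >= 3 && flips == 1 && !pattern[1]) return("stably_added")
  if (T_ >= 3 && flips == 1 && pattern[1]) return("stably_removed")
  "other"
}

# Exact one-sided signed-rank p-value by enumerating all 2^n sign patterns.
signed_rank_oracle <- function(a, b) {
  d <- (a - b)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- signs %*% r
  mean(W_all >= W_obs - 1e-12)
}

# All permutations of 1..n (recursive, n small).
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Random SPD matrix with unit-ish scale.
random_spd <- function(C, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(C * C), C)
  crossprod(A) / C + diag(C) * 0.5
}

# Tiny synthetic score/noise pair without using simulate_sharing.
tiny_stack <- function(N = 20, C = 3, seed = 1) {
  set.seed(seed)
  e <- matrix(rnorm(N * C), N, C)
  std <- matrix(runif(N * C, 0.3, 1), N, C)
  list(stack = edge_score_stack(e),
       noise = list(std = std, missing = matrix(FALSE, N, C)))
}

# Exact log marginal likelihood of e ~ N(mu, Sigma + D) per edge.
gaussian_evidence <- function(e, mu, Sigma, std) {
  S <- Sigma + diag(std^2, length(std))
  C <- length(e)
  -0.5 * (C * log(2 * pi) + as.numeric(determinant(S)$modulus) +
            as.numeric(t(e - mu) %*% solve(S, e - mu)))
}

# Exact posterior inclusion probabilities of a spike-and-slab linear model
# by enumerating all 2^p support configurations (conjugate evidence).
exact_pip <- function(X, y, se2, sb2, pi0) {
  X <- scale(X, scale = FALSE)
  y <- y - mean(y)
  p <- ncol(X)
  n <- nrow(X)
  logev <- function(g) {
    idx <- which(g == 1)
    base <- -n / 2 * log(2 * pi * se2) - sum(y^2) / (2 * se2)
    if (length(idx) == 0) return(base)
    Xs <- X[, idx, drop = FALSE]
    A <- crossprod(Xs) / se2 + diag(1 / sb2, length(idx))
    b <- crossprod(Xs, y) / se2
    base + 0.5 * sum(b * solve(A, b)) -
      0.5 * as.numeric(determinant(A)$modulus) -
      length(idx) / 2 * log(sb2)
  }
  configs <- as.matrix(expand.grid(rep(list(0:1), p)))
  lp <- apply(configs, 1, function(g)
    logev(g) + sum(g) * log(pi0) + sum(1 - g) * log(1 - pi0))
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  as.numeric(colSums(configs * w))
}

# Build a frozen single-component state whose expected precision is exactly
# solve(Sigma) and expected mean is mu (used by conjugate-oracle tests).
frozen_component_state <- function(stack, noise, mu, Sigma, nu = 50,
                                   beta = 1e8) {
  state <- init_state(stack, noise, model_config(K = 1, seed = 1),
                      nw_prior(mu, 1, nu * Sigma, nu))
  state$components[[1]] <- list(a = mu, beta = beta, B = nu * Sigma, nu = nu,
                                weight_mass = nrow(stack$scores))
  state$comp_exp <- NULL
  state
}
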