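test_that("default_nw_prior reproduces the empirical diagonal covariance", {
  set.seed(21)
  N <- 200; C <- 4
  e <- matrix(rnorm(N * C, sd = rep(c(1, 2, 0.5, 3), each = N)), N, C)
  stack <- edge_score_stack(e)
  pr <- default_nw_prior(stack)
  expect_equal(pr$nu, C + 2)
  expect_equal(pr$mu0, colMeans(e), tolerance = 1e-12)
  # Wishart identity: E[Sigma] = Psi / (nu - C - 1)
  expect_lt(max(abs(pr$Psi / (pr$nu - C - 1) - diag(apply(e, 2, var)))),
            1e-10)
  # standardized scores -> mu0 = 0, Psi = nu * I
  z <- scale(e)
  attr(z, "scaled:center") <- attr(z, "scaled:scale") <- NULL
  przd <- default_nw_prior(edge_score_stack(z))
  expect_equal(przd$mu0, rep(0, C), tolerance = 1e-12)
  expect_equal(przd$Psi, (przd$nu - C - 1) * diag(C), tolerance = 1e-8)
  expect_equal(default_nw_prior(edge_score_stack(matrix(rnorm(40), 20, 2)))$nu, 4)
})

test_that("init_state is deterministic and recovers planted clusters", {
  tf <- tiny_stack(N = 40, C = 3, seed = 2)
  s1 <- init_state(tf$stack, tf$noise, model_config(K = 1, seed = 5))
  expect_true(all(s1$phi == 1))
  # planted two-cluster instance
  set.seed(8)
  e <- rbind(matrix(rnorm(30 * 3, mean = 5, sd = 0.2), 30, 3),
             matrix(rnorm(30 * 3, mean = -5, sd = 0.2), 30, 3))
  planted <- rep(1:2, each = 30)
  stack <- edge_score_stack(e)
  noise <- list(std = matrix(0.5, 60, 3), missing = matrix(FALSE, 60, 3))
  st <- init_state(stack, noise, model_config(K = 2, seed = 3))
  expect_equal(ari(max.col(st$phi), planted), 1)
  st2 <- init_state(stack, noise, model_config(K = 2, seed = 3))
  expect_identical(st$phi, st2$phi)
  expect_error(init_state(stack, noise, model_config(K = 100, seed = 1)),
               "exceeds")
})

test_that("update_edges obeys data- and prior-dominated limits and the
           conjugate closed form", {
  set.seed(31)
  C <- 4; N <- 60
  mu <- rnorm(C)
  Sigma <- random_spd(C, 31)
  e <- matrix(rnorm(N * C), N, C)
  stack <- edge_score_stack(e)
  # sigma -> 0: posterior mean -> observed scores
  tiny <- list(std = matrix(1e-9, N, C), missing = matrix(FALSE, N, C))
  st <- frozen_component_state(stack, tiny, mu, Sigma)
  st <- update_edges(st, stack, tiny)
  expect_lt(max(abs(st$M - e)), 1e-6)
  # sigma -> inf with K=1: posterior mean -> component mean
  huge <- list(std = matrix(1e9, N, C), missing = matrix(FALSE, N, C))
  st <- frozen_component_state(stack, huge, mu, Sigma)
  st <- update_edges(st, stack, huge)
  expect_lt(max(abs(sweep(st$M, 2, mu))), 1e-6)
  # closed form (Sigma^-1 + D^-1)^-1 (Sigma^-1 mu + D^-1 e) within 1e-8
  std <- matrix(runif(N * C, 0.2, 1.5), N, C)
  noise <- list(std = std, missing = matrix(FALSE, N, C))
  st <- frozen_component_state(stack, noise, mu, Sigma)
  st <- update_edges(st, stack, noise)
  Sinv <- solve(Sigma)
  for (n in seq_len(N)) {
    D <- diag(1 / std[n, ]^2)
    m_exact <- solve(Sinv + D, Sinv %*% mu + D %*% e[n, ])
    expect_lt(max(abs(st$M[n, ] - m_exact)), 1e-8)
  }
})

test_that("update_responsibilities: symmetry, dominance, and MC oracle", {
  tf <- tiny_stack(N = 20, C = 3, seed = 7)
  st <- init_state(tf$stack, tf$noise, model_config(K = 2, seed = 1))
  st <- update_edges(st, tf$stack, tf$noise)
  # identical component posteriors -> uniform responsibilities
  st_sym <- st
  st_sym$components[[2]] <- st_sym$components[[1]]
  st_sym$comp_exp <- NULL
  st_sym <- update_responsibilities(st_sym, tf$stack)
  expect_lt(max(abs(st_sym$phi - 0.5)), 1e-12)
  # rows renormalize to 1 within 1e-10
  st_r <- update_responsibilities(st, tf$stack)
  expect_lt(max(abs(rowSums(st_r$phi) - 1)), 1e-10)
  # dominance: one concentrated component centred at m, the other far away
  C <- 3; nu_big <- 1e6
  st_dom <- st
  st_dom$components[[1]] <- list(a = st$M[1, ], beta = 1e6,
                                 B = nu_big * diag(1e-4, C), nu = nu_big,
                                 weight_mass = 10)
  st_dom$components[[2]] <- list(a = st$M[1, ] + 100, beta = 1e6,
                                 B = nu_big * diag(1e-4, C), nu = nu_big,
                                 weight_mass = 10)
  st_dom$comp_exp <- NULL
  st_dom <- update_responsibilities(st_dom, tf$stack)
  expect_gt(st_dom$phi[1, 1], 1 - 1e-10)
  # Monte Carlo oracle for E_q[log N(z | mu_k, Sigma_k)] on 3 edges
  st <- update_components(update_responsibilities(st, tf$stack), tf$stack)
  st <- update_edges(st, tf$stack, tf$noise)
  logrho <- edgeshare:::.expected_log_density(st)
  set.seed(99)
  R <- 2e5
  for (k in 1:2) {
    ck <- st$components[[k]]
    W <- stats::rWishart(R, df = ck$nu, Sigma = solve(ck$B))
    eld <- apply(W, 3, function(w) determinant(w)$modulus)
    for (n in 1:3) {
      Sn <- matrix(st$S_flat[n, ], C, C)
      dv <- st$M[n, ] - ck$a
      # E[(z - mu)' Lam (z - mu) | Lam] = dv'Lam dv + tr(Lam Sn) + C/beta
      quad <- apply(W, 3, function(w)
        sum(dv * (w %*% dv)) + sum(w * Sn)) + C / ck$beta
      draws <- 0.5 * eld - C / 2 * log(2 * pi) - 0.5 * quad
      se <- sd(draws) / sqrt(R)
      expect_lt(abs(mean(draws) - logrho[n, k]), 3 * se + 1e-8)
    }
  }
})

test_that("update_components: conjugate degeneracies and prior reset", {
  tf <- tiny_stack(N = 15, C = 3, seed = 12)
  prior <- nw_prior(rep(0, 3), 1e-12, diag(3) * 5, 6)
  st <- init_state(tf$stack, tf$noise, model_config(K = 2, seed = 2), prior)
  # all mass on component 1 with S = 0 and beta0 -> 0: a = mean of M
  st$phi <- cbind(rep(1, 15), rep(0, 15))
  st$S_flat <- matrix(0, 15, 9)
  expect_message(st <- update_components(st, tf$stack), "reset to prior")
  expect_equal(st$components[[1]]$a, colMeans(st$M), tolerance = 1e-9)
  # empty component equals the prior exactly
  ck <- st$components[[2]]
  expect_identical(ck$B, prior$Psi)
  expect_equal(ck$nu, prior$nu)
  # B SPD for a random responsibility matrix
  set.seed(4)
  st$phi <- matrix(runif(30), 15, 2)
  st$phi <- st$phi / rowSums(st$phi)
  st <- update_components(st, tf$stack)
  for (k in 1:2)
    expect_true(all(eigen(st$components[[k]]$B, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
})

test_that("ELBO equals the exact conjugate evidence when nothing is shared", {
  set.seed(41)
  C <- 3; N <- 5
  mu <- rnorm(C)
  Sigma <- random_spd(C, 41)
  e <- matrix(rnorm(N * C), N, C)
  std <- matrix(runif(N * C, 0.3, 1), N, C)
  stack <- edge_score_stack(e)
  noise <- list(std = std, missing = matrix(FALSE, N, C))
  # freeze q(mu, Lambda) at a near-point-mass prior => KL term vanishes and
  # the optimal q(z) makes the ELBO the exact log marginal likelihood
  nu <- 1e8
  pr <- nw_prior(mu, 1e8, nu * Sigma, nu)
  st <- init_state(stack, noise, model_config(K = 1, seed = 1), pr)
  st$components[[1]] <- list(a = mu, beta = 1e8, B = nu * Sigma, nu = nu,
                             weight_mass = N)
  st$comp_exp <- NULL
  st <- update_edges(st, stack, noise)
  elbo <- compute_elbo(st, stack, noise)
  exact <- sum(vapply(seq_len(N), function(n)
    gaussian_evidence(e[n, ], mu, Sigma, std[n, ]), numeric(1)))
  expect_lt(abs(elbo - exact), 1e-6 * abs(exact))
})

test_that("each coordinate update does not decrease the ELBO and updates are
           local optima (finite differences)", {
  tf <- tiny_stack(N = 5, C = 2, seed = 3)
  st <- init_state(tf$stack, tf$noise, model_config(K = 2, seed = 6))
  st <- update_edges(st, tf$stack, tf$noise)
  el <- compute_elbo(st, tf$stack, tf$noise)
  for (step in 1:3) {
    st <- update_edges(st, tf$stack, tf$noise)
    e1 <- compute_elbo(st, tf$stack, tf$noise)
    expect_gte(e1, el - 1e-8 * abs(el)); el <- e1
    st <- update_responsibilities(st, tf$stack)
    e2 <- compute_elbo(st, tf$stack, tf$noise)
    expect_gte(e2, el - 1e-8 * abs(el)); el <- e2
    st <- update_components(st, tf$stack)
    e3 <- compute_elbo(st, tf$stack, tf$noise)
    expect_gte(e3, el - 1e-8 * abs(el)); el <- e3
  }
  # finite-difference probes: each family is brought to its conditional
  # optimum first; perturbing it away then lowers the ELBO
  for (d in c(-0.05, 0.05)) {
    st_m <- update_edges(st, tf$stack, tf$noise)
    base_m <- compute_elbo(st_m, tf$stack, tf$noise)
    stp <- st_m; stp$M[2, 1] <- stp$M[2, 1] + d
    expect_lt(compute_elbo(stp, tf$stack, tf$noise), base_m)
    st_p <- update_responsibilities(st, tf$stack)
    base_p <- compute_elbo(st_p, tf$stack, tf$noise)
    stp <- st_p
    stp$phi[3, ] <- pmin(pmax(stp$phi[3, ] + c(d, -d), 1e-9), 1)
    stp$phi[3, ] <- stp$phi[3, ] / sum(stp$phi[3, ])
    expect_lte(compute_elbo(stp, tf$stack, tf$noise), base_p + 1e-10)
    st_c <- update_components(st, tf$stack)
    base_c <- compute_elbo(st_c, tf$stack, tf$noise)
    stp <- st_c; stp$components[[1]]$a <- stp$components[[1]]$a + d
    stp$comp_exp <- NULL
    expect_lt(compute_elbo(stp, tf$stack, tf$noise), base_c)
  }
})

test_that("fit_share_model: one-sweep mode, determinism, monotone traces", {
  tf <- tiny_stack(N = 30, C = 3, seed = 9)
  one <- fit_share_model(tf$stack, tf$noise,
                         model_config(K = 2, rel_tol = 1e6, seed = 2,
                                      max_iter = 50))
  expect_equal(length(one$elbo_trace), 2)  # needs two sweeps to compare
  f1 <- fit_share_model(tf$stack, tf$noise, model_config(K = 2, seed = 2))
  f2 <- fit_share_model(tf$stack, tf$noise, model_config(K = 2, seed = 2))
  expect_identical(f1$elbo_trace, f2$elbo_trace)
  # property: monotone ELBO across random instances and seeds
  for (s in 1:5) {
    inst <- tiny_stack(N = 25, C = 3, seed = 100 + s)
    f <- fit_share_model(inst$stack, inst$noise,
                         model_config(K = 3, seed = s, max_iter = 40))
    tr <- f$elbo_trace
    expect_true(all(diff(tr) >= -1e-8 * abs(tr[-length(tr)])), label = s)
  }
})

test_that("revised_scores denoise and never produce NaN on missing entries", {
  # C = 1, K = 1, near-flat prior and noise << score spread:
  # revised ~ observed (nothing to share, data dominates)
  set.seed(13)
  e <- matrix(rnorm(40), 40, 1)
  stack <- edge_score_stack(e)
  noise <- list(std = matrix(0.05, 40, 1), missing = matrix(FALSE, 40, 1))
  pr <- nw_prior(0, 1e-9, matrix(1e-6), 2.2)
  f <- fit_share_model(stack, noise, model_config(K = 1, seed = 1,
                                                  max_iter = 10), pr)
  rv <- revised_scores(f)
  expect_lt(max(abs(rv$scores - e)), 0.05)
  # two perfectly correlated cell types in truth, one column extra-noisy
  set.seed(14)
  z <- rnorm(300)
  truth <- cbind(z, z)
  obs <- truth + cbind(rnorm(300, sd = 0.1), rnorm(300, sd = 1.0))
  st2 <- edge_score_stack(obs)
  no2 <- list(std = cbind(rep(0.1, 300), rep(1.0, 300)),
              missing = matrix(FALSE, 300, 2))
  f2 <- fit_share_model(st2, no2, model_config(K = 1, seed = 1))
  err_obs <- sqrt(sum((obs[, 2] - z)^2))
  err_rev <- sqrt(sum((revised_scores(f2)$scores[, 2] - z)^2))
  expect_lt(err_rev, err_obs)
  # missing entries are revised, never NaN
  obs_na <- obs; obs_na[1:50, 2] <- NA
  st3 <- edge_score_stack(obs_na)
  no3 <- no2; no3$std[1:50, 2] <- NA; no3$missing <- st3$missing
  f3 <- fit_share_model(st3, no3, model_config(K = 1, seed = 1))
  expect_false(anyNA(revised_scores(f3)$scores))
  # a missing entry is pulled toward the truth by the observed column
  expect_lt(mean(abs(revised_scores(f3)$scores[1:50, 2] - z[1:50])),
            mean(abs(obs[1:50, 2] - z[1:50])))
})

test_that("edge-order permutation equivariance", {
  tf <- tiny_stack(N = 30, C = 3, seed = 17)
  f <- fit_share_model(tf$stack, tf$noise, model_config(K = 2, seed = 4,
                                                        max_iter = 20))
  perm <- sample(30)
  stack_p <- edge_score_stack(tf$stack$scores[perm, ])
  noise_p <- list(std = tf$noise$std[perm, ],
                  missing = tf$noise$missing[perm, ])
  # same initial responsibilities, permuted
  st0 <- init_state(tf$stack, tf$noise, model_config(K = 2, seed = 4))
  st0p <- st0
  st0p$phi <- st0$phi[perm, ]; st0p$M <- st0$M[perm, ]
  st0p$S_flat <- st0$S_flat[perm, ]; st0p$logdetS <- st0$logdetS[perm]
  st0p <- update_components(st0p, stack_p)
  a <- update_edges(st0, tf$stack, tf$noise)
  b <- update_edges(st0p, stack_p, noise_p)
  expect_equal(b$M, a$M[perm, ], tolerance = 1e-10)
})

test_that("component_correlation is a valid, cluster-ordered correlation", {
  tf <- tiny_stack(N = 40, C = 4, seed = 19)
  f <- fit_share_model(tf$stack, tf$noise, model_config(K = 2, seed = 3,
                                                        max_iter = 15))
  cc <- component_correlation(f)
  expect_equal(diag(cc$correlation), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(abs(cc$correlation) <= 1 + 1e-12))
  expect_equal(cc$correlation, t(cc$correlation))
  # diagonal B -> identity correlation
  fd <- f
  fd$components[[1]]$B <- diag(4) * 10
  fd$components[[1]]$nu <- 12
  ccd <- component_correlation(fd, k = 1)
  expect_equal(ccd$correlation, diag(4), ignore_attr = TRUE)
  bad <- f; bad$components[[1]]$nu <- 4
  expect_error(component_correlation(bad, k = 1), "undefined")
})

test_that("planted block covariance is recovered in the top component", {
  blocks <- list(1:3, 4:6)
  sim <- simulate_sharing(N = 800, C = 6, K = 1, separation = 0,
                          noise_levels = 0.3, rho = 0.8, blocks = blocks,
                          seed = 23)
  f <- fit_share_model(sim$stack, sim$noise, model_config(K = 1, seed = 1))
  cc <- component_correlation(f)
  corr <- cc$correlation[order(cc$order), order(cc$order)]  # undo reordering
  within <- c(corr[1:3, 1:3][upper.tri(diag(3))],
              corr[4:6, 4:6][upper.tri(diag(3))])
  between <- corr[1:3, 4:6]
  expect_gt(mean(within), mean(between))
})
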