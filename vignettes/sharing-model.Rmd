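---
title: "Sharing edge scores across cell types: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sharing edge scores across cell types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgeshare)
```

## The model and its assumptions

A base network inference method applied separately to each of C cell types
produces, for every directed regulator→target edge *n*, a vector of
observed scores $e_n \in \mathbb{R}^C$. We treat these as noisy readouts of
latent true scores $z_n$ whose joint law across cell types is a K-component
Gaussian mixture:

$$u_n \sim \mathrm{Cat}(1/K,\dots,1/K), \qquad
  z_n \mid u_n = k \sim \mathcal{N}(\mu_k, \Sigma_k), \qquad
  e_n^{(c)} \sim \mathcal{N}\!\big(z_n^{(c)}, \sigma_n^{(c)2}\big),$$

with a conjugate Normal–Wishart prior
$(\mu_k, \Sigma_k^{-1}) \sim \mathrm{NW}(\mu_0, \beta_0, \Psi, \nu)$ on each
component. Each $\Sigma_k$ is a *sharing pattern*: its off-diagonal entries
say how strongly an edge's scores co-vary between two cell types, so an
edge assigned to a near-diagonal component is effectively cell
type-specific while one assigned to a dense component borrows strength
globally. Learning a *mixture* of patterns, rather than one, lets different
edges share along different cell-type subsets.

Key assumptions, and when they are reasonable:

* **Gaussian observation noise per edge score.** Approximately true for
  correlation-based scores and for rank-ish scores from ensemble methods at
  moderate cell counts; it degrades for scores pinned near a boundary
  (e.g. |r| near 0 with absolute-value scoring).
* **Noise scale known, not inferred.** $\sigma_n^{(c)}$ is plugged in from
  a cell-level bootstrap (below). The model does not propagate uncertainty
  in $\sigma$ itself.
* **Edges are exchangeable given their component.** No use of network
  topology, gene identity, or shared-regulator structure.
* **One edge universe across cell types.** An edge unscorable in one cell
  type (constant or unexpressed gene) is *missing* there and contributes no
  likelihood term — probabilistically equivalent to infinite noise — while
  its other cell types still inform the shared posterior.

## Inference

The posterior is approximated by mean-field variational inference with the
factorization $q = \prod_k q(\mu_k,\Sigma_k^{-1}) \prod_n q(z_n)\,q(u_n)$,
where $q(\mu_k,\Sigma_k^{-1})$ is Normal–Wishart, $q(z_n)$ Gaussian and
$q(u_n)$ categorical. All coordinate updates are conjugate and closed-form:

* $q(z_n)$: precision $\Lambda_n = \sum_k \tilde\varphi_{nk}
  \mathbb{E}[\Sigma_k^{-1}] + D_n^{-1}$ with $D_n =
  \mathrm{diag}(\sigma_n^2)$ (zero precision at missing entries), mean
  $\tilde m_n = \Lambda_n^{-1}(\sum_k \tilde\varphi_{nk}
  \mathbb{E}[\Sigma_k^{-1}\mu_k] + D_n^{-1} e_n)$.
* $q(u_n)$: $\log \tilde\varphi_{nk} \propto
  \mathbb{E}[\log \mathcal{N}(z_n \mid \mu_k, \Sigma_k)]$, normalized by
  log-sum-exp; the uniform mixture prior adds no tilt.
* $q(\mu_k, \Sigma_k^{-1})$: the standard responsibility-weighted
  Normal–Wishart update, using both moments of $q(z_n)$. The scale update is
  per-component ($\tilde\beta_k = \beta_0 + N_k$); a component that loses
  all mass is reset to the prior rather than pruned, keeping K fixed and the
  ELBO well defined.

Because every update exactly maximizes the ELBO in its coordinate block, the
ELBO is monotone; `fit_share_model()` records the trace and the test suite
asserts monotonicity on every fit it runs. Correctness of the update
algebra is pinned down by three independent oracles: an exact conjugate
closed form (single frozen component), the exact log marginal likelihood in
the unshared K = 1 limit, and finite-difference local-optimality probes of
each variational block. The revised edge scores are the posterior means
$\tilde m_n$; $\mathbb{E}[\Sigma_k] = \tilde B_k/(\tilde\nu_k - C - 1)$
gives the reportable sharing patterns as correlation matrices, ordered by
average-linkage clustering on $1 - \text{correlation}$.

## Tunable parameters

| parameter | default | meaning / why this default |
|---|---|---|
| `K` (components) | 10 | enough diversity of sharing patterns for tens of cell types; performance is flat in K once K > 1, so K is a knob, not a tuning burden |
| bootstrap trials M | 5 | per-edge score standard deviations stabilise after ~5 cell-resampling rounds for correlation-type scorers |
| `rel_tol` | 1e-6 | relative ELBO change declaring convergence; typical CAVI practice |
| `max_iter` | 500 | safety cap; fits in this package's tests converge in 5–60 sweeps |
| `beta0` | 1e-3 | near-flat prior on component means |
| `nu` | C + 2 | smallest dof with a finite covariance expectation |
| `Psi` | (ν−C−1)·diag(empirical per-cell-type score variances) | makes the prior expected covariance exactly the empirical diagonal; the data overwhelm it after a few hundred edges |
| noise floor | max(1e-6, 1st percentile of positive stds) | a literally-zero bootstrap std would give an improper likelihood; the percentile floor leaves informative edges untouched |
| BVS `pi` | 0.1 | prior edge density when no sharing layer is used |
| BVS `sigma_beta2` | 1 | slab variance on standardized expression; scalar or per-regulator (the per-regulator form makes the column-scaling contract exact) |
| BVS `sigma_eps2` | method of moments | residual variance of the best single-regulator fit, floored at 10% of the target variance |

Design choices made where the design was genuinely open:

* **Dispersion statistic** for highly-variable-gene selection: Fano factor
  (variance/mean) of transformed expression pooled across all cells;
  deterministic, with a per-cell-type-maximum variant behind a flag. The
  pooled form is the default because gene selection must produce one edge
  universe for all cell types.
* **Absolute-value Pearson scores** by default, so the built-in scorer is
  comparable with the non-negative importances of tree- and
  information-based methods; signed scores are available via
  `absolute = FALSE`.
* **Initialisation**: k-means on mean-imputed score rows (seeded), one
  component update, edge means at the observed scores. Deterministic under
  the seed; a `"random"` init is available.
* **Raw scores are shared, not standardized scores**; per-cell-type
  standardization can be applied upstream if score scales differ wildly
  between cell types (the prior's empirical diagonal absorbs moderate scale
  differences).
* **PR area convention**: average precision (step interpolation), because
  trapezoidal interpolation overestimates PR area; tied scores collapse
  into one threshold group so the result is order-independent. The same
  convention is applied to all methods being compared, so ratios are
  internally consistent.
* **Signed-rank test**: exact null distribution (rank convolution) for
  n ≤ 25 without ties, otherwise the normal approximation with continuity
  and tie corrections.
* **Stably added/removed definitions**: exactly-one-flip patterns with the
  required start state; a single active (or inactive) suffix step suffices,
  which is the tightest fully-testable reading of "emerges and is stably
  maintained".
* **BVS sigmoid non-conjugacy**: Jaakkola–Jordan quadratic bound. The bound
  keeps the joint objective a true lower bound with monotone updates (the
  inclusion-probability update needs no bound at all, since
  $\mathbb{E}[\mathrm{logit}\,g(z)] = \tilde m$ exactly); accuracy is
  checked against exhaustive 2^p enumeration of the exact posterior.
* **Predictive likelihood**: the exact posterior predictive is a 2^p
  mixture, so a moment-matched Gaussian is used; the enumeration oracle
  bounds its error at small p.

## What the synthetic generators emulate — and what they do not

`simulate_sharing()` draws from exactly the generative process above:
planted component assignments, controllable mean separation (in units of
within-component standard deviation), exchangeable or block cell-type
correlation, heteroscedastic Gaussian noise (Uniform(0.5, 1.5) × a base
level, the kind of 2–3× spread in noise scale the bootstrap typically
reports), and completely-at-random missingness. `simulate_expression()`
realises the BVS linear model on the transformed scale with standard
Gaussian regulators, optionally back-transformed to CPM-like counts.
`simulate_chain()` plants dynamics patterns by family.

They deliberately do **not** emulate: scRNA-seq count noise beyond the
model's own assumptions (no dropout, no overdispersion, no library-size
variation), structured missingness, network topology (no hubs, no shared
regulators inducing correlated scores between edges), or non-Gaussian score
noise. A green recovery test therefore establishes that the inference
machinery is correct *under the model's assumptions* — it does not
establish that real scRNA-seq edge scores satisfy those assumptions. The
noise standard deviations are reported exactly (oracle mode); the
pipeline-style alternative — re-estimating them by bootstrap — is exercised
end-to-end by composing `simulate_expression()`, `pearson_scores()` and
`bootstrap_edge_std()`.

## Numerical notes

* All SPD work goes through Cholesky factorizations; a non-SPD component
  scale or edge precision raises an error naming the offender rather than
  silently regularizing.
* Responsibilities are computed in log space with log-sum-exp; an all-zero
  row is treated as an implementation bug and raises.
* Ties: dispersion ranking breaks ties lexicographically by gene symbol;
  top-fraction binarization breaks ties by edge-universe order; equal AUPRC
  scores form one threshold group.
* Degenerate inputs: constant genes score 0 and are flagged missing;
  constant min–max trajectories normalize to 0.5; empty mixture components
  reset to the prior; zero bootstrap stds are floored.
* Seeds: every stochastic routine takes or derives a seed
  (`derive_seed(master, key)`, kept below 2^31), so per-cell-type work is
  order-independent and whole pipelines are byte-reproducible — asserted by
  an end-to-end determinism test.

## Known limitations

* CAVI finds a local optimum; with poorly separated components the
  component labels (not the revised scores) can vary across seeds.
* The per-edge C×C solve makes the cost O(N·C³) per sweep; C in the
  hundreds would call for structured covariance approximations, which are
  out of scope.
* The BVS sharing layer couples edges only through the mixture; it does not
  model correlated designs across cell types.
* Imported external scores come without bootstrap replicates; the constant
  per-cell-type noise fallback is crude and clearly logged — supplying a
  matching std table is always better.

## A minimal end-to-end run

```{r example, eval = FALSE}
sim <- simulate_sharing(N = 1000, C = 5, K = 3, separation = 3,
                        noise_levels = 0.6, seed = 42)
fit <- fit_share_model(sim$stack, sim$noise, model_config(K = 3, seed = 1))
rev <- revised_scores(fit, sim$stack)
mean((sim$stack$scores - sim$truth$z_true)^2)  # MSE of the observed scores
mean((rev$scores - sim$truth$z_true)^2)        # strictly smaller after sharing
component_correlation(fit)$correlation         # the dominant sharing pattern
```
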