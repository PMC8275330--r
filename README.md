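# edgeshare

Adaptive sharing of gene regulatory edge scores across cell types.

## The problem

Cell type-specific gene regulatory networks (GRNs) inferred from single-cell
RNA-seq are noisy, and dramatically so for rare cell types: a network scored
from 50 cells is mostly sampling noise. Yet many regulatory interactions are
shared between related cell types, so each cell type's network carries
information about the others. `edgeshare` revises the per-cell-type edge
scores of *any* base network inference method (Pearson co-expression is
built in; GENIE3/PIDC-style score tables are imported via an adapter) by
pooling evidence across cell types through a sharing structure that is
itself learned from the data.

## The model

For each putative directed edge *n* = (regulator *i* → target *j*), let
*e_n* ∈ ℝ^C collect its observed scores in the C cell types. Each edge has a
latent true score vector *z_n*, drawn from a mixture of K multivariate
Gaussians whose C×C covariances are the *sharing patterns*:

    u_n ~ Categorical(1/K, …, 1/K)
    z_n | u_n = k ~ N(μ_k, Σ_k)
    (μ_k, Σ_k⁻¹) ~ NW(μ₀, β₀, Ψ, ν)            (Normal-Wishart prior)
    e_n^(c) ~ N(z_n^(c), σ_n^(c)²)

The per-edge, per-cell-type noise scale σ_n^(c) is estimated by
bootstrapping cells and re-scoring (M = 5 resamples by default). Posterior
inference is mean-field coordinate-ascent variational inference (CAVI) with
fully conjugate closed-form updates; the ELBO is monotone by construction
and is checked at every sweep. The posterior means m̃_n of the latent scores
are the revised, denoised edge scores; the fitted Σ_k reveal which cell
types inform each other.

Two extensions are included:

* **BVS** — an end-to-end spike-and-slab regression of each target on the
  regulators, `y = Σ_i X_i β_i γ_i + ε` with γ ~ Bernoulli(g(z)), where the
  inclusion logits z are shared across cell types through the same mixture
  (sigmoid link handled with the Jaakkola–Jordan bound). It yields posterior
  inclusion probabilities and holdout predictive likelihoods.
* **Trajectory dynamics** — binarize the top fraction of edges per network
  along an ordered cell-type chain and classify each edge as stably added
  (0…0 1…1), stably removed (1…1 0…0), unstable (> 4 activity flips), or
  other.

Evaluation utilities compute AUPRC and the AUPRC ratio (AUPRC / prevalence,
i.e. improvement over a random predictor) against reference networks,
including ChIP-seq-derived references (peak with q < 1e-5 within 5 kb of a
TSS), and the one-sided Wilcoxon signed-rank test for paired comparisons.

## Worked example

Simulate 1000 edges across 5 cell types from the model's own generative
process (3 planted sharing patterns, heteroscedastic noise), fit, and
inspect the result:

```r
library(edgeshare)

sim <- simulate_sharing(N = 1000, C = 5, K = 3, separation = 3,
                        noise_levels = 0.6, seed = 42)
fit <- fit_share_model(sim$stack, sim$noise, model_config(K = 3, seed = 1))
fit
#> <share_fit> 1000 edges x 5 cell types, 3 components; 12 sweeps (converged)
#>   final ELBO: -8742.771

rev <- revised_scores(fit, sim$stack)
mean((sim$stack$scores - sim$truth$z_true)^2)  # 0.386  (observed vs truth)
mean((rev$scores - sim$truth$z_true)^2)        # 0.229  (revised vs truth)
```

The revised scores cut the mean squared error to the latent truth from
0.386 to 0.229 — the denoising effect of sharing. The dominant learned
sharing pattern is a cell-type correlation matrix (here: everything
moderately positively correlated, as planted):

```r
component_correlation(fit)$correlation
#>      ct4  ct2  ct5  ct1  ct3
#> ct4 1.00 0.53 0.53 0.46 0.46
#> ct2 0.53 1.00 0.61 0.45 0.51
#> ...
```

A full file-based pipeline (expression → scores + bootstrap noise → fit →
evaluation → trajectory calls) is available through the CLI:

```sh
Rscript inst/cli/edgeshare.R simulate --out_dir run/sim --seed 7
Rscript inst/cli/edgeshare.R score --expression_manifest run/sim/expression_manifest.json \
    --tf_list run/sim/tf_list.txt --out_dir run/scores --seed 7
Rscript inst/cli/edgeshare.R fit --score_manifest run/scores/score_manifest.json \
    --out_dir run/fit --seed 7 --components 10
```

Subcommands: `simulate`, `score`, `fit`, `bvs`, `evaluate`, `trajectory`.
Settings may come from a YAML/JSON file via `--config`; explicit flags win.
Exit codes: 0 success, 2 validation error, 3 numerical failure.

## Documentation

See `vignettes/sharing-model.Rmd` for the model, its assumptions, the
meaning and defaults of every tunable parameter, what the synthetic
generators do and do not emulate, and known limitations.
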