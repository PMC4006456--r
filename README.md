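# priorclust

Bayesian model-based clustering of gene-expression profiles in which
prior knowledge about gene *pairs* — protein–protein interactions,
transcription-factor binding predictions, protein sequence similarity —
informs the prior over partitions. The goal is to find modules of
co-regulated, functionally related genes by combining what the
expression data say with what interaction databases already know.

## The model in brief

For a partition `g` of `n` genes into `K` groups, the genes of group `k`
(an `N × n_k` block `X_k` of the standardized expression matrix) are
zero-mean multivariate normal with covariance `Σ_k ~ IW(Ψ_k, m_k)`,
`Ψ_k = I`, `m_k = n_k + 2`, giving the closed-form marginal likelihood

    P(D|g) = ∏_k |Ψ_k|^{m_k/2} Γ_{n_k}((m_k+N)/2)
             / [ π^{N n_k/2} |Ψ_k + X_kᵀX_k|^{(m_k+N)/2} Γ_{n_k}(m_k/2) ]

The partition prior mixes a baseline measure — uniform over the number
of groups, then uniform over the `N(n,K)` partitions with `K` groups —
with components that *force* known pairs together: each prior pair
`(i, j, p)` is enforced with probability `p`, and a mask with `x`
enforced pairs merges the genes into `n − x` units carrying the baseline
measure. Prior pair sets are reduced to their maximum-weight spanning
forest first (cyclic priors would distort the meaning of `p`). Posterior
sampling is split/merge/move Metropolis–Hastings over partitions with
optional parallel tempering; the reported clustering minimises the
posterior expected loss `e_K = Σ_{i<j} |I_K(i,j) − p_ij|` over
tree-cuts of the posterior similarity matrix `p_ij`.

A synthetic benchmark generator (hierarchical log-normal clusters with
prior-pair scenarios A/B/C), pair-network evaluation (sensitivity,
specificity, PPV, single-point AUC, adjusted Rand index), and readers
for tab-separated expression/prior tables with score-to-probability
transforms and differential-expression preselection are included.

## Worked example

```r
library(priorclust)
set.seed(7)

# three true clusters, 30 samples, all prior pairs correct
sim <- simulate_clustered_dataset("C",
  sim_control(n_clusters = 3, lambda = 3, n_samples = 30), q = 6)

fit <- priorclust(t(sim$expression), sim$prior,
  control = sampler_control(n_iterations = 8000, burn_in = 2000,
                            thin = 10, n_temperatures = 2,
                            temperature_ratio = 0.5, audit_every = 0))
fit
#> Bayesian partition clustering with informative pairwise priors
#> Call: priorclust(x = t(sim$expression), priors = sim$prior, control = ...)
#> 32 genes, 6 prior pair(s), 600 posterior samples
#> Inferred K = 4 clusters; sizes: 9, 7, 10, 6

adjusted_rand(clusters(fit), sim$true_labels)
#> [1] 0.7029432
```

The fit selects `K = 4` clusters for the three simulated ones — one
cluster is split, a known tendency of the diffuse covariance prior
discussed in the vignette — for an adjusted Rand index of 0.70 against
the simulated truth; `summary(fit)` adds the sampled posterior over `K`
and acceptance rates, and `plot(fit)` draws the loss curve over
candidate cluster counts and the log-posterior trace.

A thin command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "priorclust.R", package = "priorclust"))') \
  cluster --expression expr.tsv --priors priors.tsv --seed 1 --out-prefix run
```

with subcommands `cluster`, `simulate`, `evaluate` and `select-genes`;
all inputs and outputs are tab-separated text.

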