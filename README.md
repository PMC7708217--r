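# methylMRM

DNA methylation imputation with mixtures of radial basis function (RBF)
regressions.

## The problem

Affordable methylation assays (RRBS, BeadChip arrays, shallow WGBS) measure
only a small fraction of the genome's CpG sites, and which sites are
covered differs between subjects. Association analyses downstream work on a
subjects x CpGs matrix of beta values in [0, 1] that is mostly holes.
methylMRM fills the holes by combining two empirical regularities:
neighbouring CpGs within a region are strongly correlated (an LD-like local
structure), and across subjects a region's methylation profiles fall into a
few distinct patterns.

## The model

Within a region whose CpG coordinates are scaled onto [-1, 1], a profile is
a linear combination of Gaussian bumps,

    y_i = sum_j w_j exp(-delta (x_i - mu_j)^2) + eps_i,

with J = 50 equally spaced centers and rate delta = 10 by default. The N
subjects of a region arise from at most K latent clusters with proportions
pi_k and cluster-specific coefficients w_k, sharing a noise variance
sigma^2. The log-likelihood is penalized by
`lambda * sum_k pi_k * ||w_k||_1` and maximized by a compiled EM with an
exact active-set lasso M-step. `lambda` is chosen per K by tenfold
cross-validation (one-standard-error rule); K by the lowest integrated
completed likelihood (ICL) with a nonzero-coefficient parameter count.

Three imputers are built on this core:

* **regional** — clusters the subjects of each region (the workhorse);
* **subject** — clusters the regions of each subject;
* **stacked** — combines the two by bootstrapped non-negative least
  squares, `y ~ beta_r * yhat_regional + beta_s * yhat_subject`.

The package also ships the model-based simulator with known ground truth,
correlation-based region definition (adjacent-site agglomeration, fixed
windows, promoter pruning) and the variance/skewness/runs region filters,
two baseline imputers (distance-weighted neighbour average, row-wise KNN),
and an evaluation harness (per-subject RMSE / correlation / AUC, paired
t-tests).

## A worked example

Simulate 5 regions of 50 CpGs for 20 subjects from a 4-cluster mixture
(proportions 0.1/0.2/0.3/0.4, noise sd 0.2), delete 80% of every subject's
cells, impute, and score each subject's hidden cells against the noise-free
cluster curves:

```r
library(methylMRM)

st <- simulate_mrm(sim_config(n_regions = 5, n_subjects = 20,
                              noise_sd = 0.2, missing_rate = 0.8, seed = 1))
scores <- benchmark_imputation(st, methods = c("regional", "average", "knn"),
                               seed = 1)
aggregate(value ~ method, data = subset(scores, metric == "correlation"),
          FUN = mean)
#>     method     value
#> 1  average 0.7692105
#> 2      knn 0.3035703
#> 3 regional 0.8651090
```

Even with 80% of the data deleted, the regional mixture model reconstructs
profiles at a mean per-subject correlation of 0.87 (RMSE 0.14), while the
weighted-neighbour average reaches 0.77 and KNN collapses to 0.30 — with so
few observed CpGs per row, nearest-neighbour averaging has little to work
with, which is exactly the regime the mixture model was designed for.

For file-based workflows there is a thin command-line wrapper in
`inst/cli/mrm` with subcommands `simulate`, `regions`, `impute`, `evaluate`
and `benchmark`; every stochastic subcommand takes `--seed` and is
reproducible given it.

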