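# cormclust

Model-based clustering of gene expression profiles on the **systematic**
part of their variation. Instead of grouping genes by their raw expression
vectors (as K-means does), `cormclust` fits a finite mixture of regression
models — linear models for cross-sectional designs, linear mixed models for
longitudinal designs with technical replicates — and clusters genes by how
their expression relates to the sample covariates. It is aimed at
time-course microarray / expression studies, in particular the
longitudinal-with-replications (LWR) design: several conditions
(e.g. genotypes), each measured as repeated time-course profiles.

## The model

Gene $g$ with observed expression vector $y_g$ belongs to a latent cluster
$u_g \in \{1,\dots,K\}$ with probabilities $\pi_1,\dots,\pi_K$, and

$$
y_g \mid u_g = k \;\sim\; N\!\big(X_g\beta_k,\; Z_g D_k Z_g^\top + \sigma_k^2 I\big),
$$

where $X_g$ stacks B-spline time-basis rows (optionally one coefficient
block per condition), and $Z_g$ carries gene-level random effects
$b_g \sim N(0, D_k)$ shared by all of the gene's observations — both
technical replicates included, which is how replication is modelled
hierarchically. Missing cells are handled by row deletion under a
missing-at-random assumption; unbalanced designs (condition-specific bad
time points) need no special casing. The model is fitted by EM with both
$u_g$ and $b_g$ latent; with $q = 0$ random effects it reduces to a
mixture of linear models, and in a degenerate configuration (saturated
design, shared scalar variance, equal proportions, hard assignment) the
same engine reproduces Lloyd's K-means exactly — the baseline it is
compared against.

The package provides the EM fitter with BLUPs and an explicit prediction
rule for new genes, a K-means baseline and its classification-EM mixture
form, diagnostics (residual-by-time summaries, two-eigenvector displays,
peak-time cluster relabelling, contingency-table comparison of two
clusterings, informative-gene screening with BH adjustment), synthetic
generators for the benchmark scenarios, and a command-line pipeline.

## Worked example

```r
library(cormclust)

sim  <- simulate_lwr_timecourse(sim_spec(G = 120, K = 3), seed = 1)
sim$dataset
#> expression_dataset: 120 genes x 92 observations (2 conditions, 552 masked cells)

spec <- design_spec(condition_blocking = TRUE)
fit  <- fit_clmm(sim$dataset, spec, K = 3, n_restarts = 5, seed = 1)
fit  <- relabel_by_peak(fit, "WT")
fit
#> clmm_fit: K = 3, 120 genes, loglik = 1515.4369 (6 iterations, converged, restart 1)
#> cluster sizes: 40 40 40

table(fitted = fit$map_labels, truth = sim$labels)
#>       truth
#> fitted  1  2  3
#>      1 40  0  0
#>      2  0 40  0
#>      3  0  0 40
```

The simulated two-genotype course has 92 observations per gene (two
conditions × two replicates over 25 five-minute time points, minus the
condition-specific bad time points) with 5% of cells masked at random;
the three phase-shifted clusters are recovered exactly, with clusters
renumbered in order of their fitted curves' first peak. A fitted model
classifies new genes without refitting:

```r
g1 <- sim$dataset$values[1, sim$dataset$mask[1, ]]
predict_new_gene(fit$params, g1, build_designs(sim$dataset, spec)[[1]])
#> $posterior
#> [1] 1 0 0
#> $map
#> [1] 1
```

and the eigen display summarises cluster separation:

```r
av <- average_replicates(sim$dataset)
pc <- pca_scores(complete_profiles(av$profiles, "impute"),
                 labels = as.integer(fit$map_labels))
#> top-2 eigenvectors explain 91.79% of the variance
```

Fitted curves come from `fitted_cluster_profile(fit$params, "WT", times)`;
`residuals(fit, sim$dataset)` gives per-gene residuals and a
variance-by-time table for model checking.

## Command line

A thin wrapper over the same functions ships at
`inst/cli/corm-tools.R`:

```sh
Rscript inst/cli/corm-tools.R simulate --config sim.yaml --out sim/ --seed 1
Rscript inst/cli/corm-tools.R fit sim/data.tsv --config fit.yaml --K 6,7,8 --out fits/
Rscript inst/cli/corm-tools.R compare fits/fit_K8.json fits/kmeans_K8.json
```

`fit` writes one JSON artifact and one assignment TSV per K plus a
summary table (log-likelihood, BIC, cluster sizes); choosing K is left to
the analyst. Every stochastic command records its seed.

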