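---
title: "Clustering genes on regression models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering genes on regression models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cormclust)
```

## The problem

Clustering algorithms such as K-means group genes directly on their
observed expression vectors. That ignores the experimental design: in a
longitudinal study with technical replicates, two measurements of the same
gene at the same time point are not two independent features, and time
points are ordered and correlated, not exchangeable. `cormclust` instead
clusters genes on the *systematic* part of their expression — the part
explained by the sample covariates through a regression model — and treats
the rest as noise. Genes end up in the same cluster when they relate to
the covariates (e.g. time, genotype) in the same way.

## The model

Let $y_g$ be the vector of observed (unmasked) expression values of gene
$g$, stacked over all conditions, technical replicates, and time points in
a fixed canonical order, and let $u_g \in \{1,\dots,K\}$ be its latent
cluster with prior probabilities $\pi_1,\dots,\pi_K$. Conditional on
$u_g = k$,

$$
y_g \mid u_g = k \;\sim\;
N\!\left(X_g \beta_k,\; Z_g D_k Z_g^\top + \sigma^2_k I\right).
$$

* $X_g$ is the fixed-effect design: a B-spline basis in time (cubic, 7
  equally spaced interior knots on the sampled range by default, hence 11
  columns), optionally block-diagonal over conditions so each condition
  has its own coefficient vector $\beta_k$ per block.
* $Z_g$ carries gene-level random effects $b_g \sim N(0, D_k)$. The
  default is one random intercept per condition, shared by *all* of the
  gene's observations in that condition — in particular by both technical
  replicates, which is how replication enters hierarchically: replicates
  share the gene's curve-level deviation and differ only through
  measurement noise. A `basis-subset` option instead puts random
  coefficients on the first $q$ spline columns for richer gene-level
  curve deviations; which of the two a given dataset warrants is a
  modelling choice, and both are exposed because the minimal intercept
  structure is the safer default for two technical replicates.
* $\sigma^2_k$ is the residual variance. With no random effects
  ($q = 0$) the model is a mixture of ordinary linear models.

Missing entries are carried by a mask and handled by row deletion (each
gene's likelihood uses only its observed rows), which is the correct
likelihood under missingness at random. No imputation happens inside the
fit; values are used on their original (log-ratio) scale with no per-gene
standardisation — a `center_genes` flag exists in the pipeline config but
is off by default.

## Fitting by EM

Both $u_g$ and $b_g$ are treated as latent. The E step computes, per gene
and cluster, the marginal Gaussian log density (via a low-rank $q \times
q$ decomposition of $Z_g D_k Z_g^\top + \sigma^2 I$, so the cost is linear
in the profile length), the posterior memberships $p_{gk}$ through
log-sum-exp, and the conditional moments
$\hat b_{gk} = D_k Z_g^\top V_{gk}^{-1}(y_g - X_g\beta_k)$,
$C_{gk} = D_k - D_k Z_g^\top V_{gk}^{-1} Z_g D_k$. The M step is in closed
form:

* $\pi_k = \frac1G \sum_g p_{gk}$ (or fixed at $1/K$ in
  `equal_proportions` mode);
* $\beta_k$ solves the $p_{gk}$-weighted least-squares problem with
  working response $y_g - Z_g \hat b_{gk}$;
* $D_k = \sum_g p_{gk}(\hat b_{gk}\hat b_{gk}^\top + C_{gk}) / \sum_g p_{gk}$,
  projected to the positive semi-definite cone by clipping eigenvalues at
  zero;
* $\sigma^2_k$ averages the squared working residual (with the refreshed
  $\beta_k$) plus the trace correction
  $\mathrm{tr}(Z_g C_{gk} Z_g^\top)$, floored at $10^{-8}$.

Because $\beta_k$, $D_k$ and $\sigma^2_k$ jointly maximise the expected
complete-data log likelihood, each iteration cannot decrease the observed
log likelihood; the test suite asserts monotone traces (slack $10^{-8}$)
across soft, hard, pooled-variance and fixed-proportion variants.

**Initialisation.** Lloyd's K-means on replicate-averaged per-gene
profiles (missing cells mean-imputed for initialisation only), started
from $K$ distinct randomly chosen gene profiles; the resulting hard labels
feed one M step, with $D_k$ then seeded at $\sigma^2_k I$ so the random
effects can move off zero. `n_restarts` (default 10) seeded starts are
run and the best final log likelihood wins, ties to the lowest restart
index. All randomness derives from the `seed` argument; fits are
bit-reproducible.

**Convergence and degeneracies.** Iteration stops when the relative
log-likelihood change falls below `tol` ($10^{-6}$ by default, `max_iter`
500). A cluster whose posterior mass falls below one gene is re-seeded
from the worst-fit gene (lowest MAP joint log density), that gene's own
least-squares coefficients becoming the cluster's; three re-seeds abort
the restart. MAP ties go to the lowest cluster index throughout.

**Classification EM and K-means.** With hard assignments, a saturated
identity design, a shared scalar variance, and $\pi_k$ fixed at $1/K$,
the EM above is exactly the classical K-means iteration: the E step is
nearest-center assignment, the M step recomputes centers as means, and
the recovered $\hat\sigma^2$ equals the within-cluster sum of squares
over $Gn$. `kmeans_as_classification_em()` runs this configuration
through the same engine and the suite checks label-for-label agreement
with `fit_kmeans()` (an independently coded Lloyd) under matched
initialisation on dozens of random datasets. The tie-break and
empty-cluster rules of the two implementations are deliberately aligned
(lowest index; re-seed from the farthest/worst-fit gene, which coincide
under the degenerate model). For this equivalence the engine's tolerance
is dropped to near machine precision, since the classification likelihood
is exactly stationary once labels stop moving.

## Diagnostics

* `residuals()` returns $y_g - X_g\beta_{\hat u_g} - Z_g\hat b_g$ and a
  per-cluster, per-time variance table (the spread should be roughly flat
  in time if the error model fits).
* `pca_scores()` projects genes and cluster centers on the two leading
  eigenvectors of the column-centered profile covariance and reports the
  variance fraction they explain. Centering is the default and a flag,
  since an uncentered decomposition answers a slightly different
  question.
* `relabel_by_peak()` renumbers clusters by the first interior local
  maximum of their fitted curves (global maximum as fallback, earliest
  time on ties), the conventional ordering for cell-cycle phase clusters.
* `cross_tab()` compares two clusterings; the agreement score matches row
  to column labels one-to-one by an exact maximum-weight assignment
  (dynamic programming over label subsets, exact up to 16 labels, greedy
  beyond). One-to-one matching is a *definition chosen here* — published
  agreement percentages computed by unstated rules are not reproduced,
  only the tables themselves, which ship as transcribed TSV fixtures.
* `select_informative_genes()` runs a per-gene F test of the spline
  design against an intercept-only model and keeps genes passing a
  Benjamini–Hochberg adjusted cutoff; BH is used because a concrete FDR
  procedure has to be fixed and it is the field's default.

## The synthetic generators

`simulate_lwr_timecourse()` emulates a replicated two-genotype cell-cycle
course: 25 five-minute time points over 0–120 min, conditions WT and SM
with two technical replicates each, condition-specific bad time points
(WT loses 105 min; SM loses 25, 40 and 55 min — giving the characteristic
$2\times24 + 2\times22 = 92$ observations per gene), and 5% of cells
masked at random. Cluster templates are sinusoids with a 60-minute period
(two cycles per course; the period is a parameter, since the real cycle
length under a given synchronisation protocol varies) and equally spaced
cluster phases; the SM amplitude is damped to 0.6 to mimic a mutation
that preserves periodicity at reduced magnitude. Gene-level
random intercepts (sd 0.1 per condition) are shared across replicates and
residual noise has sd 0.2, both on the log-ratio scale — values typical of
well-normalised two-colour array data. The recovery study uses $G = 300$
genes in $K = 3$ clusters, large enough for stable variance estimates and
small enough that the whole suite runs in well under a minute.

`simulate_clm_benchmark()` is the cross-sectional counterpart: 8 genes in
two clusters of four, a covariate with 10 levels and 10 samples per level,
cluster-specific linear trends (slopes $\pm 0.3$ about the covariate
mean), gene offsets (sd 0.3) and noise (sd 0.5). The magnitudes are
package constants chosen so cluster separation dominates noise — the
scenario where regression-based clustering is expected to recover the
partition essentially always, which the suite verifies across 100 seeds.

What these generators deliberately do *not* emulate: dye bias, spatial
artifacts, probe-level effects, heavy-tailed outliers, or informative
missingness. Passing the recovery tests therefore demonstrates
correctness of the estimator under its own assumptions, not robustness of
the model on raw microarray data; on real data the residual and BLUP
diagnostics are the tool for judging the latter.

A note on the recovery tolerance: the fitted mean curves are compared to
the generating sinusoids within three times the Monte-Carlo standard
error implied by the generator,
$\sqrt{(d_k + \sigma^2_k/R)/G_k}$ per time point. A cubic spline with
interior knots every 15 min approximates a 60-min-period sinusoid with a
worst-case error near 0.016, which consumes part of that budget; with the
default sizes the bound still holds comfortably.

## Numerical choices

* "7 equally spaced knots" is read as seven *interior* knots on the open
  time interval, full-multiplicity boundary knots at the range ends:
  11 cubic basis columns. Clustering results are not sensitive to the
  knot count within a reasonable range, and the basis is used raw (no
  orthogonalisation); fitted curves come from `fitted_cluster_profile()`
  rather than from reading spline coefficients.
* $D_k$ is kept positive semi-definite by eigenvalue clipping each M
  step; $\sigma^2_k \ge 10^{-8}$. The marginal likelihood is evaluated
  through the $q\times q$ factorisation $V^{-1} =
  \sigma^{-2}(I - ZL S^{-1} (ZL)^\top)$ with $D = LL^\top$ and
  $S = \sigma^2 I_q + (ZL)^\top(ZL)$, which never inverts $D$ and is
  therefore safe at the $D \to 0$ boundary; `marginal_loglik_gene()`
  keeps a dense-Cholesky path that serves as an internal cross-check.
* Model selection across $K$ is reported (log likelihood, BIC with the
  observed-cell count as sample size, cluster sizes), never decided
  automatically: with two technical replicates, resampling-based
  criteria are not applicable, and the choice of $K$ is left to the
  analyst.

## Known limitations

* Variance components are maximum-likelihood, not REML; with few genes
  per cluster $\sigma^2$ is biased low.
* The EM finds local optima; the seeded multi-restart scheme mitigates
  but does not eliminate this (the suite's recovery checks quantify it at
  the default settings).
* No automatic outlier detection: cells judged to be technical outliers
  must be supplied to `mask_entries()` by the analyst.
* Nonlinear or nonparametric component regressions, hierarchical
  clustering, and GO annotation of clusters are out of scope.

## A compact worked example

```{r example, eval = FALSE}
sim <- simulate_lwr_timecourse(sim_spec(G = 120, K = 3), seed = 1)
spec <- design_spec(condition_blocking = TRUE)
fit <- fit_clmm(sim$dataset, spec, K = 3, seed = 1)
fit <- relabel_by_peak(fit, "WT")
table(fit$map_labels, sim$labels)
prof <- fitted_cluster_profile(fit$params, "WT", seq(0, 120, 5))
res <- residuals(fit, sim$dataset)
```
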