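---
title: "Phylogenetic GLS scans for lifespan-associated phenotypes: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic GLS scans for lifespan-associated phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pglscan)
```

## The problem

Strains of a species are not independent samples: they share evolutionary
history, and any trait with heritable variation will be more similar between
closely related strains than between distant ones. A naive regression of an
omics feature (a transcript level, a peptide abundance, a metabolite, a
morphology measure) on a lifespan phenotype across a strain panel therefore
sees correlated errors and produces too many small p-values. `pglscan`
implements the standard remedy — phylogenetic generalized least squares
(PGLS) — as a scan engine over strains-by-features matrices, with replicative
lifespan (RLS) measures of budding-yeast natural isolates as the motivating
response.

## The model

For a response $y$ (one lifespan measure over $n$ strains) and one feature
$x$ we fit

$$ y = \beta_0 + \beta_1 x + \varepsilon, \qquad
   \varepsilon \sim \mathcal{N}(0, \sigma^2 V), $$

where $V$ encodes the assumed trait-evolution process on the strain
phylogeny. With $C$ the matrix of root-to-MRCA path lengths (tip depths on
the diagonal) and $D$ the patristic distances:

* **Null** — no phylogenetic structure, $V = I$;
* **BM** — Brownian motion, $V = C$;
* **Lambda** — Pagel's $\lambda \in [0,1]$ scaling the off-diagonal of $C$,
  interpolating between Null-like ($\lambda = 0$; exactly Null on
  ultrametric trees) and BM ($\lambda = 1$);
* **OU** — fixed-root Ornstein–Uhlenbeck with reversion strength
  $\alpha > 0$ per unit branch length,
  $V_{ij} = e^{-\alpha D_{ij}}(1 - e^{-2\alpha C_{ij}})/(2\alpha)$,
  which tends to $C$ as $\alpha \to 0$ and to a scaled identity as
  $\alpha \to \infty$.

The formulas are written for arbitrary (not necessarily ultrametric) trees;
unequal tip depths are carried through all four models. A root edge is
ignored: it adds the same constant to every entry of $C$ and is confounded
with the intercept.

$\sigma^2$ and the coefficients are profiled analytically
($\hat\sigma^2_{ML} = \hat\varepsilon' V^{-1} \hat\varepsilon / n$), leaving
a one-dimensional profile likelihood in $\lambda$ or $\log\alpha$ that is
maximized by bounded search ($\lambda \in [0,1]$;
$\log \alpha \in [\log(10^{-4}/h), \log(10^2/h)]$ with $h$ the maximum tip
depth, i.e. from "effectively BM" to "effectively independent"). Both
interval endpoints are evaluated so the reported optimum never falls below
them. The likelihood is plain ML, not REML, because model selection across
the four kinds compares raw maximized likelihoods; an AIC option exists in
`select_best_model()` but is not the default, since the selection rule this
package mirrors is "highest maximum likelihood". Exact ties break toward the
simpler model (Null, BM, then Lambda/OU).

The slope is tested two-sided against Student's $t$ with $n - 2$ degrees of
freedom, using the unbiased variance estimate for the standard error. No
multiple-testing correction is applied anywhere in the scan — deliberately,
for fidelity to the procedure being reproduced (see "Known limitations").

Numerical choices: positive-definiteness is established by Cholesky
factorization, with a single jitter of $10^{-10}\,\mathrm{tr}(V)/n$ added on
failure before giving up; a residual quadratic form below $10^{-12}$ of the
response scale marks the fit *degenerate* (perfect fit), with
$p = 0$ by convention and the log-likelihood flagged non-finite; degenerate
evaluations inside the profile search are replaced by large finite sentinels
so the optimizer remains well behaved.

## The scan and the top-hit rule

`association_scan()` crosses every feature with four response measures —
mean RLS, maximum RLS, and their natural logarithms (slope *t* statistics
and p-values are invariant to the log base; natural log is used and the
choice is inconsequential). For each pair it fits all four covariance
models, selects the best by ML, and records the slope, its p-value, and
optionally the maximum leave-one-out p-value. Leave-one-out refits drop one
strain at a time; because removing a tip changes no remaining pairwise MRCA
depth or patristic distance, pruning is a matrix subset. A feature is a
*top hit* when its slope is significant (strict $p < \alpha$, default
$\alpha = 0.05$) under at least two of the four measures
(`call_top_hits()`, `min_measures = 2`). The robustness flag marks hits
whose significant measures all survive leave-one-out at the same threshold;
filtering on it is left to the user, since the procedure being mirrored
reports robustness but does not state that non-robust hits were removed.

Strains are aligned per omics block by inner join of block rows, measure
names, and tree tips, with dropped strains reported — mirroring panels where
one strain lacks an entire layer (classically the metabolite panel).

## Preprocessing rules

* `standardize()`: per-feature z-scores across strains, sample ($n-1$)
  standard deviation, missing values excluded from the moments and preserved;
  constant features are dropped with a warning.
* `filter_metabolites()`: a feature is discarded when missing in more than
  one strain, not counting one designated strain that lacks the whole panel;
  features missing in exactly one other strain are kept for imputation.
* `knn_impute()` (default $k = 10$): case-wise k-nearest-neighbour
  imputation — neighbours are complete strain rows, distance is Euclidean
  over the target row's observed features, and imputed entries are
  $e^{-d}$-weighted means of neighbour values. This mirrors the documented
  behaviour of the classic `knnImputation` routine; the source procedure
  names only "10 nearest neighbors", so the weighting scheme is a documented
  design choice. $k$ is clamped to the number of complete rows with a
  warning.
* `aggregate_peptides()`: genes represented by multiple peptides get the
  mean of the standardized peptide values.
* `run_pca()` / `top_contributors()`: centered PCA on the complete
  standardized matrix; contributors to a component are ranked by absolute
  loading (squared-loading ranking is available but non-default) and the top
  $\lfloor 0.10\,F \rfloor$ are exported as a plain gene list — the floor
  and the absolute-loading convention are package choices where only
  "top 10%" was specified. Ties at the cutoff break by feature id.

## The coverage statistic

`relative_mtdna_coverage()` is the mean per-base depth of the mitochondrial
sequence divided by the mean per-base depth of all nuclear positions outside
excluded regions, a proxy for mitochondrial genome copy number. The default
exclusion is positions 45,000–50,000 of chromosome XII (1-based inclusive),
the collapsed rDNA repeat window whose depth is inflated by the tandem array
mapping onto one reference copy. "Normalized ratio" is interpreted as this
ratio of means: any per-library scaling applied to both tracks cancels, so
no separate normalization step is needed — a documented resolution of an
ambiguity in the source description. BED input (0-based half-open) is
converted on read.

## What the synthetic data emulate — and what they do not

All tests and demos run on generated inputs, because the original strain
tree and omics matrices are not redistributable in machine-readable form:

* Trees are pure-birth (Yule) with exponential waiting times; they are
  ultrametric, so non-ultrametric behaviour is exercised separately with
  hand-written Newick fixtures.
* Traits are exact draws from $\mathcal{N}(0, \sigma^2 V)$ for any of the
  four models — so parameter-recovery and calibration tests condition on a
  correctly specified generative model.
* Feature matrices plant linear effects $x_j = \beta_j y + \epsilon_j$ with
  phylogenetic (BM) or iid noise, plus optional uniform missingness; a truth
  table records $\beta_j$ so power and false-discovery can be scored.
* The end-to-end generator draws the log-lifespan trait under BM with
  $\sigma^2 = 0.15$ (tree height $\approx 2.5$–$3.5$), so the simulated
  panel spans roughly the >10-fold lifespan range observed in real isolate
  panels; $\sigma^2 = 1$ would give a ~1000-fold range and an unrealistically
  skewed response. Simulated maximum RLS adds independent log-scale noise
  (s.d. 0.25) to the mean-RLS trait, emulating the strong-but-imperfect
  correlation ($r \approx 0.95$) between mean and maximum lifespan in
  observed tables; an exact copy would make the two-measure hit rule
  vacuous. Both values were fixed once on realism grounds.
* Depth profiles are Poisson with a configurable mitochondrial-to-nuclear
  factor and an optional rDNA-like spike.

A green test therefore establishes correctness of the algorithms under
their own assumptions. It does not establish robustness to library-size or
batch effects, non-Gaussian trait distributions, measurement error in the
tree, or model misspecification beyond what the calibration tests probe.

## Known limitations

The select-then-test procedure — pick the covariance model with the highest
maximized likelihood, then read the slope p-value from the selected model —
is anticonservative. In our calibration experiments a *pre-specified*
Lambda-model test is well calibrated (empirical size $\approx 0.04$ at
nominal 0.05 on BM null data), while the best-of-four rule roughly doubles
the per-measure size (0.08–0.12). Compounding this, mean RLS and log mean
RLS are near-duplicate responses, so "significant under at least two of
four measures" filters far less than independence would suggest. As a
result, with 10 strong planted features among 200 the scan recovers
essentially all planted features but the false-discovery proportion among
hits sits near 0.5, not below 0.2; the acceptance test asserting
FDR ≤ 0.2 is left failing rather than weakened, and the arithmetic is
recorded in the repository notes. Users who need calibrated error control
should pre-specify the Lambda model and/or apply a multiple-testing
correction across features — both are available but deliberately not the
default.

## A worked example

```{r, eval = FALSE}
out <- tempfile("demo")
run_analysis(list(
  out_dir = out, loo = FALSE,
  synthetic = list(n_tips = 30, n_features = 200, n_planted = 10,
                   beta = 2, seed = 7)))
hits <- read.delim(file.path(out, "top_hits.tsv"))
truth <- read.delim(file.path(out, "truth.tsv"))
sum(hits$feature_id %in% truth$feature_id[truth$beta != 0])  # 10 of 10
```

The same pipeline is scriptable through the installed `pglscan` CLI
(`simulate`, `preprocess`, `scan`, `tophits`, `coverage`, `report`).
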