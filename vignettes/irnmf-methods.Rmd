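---
title: "Methods: integrative regularized NMF for multi-dataset expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative regularized NMF for multi-dataset expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irnmf)
```

## The model

Given $k \ge 2$ non-negative expression matrices $X_i \in \mathbb{R}^{n_i
\times g}$ (samples by genes, one matrix per dataset — in the motivating
application, per brain cell type) over one gene vocabulary, the package fits

$$\min_{W,\,V_i,\,H_i \ge 0} \;\sum_{i=1}^k \lVert X_i - H_i (W + V_i)
\rVert_F^2 \;+\; \lambda_1 \sum_{i=1}^k \lVert H_i V_i \rVert_F^2 \;+\;
\lambda_2 \sum_{i=1}^k \lVert H_i W \rVert_F^2,$$

where $W \in \mathbb{R}^{m \times g}$ holds $m$ shared gene factors, each
$V_i$ the dataset-specific deviations of those factors, and $H_i \in
\mathbb{R}^{n_i \times m}$ the sample loadings. With $\lambda_2 = 0$ this is
the integrative NMF objective popularized by LIGER; the additional
$\lambda_2$ term penalizes the shared-factor contribution to each dataset's
reconstruction, which shifts dataset-specific structure out of $W$ into the
$V_i$ and gives cleaner shared/specific attribution. Rows of $W$ and of the
$V_i$ are read as *gene modules*; rows of $H_i$ say how much each sample
uses each module.

### Why the split needs $\lambda_1, \lambda_2 > 0$

At $\lambda_1 = \lambda_2 = 0$ only the sums $W + V_i$ are identified: any
pattern can move between $W$ and a $V_i$ without changing the fit, provided
the other datasets' loadings on that factor are free to become zero.
Moreover, a factor slot whose $W$ row is empty carries no cross-dataset
identity at all, so two datasets may park unrelated specific patterns in
the same slot of their respective $V_i$. Both degeneracies are real
behaviors of the optimizer, not defects; [match_factors()] therefore scores
recovery per matrix (true shared factors against rows of $\widehat W$, each
dataset's true specific factors against rows of its $\widehat V_i$), and
the regularized fit ($\lambda_1, \lambda_2 > 0$) is what resolves the
attribution in practice.

## Optimization

The objective is minimized by block coordinate descent over $2k + 1$
blocks. One sweep updates $W$, then for each dataset $V_i$ and $H_i$; this
order is fixed for determinism. Each block update is an exactly solved
non-negative least-squares (NNLS) problem, so every update weakly decreases
the objective and the per-sweep trace is non-increasing — a property the
test suite checks on random data. Multiplicative updates were deliberately
not implemented: they lack this guarantee.

Each stacked design uses $\sqrt{\lambda}$ scaling (for example the $W$
update stacks $\sqrt{\lambda_2} H_i$ under $H_i$), so that the squared
residual of the subproblem equals the penalized objective exactly; stacking
the raw $\lambda$ would penalize $\lambda^2 \lVert \cdot \rVert^2$. A
`literal_lambda` flag exposes the raw-$\lambda$ variant for auditing; with
it the subproblems optimize a different criterion and sweeps need not be
monotone.

The NNLS kernel ([nnls_bpp()]) is block principal pivoting: starting from
the all-active KKT point, infeasible variables are exchanged between the
active and passive sets in full blocks while the infeasibility count keeps
shrinking; after three non-improving full exchanges a backup rule swaps
only the largest infeasible index, which provably terminates at the exact
KKT point. Columns sharing a passive-set pattern share one Cholesky
factorization. Principal subsystems are stabilized with a ridge of
$10^{-12} \cdot \max(\operatorname{diag})$; when the Cholesky pivots still
indicate near rank deficiency (dead factors produce Gram eigenvalues at
rounding level, where a naive triangular solve can explode along the null
space and break monotonicity) the solve falls back to the minimal-norm
solution via truncated eigendecomposition.

### Convergence and degenerate states

Iteration stops when the relative objective change
$|f_t - f_{t-1}| / \max(f_{t-1}, \varepsilon)$ drops below `tol` (default
$10^{-6}$) or after `max_iter` (default 100) sweeps. Initialization is
i.i.d. uniform$(0,1)$ from one seeded generator recorded in the result, so
a (collection, config) pair reproduces its trace bitwise on one platform.
Dead factors and all-zero sample loadings are left untouched — reseeding
them would break monotonicity — and are listed in the fit log.

## Choosing $m$ and the penalties

**Factor count.** For each candidate $m$, each sample's loading row is
normalized to a probability vector and its KL divergence from the uniform
distribution, $\log m + \sum_j p_j \log p_j$ (nats), is computed; the
median over samples rises with $m$ and flattens once factors stop
splitting real structure. [select_saturation()] reads the curve's
saturation point as the smallest $m$ reaching $(1-\epsilon)$ of the curve
maximum ($\epsilon = 0.05$ by default). The rule makes "saturation"
reproducible, but the curve is always returned so a human can override;
[reconstruction_mse()] — the sum over datasets of per-entry mean squared
errors — is the companion diagnostic.

**Penalties.** [lambda_grid_search()] fits every $(\lambda_1, \lambda_2)$
pair on the grid $\{0.01, 0.1, 1, 10, 100\}^2$ (all fits share one seed so
differences reflect the penalties, not initialization) and scores each fit
with the kNN alignment metric: sample $\min_i n_i$ cells per dataset,
L2-normalize the concatenated loadings, count same-dataset neighbors among
each point's $k_{nn}$ Euclidean nearest neighbors, and map the mean count
$\bar x$ to $1 - (\bar x - k_{nn}/k)/(k_{nn} - k_{nn}/k)$, clipped to $[0,
1]$. When the input datasets are *different* cell types they should not
mix, so the selected pair *minimizes* alignment (ties break toward smaller
penalties); the full ranked table is returned — selection between the
minimizer and a close runner-up is a judgment call the package never makes
on its own. Subsample size, row normalization, the Euclidean metric and
the `"auto"` rule $k_{nn} = \max(10, \lfloor 0.01 N \rfloor)$ follow the
metric's original usage; all are arguments.

The data are factorized exactly as supplied: the package performs no
internal normalization or gene scaling, and the loaders refuse negative or
non-finite entries rather than repairing them.

## Gene modules and enrichment

Within each factor row, per-gene z-scores use the population
(divide-by-$g$) standard deviation — at thousands of genes the choice is
immaterial but must be fixed for reproducibility. Genes with $z > 1$ form
the module; modules with at least 20 members are reported. Constant rows
yield empty modules. Modules from $W$ are shared; modules from a $V_i$ are
specific to that dataset.

Risk-gene association uses the one-sided hypergeometric upper tail
$P(X \ge x)$ with the analyzed matrix's gene vocabulary as universe and
the risk set intersected with that universe first (the raw and intersected
sets are both exposed by [load_gene_list()], since public risk catalogues
always contain symbols absent from any one expression matrix). Bonferroni
correction is applied over the *reported* modules of one source matrix by
default — each matrix is reported as its own family downstream — with
`family = "global"` pooling all sources; associated means adjusted
$p < 0.1$. Over-representation against GMT gene sets uses the same test
per term with Benjamini–Hochberg adjustment across the terms tested for a
module; significant means $q < 0.1$ *and* at least 10 term genes in the
universe. Term specificity is exact uniqueness: a module-specific term is
significant in exactly one module of its scope, a cell-type-specific term
in exactly one module of exactly one cell type; no ontology-aware
redundancy trimming is attempted. Top genes and top terms break ties
lexicographically so reports regenerate identically.

## Synthetic data and what passing tests mean

[generate_planted_collection()] builds collections whose every pipeline
stage has ground truth. Defaults (chosen once, at desk scale): $k = 3$
datasets of $n_i = 100$ samples over $g = 200$ genes with $m = 8$ factors —
2 shared plus 2 specific per dataset — and disjoint 25-gene modules.
Factor weights are two-level (high 1, low 0) so planted membership is
unambiguous for Jaccard scoring; each sample group loads
uniform$(0.5, 1.5)$ on one of its dataset's active factors. Noise is
clipped Gaussian ($\sigma = 0.1$ against signals of order 1, i.e. a
realistic ~10% relative error) or Poisson with the noise-free entry as
mean. Risk genes are 75% of two planted modules (one shared, one specific)
plus a 5% background rate — roughly the share of catalogued risk genes
among protein-coding genes. Factor matching for recovery scoring solves
the assignment exactly (Hungarian algorithm) because greedy matching can
understate recovery.

The generator emulates block-structured, non-negative signal with known
sharing — not the depth, dropout, or library-size variation of real
single-nucleus data, nor correlated gene programs that fractionate across
factors. Passing recovery tests therefore demonstrates the optimizer and
the downstream statistics are correct, not that any particular biological
dataset will factor cleanly.

## Problem sizes used by the tests and the acceptance script

Monotonicity is checked on twenty random $k=3$, $n_i=50$, $g=80$, $m=5$
collections; the NNLS solver against exhaustive active-set enumeration at
up to 8 variables; the hypergeometric tail against exact enumeration for
all configurations up to $N = 40$; recovery on the default generator
config over seeds 1–5; and enrichment power over twenty seeded
collections. `scripts/acceptance.R` re-runs the pipeline at the default
generator scale and writes its principal quantities as JSON. These sizes
were chosen so the whole suite runs in a couple of minutes on one core
while still exercising every code path at non-trivial scale.

## Known limitations

* No HDF5/loom/AnnData input and no gene-identifier mapping; gene matching
  is exact and case-sensitive (an opt-in uppercase flag exists).
* The factor-count rule depends on $\epsilon$ near flat curve maxima; on
  coarse grids adjacent $m$ values can be selected across seeds.
* K-means (seeded, `nstart = 10`) and the alignment subsample introduce
  the only downstream stochasticity; both take explicit seeds.
* With strong penalties the absolute reconstruction error grows — the
  penalties trade fidelity for attribution, which is the point of the
  model, but raw MSE should not be compared across penalty settings.

## A worked example

```{r example, eval = FALSE}
sim <- generate_planted_collection(synthetic_config(seed = 1))
fit <- fit_irnmf(sim$collection, m = 8, lambda1 = 1, lambda2 = 10, seed = 1)
recovery_report(fit, sim$truth)
mods <- gene_modules(fit)
flag_associated_modules(mods, sim$truth$risk_genes,
                        sim$collection$gene_names, family = "global")
```
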