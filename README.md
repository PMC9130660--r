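# irnmf

Integrative regularized non-negative matrix factorization for multi-dataset
gene expression, with the downstream statistics to turn factors into
testable gene modules.

## The problem

Expression measured across several related datasets — e.g. single-nucleus
profiles of different brain cell types — mixes structure that is *common*
to all datasets with structure *specific* to each. Separating the two
matters when asking, say, which dysregulated gene programs a disorder
shares across cell types and which are cell-type-private. Given k ≥ 2
non-negative matrices X_i (samples × genes, common gene vocabulary), the
package solves

    min  Σ_i ‖X_i − H_i(W + V_i)‖²_F
         + λ₁ Σ_i ‖H_i V_i‖²_F  +  λ₂ Σ_i ‖H_i W‖²_F     (W, V_i, H_i ≥ 0)

for one shared gene-factor matrix `W` (m × g), dataset-specific deviations
`V_i`, and sample loadings `H_i`. λ₂ = 0 recovers the iNMF objective used
by LIGER; λ₂ > 0 additionally shrinks the shared-factor contribution so
dataset-specific signal settles in the `V_i`. Fitting is block coordinate
descent in which every block update is an exactly solved non-negative
least-squares problem (block principal pivoting), so the objective is
provably non-increasing sweep by sweep.

Around the factorization the package provides, as separate composable
steps: factor-count selection via the per-sample KL-divergence saturation
curve; penalty selection via a kNN alignment-metric grid (minimized, since
datasets of different cell types should *not* mix); z-score gene-module
extraction (z > 1, ≥ 20 members reported); hypergeometric risk-gene
enrichment with Bonferroni correction; GMT over-representation analysis
with BH/FDR correction; module-specific and cell-type-specific term logic;
reconstruction/structure/clustering evaluation metrics; and a
planted-factor synthetic generator with exact (Hungarian) factor matching
for recovery scoring. See `vignettes/irnmf-methods.Rmd` for the methods in
full.

## Worked example

```r
library(irnmf)

sim <- generate_planted_collection(synthetic_config(seed = 1))  # 3 datasets, 200 genes, 8 planted factors
fit <- fit_irnmf(sim$collection, m = 8, lambda1 = 1, lambda2 = 10, seed = 1)
recovery_report(fit, sim$truth)
```

```
recovery_report: gene-factor cosine 0.998 (shared 0.998, specific 0.998)
  loading cosine 0.999, module Jaccard 1.000, rel. recon. error 0.229
  planted risk modules flagged: TRUE; false flags: 4
```

Every planted factor is recovered (cosine ≈ 1 between estimated and true
gene-factor rows after exact matching) and z-score extraction returns
exactly the planted module genes (Jaccard 1). The reconstruction error of
0.23 is the price of the penalties at λ₁ = 1, λ₂ = 10 — they trade raw
fidelity for shared/specific attribution. Testing all reported modules
against the planted risk-gene list:

```r
mods <- gene_modules(fit)
flag_associated_modules(mods, sim$truth$risk_genes,
                        sim$collection$gene_names, family = "global")
```

```
 module module_size overlap        raw_p   adjusted_p associated
 ds1_M2          25      19 1.629703e-09 4.889108e-08       TRUE
 ds1_M4          25      19 1.629703e-09 4.889108e-08       TRUE
 ds2_M2          25      19 1.629703e-09 4.889108e-08       TRUE
 ...
```

Each row is one hypergeometric test: of the 25 module genes, 19 are risk
genes (46 risk genes among the 200-gene universe), giving Bonferroni-
adjusted p ≈ 5e-8 — the planted risk modules are correctly flagged. The
same module appearing under several sources (`ds1_M2`, `ds2_M2`, ...) is
the shared planted module seen once per matrix; at these penalties part of
its pattern is carried in each V_i. `alignment_metric(fit)` returns 0.30
here: the three datasets occupy largely distinct regions of the loading
space, as their private factors dictate.

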