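# scBulkImpute

Imputation of dropout zeros in single-cell RNA-seq by **bulk-constrained,
non-negative, low-rank matrix completion**, together with the matching
dropout-data simulator and a toolbox of evaluation statistics.

## The problem

Single-cell RNA-seq matrices are riddled with *dropouts*: zeros caused by
failure to capture or amplify an expressed transcript, not by true absence of
expression. Dropouts distort expression distributions, cell–cell and
gene–gene correlation structure, and downstream clustering. Matched bulk
RNA-seq of the same cell population, in contrast, measures per-gene averages
reliably. scBulkImpute recovers the expression matrix by combining three
sources of information: the observed (non-zero) single-cell entries, the
expectation that cells occupy few effective states (low rank), and agreement
of the cell-averaged profile with the bulk measurement.

## The model

Let `X0` be the raw `n cells x m genes` matrix, `Ω = {(i,j) : X0[i,j] ≠ 0}`
the observed set, `P_Ω` the projection that zeroes entries outside `Ω`,
`a = (1/n, …, 1/n)` the uniform averaging row vector, and `D` the length-`m`
bulk vector. The imputed matrix is

```
X̂ = argmin_{X ≥ 0}  1/2 ‖P_Ω(X) − X0‖_F² + α ‖X‖_* + β ‖aX − D‖_2²
```

where `‖X‖_*` is the nuclear norm (sum of singular values), the convex
envelope of matrix rank. The problem is convex and is solved by ADMM after
splitting `X = Y`:

- **X-update** — the bound-constrained quadratic subproblem
  `P_Ω(X) + W X = γY + T − Λ`, `X ≥ 0`, with
  `W = γI + (2β/n²)·ones` and `T = 2β aᵀD + X0`, solved exactly by projected
  Gauss–Seidel sweeps (implemented in C++; `W` is never materialised);
- **Y-update** — singular value thresholding,
  `Y = SVT(X + Λ/γ, α/γ)`, the proximal map of the nuclear norm;
- **dual update** — `Λ ← Λ + γ(X − Y)`.

The loop stops when the relative primal residual `‖X − Y‖_F / max(1, ‖X0‖_F)`
and the relative objective change both fall below `tol`. `γ` affects only the
optimisation path, never the optimum. The solver is fully deterministic.

The simulator generates cluster-structured ground truth (per-cluster
log-normal gene means, Gaussian cell-level noise, clamped at zero), then
introduces zeros gene-wise with Bernoulli draws at rate
`exp(−λ · mean_g²)`; `calibrateLambda()` finds `λ` for a requested overall
zero fraction, and the matched bulk vector is the per-gene mean of the truth.

Evaluation statistics: Frobenius imputation error, two-sample
Kolmogorov–Smirnov distance between expression distributions, Pearson
comparison of cell–cell / gene–gene correlation matrices, within- vs
between-cluster correlation distortion, pathway gene correlation score
(PGCS and its paired difference ΔPGCS), and the Dunn cluster-separation
index.

## Worked example

```r
library(scBulkImpute)

cfg <- simConfig(nCells = 100, nGenes = 200, seed = 1)
sim <- simulateDropoutData(cfg, targetZeroFraction = 0.7)
sim
#> SimTruth: 100 cells x 200 genes, 3 clusters
#>   zero fraction truth/dropout: 0.090 / 0.700
#>   lambda: 0.003311

x0 <- ScMatrix(dropoutMatrix(sim))
params <- suggestParams(x0)      # spectrum-scaled alpha, beta, gamma
params
#> ImputeParams: alpha=22.91 beta=2.291 gamma=0.04
#>   maxIter=1000 tol=1.0e-05 innerMaxIter=100 innerTol=1.0e-06

res <- imputeDropouts(x0, bulkVector(sim), params)
res
#> ImputeResult: 100 cells x 200 genes
#>   ADMM iterations: 163 (converged)
#>   final primal residual: 9.83e-06
#>   final objective: 183185

report <- evaluateImputation(truthMatrix(sim), res,
                             dropout = dropoutMatrix(sim),
                             labels = clusterLabels(sim))
report$imputationError      # 698  — Frobenius error of the imputed matrix
report$dropoutError         # 1109 — error of leaving the zeros in place
report$clusterDistortion    # 0.016 — cluster correlation structure kept
```

Imputation cuts the reconstruction error well below the no-op baseline
(698 vs 1109) while leaving the within/between-cluster correlation
separation almost untouched (distortion 0.016 on a 0–1 scale). For
count-like data, library-size normalisation and `log1p` upstream are
recommended — with the bulk vector on the same transform; no transform is
ever applied silently.

A command-line interface wraps the same functions:

```sh
Rscript inst/scripts/scbulkimpute.R simulate --cells 200 --genes 300 \
    --target-zeros 0.7 --seed 1 --out-dir sim/
Rscript inst/scripts/scbulkimpute.R impute --input sim/dropout.tsv \
    --bulk sim/bulk.tsv --suggest-params --output sim/imputed.tsv \
    --diagnostics sim/diag.json
Rscript inst/scripts/scbulkimpute.R evaluate --truth sim/truth.tsv \
    --imputed sim/imputed.tsv --labels sim/labels.tsv --out sim/report.json
```

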