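# decondiff

Reference-free cell-type deconvolution for bulk gene-expression and
DNA-methylation matrices, with iterative cross-cell-type differential
feature selection.

## What problem this solves

Bulk measurements from tissue — whole-blood methylation arrays, tumour
expression profiles — average over the cell types in each sample. Shifts in
cell composition confound downstream analyses, so estimating the mixing
proportions is a standard first step. When no purified reference panel
matches the tissue and population at hand, the proportions must be inferred
from the bulk matrix alone (*reference-free* deconvolution), and accuracy
then hinges on selecting features that are genuinely cell-type informative:
low within-type, high cross-type variation.

This package is for analysts with a features × samples matrix (expression
intensities, or methylation beta-values in [0, 1]), a working guess at the
number of cell types `K`, and no usable reference panel.

## The method

The data model is linear mixing, `Y = W H + ε`, with `W` (m × K) the
cell-type profiles and `H` (K × n) the proportions: `H ≥ 0`, columns summing
to 1, and `W` in [0, 1] for methylation. The algorithm:

1. **Initialize** on the `m_target` (default 1000) features with the largest
   coefficient of variation; fit `W, H` by alternating exact constrained
   least squares (simplex-constrained `H`-step per sample,
   non-negative/box-constrained `W`-step per feature).
2. **Iterate** for `total_iter` (default 30) cycles: re-select features
   using the current `H̄` and refit. Selection strategies: profile
   variance/CV, or contrast t-tests on the proportion-design linear model
   `E[Y_p] = Hᵀ β_p` — one type vs the composite of the rest (SvC), a pair
   vs the rest (DvC), direct pairs (PwD), or the hybrid `rfdecd` allocation
   combining SvC and DvC in disjoint 40/30/30 blocks.
3. **Return** the proportion snapshot from the iteration with the smallest
   full-matrix reconstruction RMSE.

A Dirichlet-mixture simulator (4- and 6-cell-type presets with realistic
blood-like compositions), optimal-assignment component matching, and mean
PCC / MAE evaluation metrics make the whole pipeline testable offline.

See `vignettes/decondiff-methods.Rmd` for the model, numerical design and
parameter guidance.

## Worked example

```r
library(decondiff)

truth <- sim_preset("expr4", seed = 1)   # 5000 features x 100 samples, K = 4
cfg <- deconv_config(K = 4, mode = "expression", strategy = "rfdecd",
                     total_iter = 10, seed = 1)
res <- run_deconv(truth$Y, cfg)
res
#> Deconvolution run (rfdecd, K = 4): best RMSE 194.602 at trace entry 4/11

evaluate_proportions(res$best_H, truth$H_true)
#> Proportion evaluation (K = 4, n = 100)
#>   mean PCC 0.9967, MAE 0.0942
#>   per-type PCC: 0.997 0.994 0.997 0.999

evaluate_proportions(res$snapshots[[1]], truth$H_true)   # "PreOpt" baseline
#> Proportion evaluation (K = 4, n = 100)
#>   mean PCC 0.9262, MAE 0.1302
#>   per-type PCC: 0.825 0.904 0.984 0.991
```

The mean PCC is the per-cell-type Pearson correlation between estimated and
true proportions across samples, averaged after matching the anonymous
components to the truth; MAE is the mean absolute proportion error under the
same matching. Iterative selection lifts the initial (top-CV, "PreOpt")
estimate from mean PCC ≈ 0.93 to ≈ 0.997 on this seed (the gap is larger on
harder draws); trace entry 1 is that initialization, entries 2–11 the ten
refinement iterations.

A command-line front end ships in `inst/cli/decondiff`
(`run`, `simulate`, `evaluate`, `benchmark` subcommands).

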