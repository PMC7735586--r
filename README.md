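# peabench

Benchmarking missing-value imputation for proximity extension assay
(PEA) proteomics data.

## The problem

PEA panels (Olink-style) quantify hundreds of plasma proteins as NPX
values — log2-scale relative abundances measured in chips of up to 88
samples per panel. Real studies lose data two ways: whole chips or
samples fail quality control (missing completely at random, MCAR), and
values fall below the per-assay limit of detection (LOD,
left-censored; coded 0 after LOD subtraction). Multivariate analyses
need complete matrices, so the MCAR cells get imputed — and the choice
of imputer changes both the accuracy of the reconstructed values and
the bias and power of every downstream regression.

`peabench` is for analysts of NPX-style data who need to decide
*whether and how* to impute. It provides:

* a **synthetic NPX generator** (latent Gaussian factor model with
  panel structure, duplicate assays, per-assay LOD censoring, chip
  layout, whole-chip MCAR masking) that serves as ground truth;
* **QC screens** that build the MCAR mask: PCA sample outliers,
  duplicate-assay concordance, malfunctioning-chip detection;
* four **imputers**: column mean, random draw, iterative random forest
  (missForest-style, with out-of-bag accuracy estimates; the forest is
  implemented in C++ in this package), and a Gibbs sampler with
  elastic-net conditional means and truncated-normal draws
  (GSimp-style);
* **evaluation**: per-assay NRMSE, relative variance, Pearson/Spearman
  against held-out truth, stratified by below-LOD fraction, plus
  panel-subset and sample-size experiments;
* a **downstream simulation** of univariate regression
  (`Y = beta * x + eps`) quantifying power, bias and coefficient error
  for complete, complete-case and imputed data.

The two headline statistics, per assay over the evaluated cells:

```
NRMSE   = sqrt( mean((x_true - x_imp)^2) / var(x_true) )
Rel.Var = var(x_imp) / var(x_true)
```

Mean imputation calibrates to NRMSE ≈ 1 with Rel.Var = 0; random
imputation to NRMSE ≈ √2 with Rel.Var ≈ 1; good model-based imputation
pushes NRMSE toward 0 while keeping Rel.Var near 1.

## Worked example

```r
library(peabench)

# a scaled-down study: 800 samples, 5 panels x 12 assays, one whole
# 80-sample chip of the Inflammation panel masked MCAR
bundle <- synth_generate(synth_config_small(n_samples = 800, seed = 1))
bundle
#> synth_bundle
#> npx_dataset: 800 samples x 60 assays, 5 panel(s)
#>   cells: 42459 observed, 1104 MAR missing, 4437 below LOD
#>   hidden truth cells: 1104

imp_rf <- impute_rf(bundle$observed, imputer_spec("RF_ITERATIVE", seed = 1))
imp_gb <- impute_gibbs_en(bundle$observed, imputer_spec("GIBBS_EN", seed = 1))

ev_rf <- evaluate_imputation(imp_rf, bundle$truth, bundle$observed)
ev_gb <- evaluate_imputation(imp_gb, bundle$truth, bundle$observed)
infl <- function(ev) ev[ev$panel == "Inflammation", ]  # the masked panel
round(sapply(list(rf = infl(ev_rf), gibbs = infl(ev_gb)), function(ev)
  c(median_pearson = median(ev$pearson, na.rm = TRUE),
    median_rel_var = median(ev$rel_var, na.rm = TRUE))), 3)
#>                    rf gibbs
#> median_pearson 0.645 0.691
#> median_rel_var 0.277 0.469
```

Read: both methods reconstruct the masked chip with a median
imputed-vs-truth correlation near 0.65–0.70 in this world, but the
forest compresses the imputed values' variance to ~28% of truth while
the Gibbs sampler retains ~47% — the variance distortion is what later
biases regression coefficients. The forest's out-of-bag estimates
(`imp_rf$oob_nrmse`) rank-predict realized per-assay NRMSE, so
imputation quality can be estimated without any remeasurement.

Downstream effects:

```r
sim <- run_simulation_all(bundle, imp_rf, imp_gb,
                          sim_config(n_reps = 200, seed = 2))
acc <- setNames(infl(ev_gb)$pearson, infl(ev_gb)$assay_id)
tr <- trend_analysis(sim, acc, census_below_lod(bundle$observed))
subset(tr$crossings, metric == "power")
#>   metric dataset  crossing
#> 1  power      RF 0.1447746
#> 2  power   GIBBS 0.3337930
```

The crossing is the accuracy threshold above which imputing beats
complete-case analysis for statistical power; below it, imputation
hurts.

A full pipeline run (generate → QC → impute with every method →
evaluate → simulate → TSV reports + manifest):

```r
res <- run_benchmark(pipeline_config(output_dir = "bench_out", seed = 1))
res$summary
```

Command line: `Rscript $(Rscript -e 'cat(system.file("cli/peabench.R",
package="peabench"))') synth --out data/ --seed 1` (subcommands
`synth`, `qc`, `impute`, `evaluate`, `run`).

## More

See the methods vignette (`vignettes/imputation-benchmarking.Rmd`) for
the generator's model and its limits, all tunable parameters, numerical
choices, and known limitations.
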