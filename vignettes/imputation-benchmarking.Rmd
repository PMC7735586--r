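---
title: "Benchmarking missing-value imputation for PEA proteomics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking missing-value imputation for PEA proteomics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Proximity extension assays (PEA) quantify hundreds of plasma proteins as
NPX values — log2-scale relative abundances, where +1 NPX is a doubling
of concentration. Samples are measured in chips (plates) of up to 88
samples per protein panel. Two kinds of missingness arise:

* **Missing completely at random (MCAR)** — technical failures; in the
  motivating scenario an entire 86-sample chip of a 91-assay panel fails
  quality control, so all 86 × 91 = 7826 of its values must be treated
  as missing.
* **Left-censored** — values below the per-assay limit of detection
  (LOD). After the conventional LOD subtraction these cells are coded
  exactly 0.

Multivariate analyses need complete matrices, so MCAR cells are imputed.
`peabench` implements four imputers and the machinery to benchmark them:
how accurately they reconstruct held-out truth, how well they preserve
variance, and what their errors do to downstream regression analyses.

## The imputers

* **Mean** — each missing cell gets its assay's observed mean. Accurate
  on average, but the filled cells have zero variance (relative variance
  0), the classic source of downstream bias.
* **Random draw** — each missing cell gets a uniform draw from its
  assay's observed values. Variance-preserving but inaccurate.
* **Iterative random forest** (missForest-style) — initialize missing
  cells with column means, then repeatedly regress each incomplete
  assay on all others with a random forest and replace its missing
  cells with the predictions, until the relative change
  $\Delta = \sum(\hat X_{new}-\hat X_{old})^2 / \sum \hat X_{new}^2$
  over imputed cells first increases (the previous iterate is
  returned). The forests' out-of-bag residuals give a per-assay NRMSE
  estimate of imputation accuracy without any ground truth.
* **Gibbs sampler with elastic-net conditional means** (GSimp-style) —
  same iterative structure, but each missing cell is *drawn* from a
  normal centred on the elastic-net prediction, with SD equal to the
  root-mean-square deviation between the assay's fitted and observed
  values, optionally truncated to `[lo, hi]`. For MCAR use the bounds
  are infinite; finite bounds support left-censored use (drawing below
  a known LOD). Drawing rather than plugging in the conditional mean
  is what preserves variance. The returned value is the mean of
  post-burn-in draws.

### Evaluation metrics

Against held-out truth $x^{true}$ and imputation $x^{imp}$ over the
evaluated cells of one assay:

$$\mathrm{NRMSE} = \sqrt{\frac{\mathrm{mean}\left((x^{true}-x^{imp})^2\right)}
{\mathrm{var}(x^{true})}},\qquad
\mathrm{Rel.Var} = \frac{\mathrm{var}(x^{imp})}{\mathrm{var}(x^{true})}$$

with the sample ($n-1$) variance. These have useful analytic
calibrations that the acceptance suite verifies: mean imputation gives
NRMSE close to 1 and relative variance exactly 0; random imputation
gives NRMSE close to $\sqrt 2$, relative variance close to 1, and
Pearson correlation close to 0. (With the $n-1$ variance, imputing
cells by their own mean gives exactly $\sqrt{(n-1)/n}$, approaching 1
from below — the reason this denominator was chosen where the metric's
written form is ambiguous.) Pearson/Spearman correlations and the
metrics are computed over MCAR-evaluated cells only; below-LOD cells
never enter accuracy metrics.

## The synthetic world

No public data exist for the motivating cohort, so all testing runs on
a generator (`synth_generate()`) whose *defaults are the stated world*:

* 802 samples randomized to 10 chips per panel (chips 1–9 hold 86
  samples; the masked chip is chip 7 of the Inflammation panel, giving
  exactly the 86 × 91 = 7826 masked cells of the motivating scenario);
* 5 panels totalling 458 assays = 444 unique proteins, with 12 proteins
  in duplicate and 1 in triplicate across panels;
* protein covariance from a linear Gaussian factor model
  $x_{ij} = \sum_k \lambda_{jk} f_{ik} + u_{ij}$ with panel-structured
  loadings (assays of a panel preferentially share that panel's factor
  pool). The model is a deliberate simplification: it reproduces the
  two drivers of imputation accuracy the benchmark cares about —
  information overlap between proteins (communality
  $\sum_k \lambda_{jk}^2$) and signal-to-noise — with interpretable
  knobs;
* duplicate assays share their protein's entire latent signal plus
  independent measurement noise whose SD is derived per protein from
  the attenuation law $\rho = v_t/(v_t+\sigma_{dup}^2)$ at the target
  concordance $\rho = 0.884$, the empirically observed duplicate
  correlation;
* per-assay left-censoring at the LOD quantile, drawn from a three-bin
  census (no censoring with probability 287/458; under 25% with
  probability 108/458; 25–98% otherwise), matching the printed census
  of the motivating study. Censored cells report the LOD (the NPX
  software convention) until `subtract_lod()` recodes them to 0;
* scattered extra MCAR cells at rate 0.003 (the study's ~1100 extra
  QC-failed values out of 802 × 458).

What the generator does **not** emulate: patient covariates and repeat
visits, non-Gaussian marginals, assay-specific dynamic ranges, and chip
effects (zero by default, since the real pipeline normalizes them away;
`chip_effect_sd` switches them on to exercise
`interplate_normalize()`). A green test therefore establishes that an
algorithm behaves correctly *under the stated covariance and censoring
structure*, not that it attains any particular accuracy on real cohort
data — the real-data medians are explicitly out of scope.

The CI-scale benchmark (`synth_config_small()`) keeps the full
structure at 5 panels × 12 assays and 800 samples.

## Numerical and design choices

* **Random forest**: authored in C++ (no RF package is assumed):
  bagged CART, variance-reduction splits, per-node feature subsampling
  with `mtry = floor(sqrt(p))` and terminal node size 5 — the
  defaults of the canonical missForest implementation, so that the
  default configuration here matches what practitioners mean by
  running that algorithm with standard settings. Split finding uses
  256 quantile bins
  per feature (histogram method); at benchmark scale that is ~3
  training rows per bin, statistically indistinguishable from exact
  scanning and several-fold faster on one CPU. The forest RNG is a
  private mt19937 seeded from the imputer spec, so results are
  bit-reproducible and independent of R's RNG state.
* **Iteration stop**: the forest imputer returns the *previous*
  iterate when Δ first increases (at most `max_iter = 10` sweeps, with
  a warning when the criterion never triggers).
* **Gibbs knobs**: 10 outer sweeps, burn-in fraction 0.5, 10 draws per
  cell per sweep, elastic-net mixing 0.5, penalty chosen per assay per
  sweep by 5-fold cross-validation (`regularization = "fixed"` trades
  accuracy for speed in unit tests). The reference implementation's
  iteration counts are not printed anywhere authoritative; these are
  explicit, documented knobs, and the per-sweep trace lets users check
  convergence. The final cell value is the mean of the post-burn-in
  draws — a Monte-Carlo estimate of the cell's conditional mean. The
  `draws_per_cell` default (10, so 50 effective draws) was chosen so
  that the Monte-Carlo error of that estimate is negligible: with a
  single draw per sweep the residual sampling noise measurably
  attenuated imputed-vs-truth correlation on the package's own
  benchmark while inflating relative variance — a trade a user can
  still make explicitly by lowering `draws_per_cell` toward 1 when
  maximal variance retention matters more than per-cell accuracy.
* **Truncated normal**: inverse-CDF sampling; `sigma = 0` returns the
  clamped mean; draws are clamped to the bounds to guard tail
  round-off.
* **Inter-plate normalization**: per-assay chip-median alignment by
  default (`scope = "per_assay"`), the convention for intensity-based
  NPX normalization; `per_chip_global` implements the literal
  one-median-per-chip reading. Below-LOD cells are excluded from the
  medians by default (they are censored, not measured) but shift with
  their chip. The pipeline normalizes before LOD subtraction; the
  order is configurable because the source description fixes neither.
* **Downstream simulation**: $Y = \beta x_C + \varepsilon$,
  $\varepsilon \sim N(0, \sigma^2)$, 1000 replicates, $\alpha = 0.05$,
  $\beta = 0.01$ at full size. $\sigma$ is nowhere specified and the
  absolute power level depends entirely on it, so the default
  calibrates $\sigma$ per protein (normal-approximation power formula)
  to put *complete-data* power near 0.5, the regime where dataset
  differences are most visible; pass `noise_sd` to override. Estimates
  are compared per replicate against the complete-data estimate of the
  same simulated outcome. The protein enters either as independent
  (`Y ~ x`) or dependent (`x ~ Y`) variable; complete-case analysis
  means dropping rows with missing `x`.
* **Trend analysis** fits least-squares lines of power / bias / average
  absolute difference against per-assay imputation accuracy over
  assays with below-LOD fraction < 0.25, and reports where an imputed
  dataset's line crosses the complete-case line — the empirical
  accuracy threshold above which imputing beats dropping rows. The
  tests assert the crossing's existence in (0, 1), not its value,
  which is case-specific.

## Degenerate inputs and edge behavior

Imputers refuse fully missing assays; the Gibbs elastic net falls back
to the column mean for a sweep if a fit fails (logged); assays with
fewer than 3 evaluated cells are dropped from evaluation records;
`nrmse`/`rel_var` error on zero truth variance rather than returning
infinities; chip flags on panels without duplicate coverage are
reported as unscreenable rather than silently absent.

## Known limitations

* The Gaussian factor world cannot exhibit heavy-tailed or multimodal
  marginals; accuracy rankings there may compress relative to real NPX
  data.
* Below-LOD *accuracy* is not benchmarked (the truncation mechanism is
  implemented and contract-tested); the generator retains censored
  truth so such experiments are possible.
* The full-scale Gibbs run with per-sweep cross-validation is the
  slowest path (~40 s per benchmark seed); use
  `regularization = "fixed"` for exploratory loops.
* OOB error estimates exist for the forest imputer only; the Gibbs
  imputer has no analogous internal accuracy estimate.
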