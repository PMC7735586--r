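# Accuracy metrics against ground truth and the benchmark experiments.

#' Normalized root mean squared error
#'
#' `sqrt(mean((x_true - x_imp)^2) / var(x_true))` with `var` the sample
#' (n-1) variance. Calibration: imputation by the column mean gives a
#' value close to 1 (approaching from below as
#' `sqrt((n-1)/n)` when imputing by the evaluated cells' own mean),
#' random-draw imputation a value close to `sqrt(2)`, and perfect
#' imputation 0.
#'
#' @param x_true,x_imp Equal-length numeric vectors (length >= 2).
#' @return Non-negative scalar.
#' @export
nrmse <- function(x_true, x_imp) {
  if (length(x_true) != length(x_imp)) stop("inputs must have equal length")
  if (length(x_true) < 2L) stop("need at least 2 values")
  v <- var(x_true)
  if (v == 0) stop("zero truth variance: NRMSE undefined")
  sqrt(mean((x_true - x_imp)^2) / v)
}

#' Relative variance of imputed values
#'
#' `var(x_imp) / var(x_true)`; ideally close to 1. Mean imputation gives
#' exactly 0 (all filled values constant), random imputation about 1,
#' and a value below 1 signals variance reduction that biases
#' downstream regression.
#'
#' @inheritParams nrmse
#' @return Non-negative scalar.
#' @export
rel_var <- function(x_true, x_imp) {
  if (length(x_true) != length(x_imp)) stop("inputs must have equal length")
  if (length(x_true) < 2L) stop("need at least 2 values")
  v <- var(x_true)
  if (v == 0) stop("zero truth variance: relative variance undefined")
  var(x_imp) / v
}

#' Per-assay evaluation of an imputation against ground truth
#'
#' For each assay with at least `min_cells` evaluated cells, computes
#' Pearson and Spearman correlation, NRMSE and relative variance over
#' the `eval_mask` cells only (below-LOD cells never enter the
#' metrics), together with the assay's below-LOD fraction. When a
#' per-assay `measurement_sd` reference is supplied (e.g. the SD of
#' repeated pooled-control measurements), the error ratio
#' `RMS(imputed - truth) / measurement_sd` is added: values near 1 mean
#' the imputation error has reached the measurement-noise floor.
#'
#' @param imp An `npx_imputed`.
#' @param truth An [npx_truth()] paired with the dataset.
#' @param ds The masked [npx_dataset()] that was imputed.
#' @param measurement_sd Optional named per-assay numeric vector.
#' @param min_cells Minimum evaluated cells per assay (default 3).
#' @param exclude_below_lod Exclude evaluated cells whose true value
#'   lies at or below the assay's LOD (default `TRUE`): left-censored
#'   cells are out of accuracy-benchmark scope, only
#'   missing-completely-at-random cells are scored. `truth` and `ds`
#'   must share the scale on which `ds$assays$lod` is expressed.
#' @return Data frame with one row per evaluated assay: `assay_id`,
#'   `panel`, `pearson`, `spearman`, `nrmse`, `rel_var`,
#'   `frac_below_lod`, `error_ratio`, `n_eval_cells`.
#' @export
evaluate_imputation <- function(imp, truth, ds, measurement_sd = NULL,
                                min_cells = 3L, exclude_below_lod = TRUE) {
  stopifnot(inherits(imp, "npx_imputed"), inherits(truth, "npx_truth"),
            inherits(ds, "npx_dataset"))
  if (!any(truth$eval_mask)) stop("eval_mask is empty")
  frac_lod <- census_below_lod(ds)
  rows <- list()
  for (j in seq_len(ncol(ds$values))) {
    cells <- truth$eval_mask[, j]
    if (exclude_below_lod && is.finite(ds$assays$lod[j]))
      cells <- cells & truth$values[, j] > ds$assays$lod[j]
    n_cells <- sum(cells)
    if (n_cells < min_cells) next
    xt <- truth$values[cells, j]
    xi <- imp$values[cells, j]
    vt <- var(xt)
    aid <- ds$assays$assay_id[j]
    rows[[length(rows) + 1L]] <- data.frame(
      assay_id = aid,
      panel = ds$assays$panel[j],
      pearson = if (vt > 0 && var(xi) > 0) cor(xt, xi) else NA_real_,
      spearman = if (vt > 0 && var(xi) > 0)
        cor(xt, xi, method = "spearman") else NA_real_,
      nrmse = if (vt > 0) nrmse(xt, xi) else NA_real_,
      rel_var = if (vt > 0) rel_var(xt, xi) else NA_real_,
      frac_below_lod = unname(frac_lod[aid]),
      error_ratio = if (!is.null(measurement_sd) && aid %in% names(measurement_sd))
        sqrt(mean((xi - xt)^2)) / measurement_sd[[aid]] else NA_real_,
      n_eval_cells = n_cells,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# Restrict a bundle to a subset of panels and/or chips (of target panel).
restrict_bundle <- function(bundle, panels = NULL, keep_chips = NULL,
                            chip_panel = NULL) {
  ds <- bundle$observed
  tr <- bundle$truth
  jj <- seq_len(ncol(ds$values))
  ii <- seq_len(nrow(ds$values))
  if (!is.null(panels)) jj <- which(ds$assays$panel %in% panels)
  if (!is.null(keep_chips))
    ii <- which(chips_on_panel(ds, chip_panel) %in% keep_chips)
  samples <- ds$samples[ii, , drop = FALSE]
  rownames(samples) <- NULL
  keep_cols <- c("sample_id", paste0("chip_", unique(ds$assays$panel[jj])))
  samples <- samples[, keep_cols, drop = FALSE]
  assays <- ds$assays[jj, , drop = FALSE]
  rownames(assays) <- NULL
  obs <- npx_dataset(ds$values[ii, jj, drop = FALSE],
                     ds$mask[ii, jj, drop = FALSE], assays, samples)
  structure(list(observed = obs,
                 truth = npx_truth(tr$values[ii, jj, drop = FALSE],
                                   tr$eval_mask[ii, jj, drop = FALSE]),
                 factor_loadings = bundle$factor_loadings[jj, , drop = FALSE],
                 config = bundle$config),
            class = "synth_bundle")
}

#' Panel-subset imputation experiment
#'
#' Emulates measuring only two panels: for each non-target panel P, the
#' dataset is restricted to the target panel plus P, imputed, and the
#' target panel's assays evaluated; the all-panels condition is run as
#' reference. Accuracy losses for specific panel pairs reveal where the
#' information about each target assay lives.
#'
#' @param bundle A `synth_bundle`.
#' @param target_panel Name of the panel whose assays are evaluated.
#' @param specs Named list of [imputer_spec()]s.
#' @return Data frame of per-assay evaluation records with added columns
#'   `condition` (`"all_panels"` or the partner panel) and `method`.
#' @export
panel_subset_experiment <- function(bundle, target_panel, specs) {
  stopifnot(inherits(bundle, "synth_bundle"))
  panels <- unique(bundle$observed$assays$panel)
  if (!target_panel %in% panels) stop("unknown target panel: ", target_panel)
  if (length(panels) < 2L) stop("need at least 2 panels")
  conditions <- c(list(all_panels = panels),
                  stats::setNames(lapply(setdiff(panels, target_panel),
                                         function(p) c(target_panel, p)),
                                  setdiff(panels, target_panel)))
  out <- list()
  for (cname in names(conditions)) {
    sub <- restrict_bundle(bundle, panels = conditions[[cname]])
    for (mname in names(specs)) {
      imp <- impute(sub$observed, specs[[mname]])
      ev <- evaluate_imputation(imp, sub$truth, sub$observed)
      ev <- ev[ev$panel == target_panel, , drop = FALSE]
      if (!nrow(ev)) next
      ev$condition <- cname
      ev$method <- mname
      out[[length(out) + 1L]] <- ev
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sample-size dependence experiment
#'
#' Simulates having measured only `k` of the chips (the masked chip is
#' always retained, since its cells are what gets imputed and scored):
#' for each level, the dataset is restricted to the masked chip plus
#' `k - 1` additional chips, imputed and evaluated. Paired per-assay
#' method comparisons (two-sided Wilcoxon signed-rank on Pearson and on
#' relative variance) are attached per level.
#'
#' @param bundle A `synth_bundle` with a masked chip configured.
#' @param chips_to_keep Integer vector of chip counts (each >= 2).
#' @param specs Named list of [imputer_spec()]s.
#' @return List with `records` (evaluation rows with `n_chips`,
#'   `n_samples`, `method`) and `comparisons` (pairwise signed-rank
#'   p-values per level).
#' @export
sample_size_experiment <- function(bundle, chips_to_keep, specs) {
  stopifnot(inherits(bundle, "synth_bundle"))
  cfg <- bundle$config
  if (is.null(cfg$mar_panel)) stop("bundle has no masked chip")
  if (any(chips_to_keep < 2L)) stop("need at least 2 chips per level")
  other <- setdiff(seq_len(cfg$n_chips), cfg$mar_chip)
  recs <- list()
  comps <- list()
  for (k in sort(chips_to_keep)) {
    keep <- c(cfg$mar_chip, other[seq_len(k - 1L)])
    sub <- restrict_bundle(bundle, keep_chips = keep,
                           chip_panel = cfg$mar_panel)
    evs <- list()
    for (mname in names(specs)) {
      imp <- impute(sub$observed, specs[[mname]])
      ev <- evaluate_imputation(imp, sub$truth, sub$observed)
      ev$n_chips <- k
      ev$n_samples <- nrow(sub$observed$values)
      ev$method <- mname
      evs[[mname]] <- ev
      recs[[length(recs) + 1L]] <- ev
    }
    if (length(specs) >= 2L) {
      nm <- names(specs)
      for (a in seq_along(nm)) for (b in seq_along(nm)) {
        if (a >= b) next
        shared <- intersect(evs[[nm[a]]]$assay_id, evs[[nm[b]]]$assay_id)
        ea <- evs[[nm[a]]][match(shared, evs[[nm[a]]]$assay_id), ]
        eb <- evs[[nm[b]]][match(shared, evs[[nm[b]]]$assay_id), ]
        comps[[length(comps) + 1L]] <- data.frame(
          n_chips = k, method_a = nm[a], method_b = nm[b],
          p_pearson = wilcox.test(ea$pearson, eb$pearson,
                                  paired = TRUE, exact = FALSE)$p.value,
          p_rel_var = wilcox.test(ea$rel_var, eb$rel_var,
                                  paired = TRUE, exact = FALSE)$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  comparisons <- if (length(comps)) do.call(rbind, comps) else NULL
  list(records = records, comparisons = comparisons)
}
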