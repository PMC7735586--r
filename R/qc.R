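# Quality-control screens that construct the MCAR mask.
#
# The screens are read-only; only apply_mcar_mask() mutates the dataset,
# moving failed cells into MAR_MISSING and their prior values into the
# paired ground truth.

#' PCA-based sample outlier detection
#'
#' Per panel, computes a principal component decomposition of the
#' panel's assays (missing cells median-filled for the decomposition
#' only; the dataset is never mutated) and flags samples whose score on
#' any of the first `n_components` components lies more than
#' `threshold_sd` robust standard deviations (MAD) from the component
#' median. Defaults are deliberately conservative so that only extreme
#' single-sample artifacts are flagged.
#'
#' @param ds An [npx_dataset()].
#' @param n_components Number of leading components screened.
#' @param threshold_sd Robust-SD multiplier.
#' @return Data frame with columns `sample_id`, `panel`, `component`,
#'   `score` (robust z-score), one row per flagged (sample, panel).
#' @export
pca_outliers <- function(ds, n_components = 2L, threshold_sd = 6) {
  validate_npx(ds)
  out <- list()
  for (panel in unique(ds$assays$panel)) {
    jj <- assay_cols(ds, panel)
    v <- ds$values[, jj, drop = FALSE]
    if (nrow(v) < 3L) stop("panel ", panel, " has fewer than 3 samples")
    # temporary median fill for the decomposition only
    for (j in seq_len(ncol(v))) {
      nas <- is.na(v[, j])
      if (any(nas)) v[nas, j] <- median(v[, j], na.rm = TRUE)
    }
    keep <- apply(v, 2L, function(x) stats::sd(x) > 0)
    v <- v[, keep, drop = FALSE]
    k <- min(n_components, ncol(v), nrow(v) - 1L)
    if (k < 1L) next
    sc <- prcomp(v, center = TRUE, scale. = FALSE, rank. = k)$x
    for (comp in seq_len(k)) {
      s <- sc[, comp]
      md <- median(s)
      rsd <- mad(s)
      if (rsd == 0) next
      z <- (s - md) / rsd
      hit <- which(abs(z) > threshold_sd)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          sample_id = ds$samples$sample_id[hit], panel = panel,
          component = comp, score = z[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(), panel = character(),
                      component = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[c("sample_id", "panel")]), , drop = FALSE]
  res <- res[order(res$panel, res$sample_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# All unordered panel pairs within duplicate groups.
duplicate_pairs <- function(ds) {
  grp <- split(seq_len(nrow(ds$assays)), ds$assays$protein_id)
  grp <- grp[vapply(grp, length, 1L) >= 2L]
  out <- list()
  for (pid in names(grp)) {
    jj <- grp[[pid]]
    cmb <- utils::combn(jj, 2L)
    for (k in seq_len(ncol(cmb)))
      out[[length(out) + 1L]] <- list(protein_id = pid,
                                      a = cmb[1, k], b = cmb[2, k])
  }
  out
}

#' Concordance of duplicate protein assays
#'
#' For each protein measured on more than one panel, computes Pearson
#' and Spearman correlation between every unordered pair of its assays
#' over the samples where both are non-MAR. Concordance of duplicates is
#' the empirical ceiling on imputation accuracy set by measurement noise.
#'
#' @param ds An [npx_dataset()] with at least one duplicate group.
#' @return Data frame with columns `protein_id`, `assay_a`, `assay_b`,
#'   `panel_a`, `panel_b`, `pearson`, `spearman`, `n`.
#' @export
duplicate_concordance <- function(ds) {
  validate_npx(ds)
  pairs <- duplicate_pairs(ds)
  if (!length(pairs)) stop("dataset has no duplicate protein assays")
  rows <- lapply(pairs, function(pr) {
    ok <- ds$mask[, pr$a] != MASK_MAR & ds$mask[, pr$b] != MASK_MAR
    if (sum(ok) < 3L)
      stop("fewer than 3 common observed samples for assays ",
           ds$assays$assay_id[pr$a], " / ", ds$assays$assay_id[pr$b])
    x <- ds$values[ok, pr$a]
    y <- ds$values[ok, pr$b]
    data.frame(protein_id = pr$protein_id,
               assay_a = ds$assays$assay_id[pr$a],
               assay_b = ds$assays$assay_id[pr$b],
               panel_a = ds$assays$panel[pr$a],
               panel_b = ds$assays$panel[pr$b],
               pearson = cor(x, y),
               spearman = cor(x, y, method = "spearman"),
               n = sum(ok), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Detect malfunctioning chips from duplicate-assay deviations
#'
#' For every (panel, chip), computes the median absolute deviation
#' between duplicate-assay pairs (one member on the screened panel, the
#' other elsewhere) restricted to the chip's samples, minus the same
#' statistic over all other chips. A chip whose excess deviation exceeds
#' `deviation_threshold` NPX is flagged; duplicate assays carry the
#' cross-panel reference that exposes a chip producing unreliable
#' values. Panels without duplicate coverage are reported as
#' unscreenable rather than erroring.
#'
#' @param ds An [npx_dataset()].
#' @param deviation_threshold Excess deviation (NPX) above which a chip
#'   is flagged; default 0.5.
#' @return Data frame with columns `panel`, `chip`, `statistic`,
#'   `flagged`, plus an attribute `unscreenable` naming panels without
#'   duplicate coverage.
#' @export
flag_bad_chips <- function(ds, deviation_threshold = 0.5) {
  validate_npx(ds)
  pairs <- duplicate_pairs(ds)
  if (!length(pairs)) stop("chip screening requires duplicate assays")
  panels <- unique(ds$assays$panel)
  out <- list()
  unscreenable <- character()
  for (panel in panels) {
    # pairs with exactly one member on this panel: the partner assay is
    # the off-panel reference
    rel <- Filter(function(pr) {
      xor(ds$assays$panel[pr$a] == panel, ds$assays$panel[pr$b] == panel)
    }, pairs)
    if (!length(rel)) {
      unscreenable <- c(unscreenable, panel)
      next
    }
    chips <- chips_on_panel(ds, panel)
    for (chip in sort(unique(chips))) {
      ii <- chips == chip
      per_pair <- vapply(rel, function(pr) {
        on_p <- if (ds$assays$panel[pr$a] == panel) pr$a else pr$b
        off_p <- if (on_p == pr$a) pr$b else pr$a
        ok <- ds$mask[, on_p] != MASK_MAR & ds$mask[, off_p] != MASK_MAR
        d <- abs(ds$values[, on_p] - ds$values[, off_p])
        inside <- median(d[ok & ii])
        outside <- median(d[ok & !ii])
        inside - outside
      }, numeric(1))
      stat <- median(per_pair, na.rm = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        panel = panel, chip = chip, statistic = stat,
        flagged = is.finite(stat) && stat > deviation_threshold,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(panel = character(), chip = integer(), statistic = numeric(),
               flagged = logical(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "unscreenable") <- unscreenable
  res
}

#' Set failed measurements missing-completely-at-random
#'
#' Masks all cells of flagged chips (that panel's assays x that chip's
#' samples), flagged samples (that panel's assays) and listed
#' (assay, chip) exclusions as `MAR_MISSING`. Prior values (observed or
#' below-LOD) move into a ground-truth object with `eval_mask` true, so
#' the masked cells can later be scored against an imputation.
#'
#' @param ds An [npx_dataset()].
#' @param chip_flags Data frame with columns `panel`, `chip` (optionally
#'   `flagged`, in which case only flagged rows are used), or `NULL`.
#' @param outliers Data frame with columns `sample_id`, `panel`, or `NULL`.
#' @param assay_chip_exclusions Data frame with columns `assay_id`,
#'   `chip`, or `NULL`.
#' @return List with elements `dataset` (masked [npx_dataset()]),
#'   `truth` (an [npx_truth()]) and `n_masked` (cells newly masked).
#' @export
apply_mcar_mask <- function(ds, chip_flags = NULL, outliers = NULL,
                            assay_chip_exclusions = NULL) {
  validate_npx(ds)
  sel <- matrix(FALSE, nrow(ds$values), ncol(ds$values))

  if (!is.null(chip_flags) && nrow(chip_flags)) {
    use <- if ("flagged" %in% names(chip_flags)) chip_flags$flagged else
      rep(TRUE, nrow(chip_flags))
    for (k in which(use)) {
      panel <- chip_flags$panel[k]
      chip <- chip_flags$chip[k]
      jj <- assay_cols(ds, panel)
      if (!length(jj)) stop("chip flag references unknown panel: ", panel)
      ii <- chips_on_panel(ds, panel) == chip
      if (!any(ii)) stop("chip flag references empty chip ", chip,
                         " on panel ", panel)
      sel[ii, jj] <- TRUE
    }
  }
  if (!is.null(outliers) && nrow(outliers)) {
    for (k in seq_len(nrow(outliers))) {
      i <- match(outliers$sample_id[k], ds$samples$sample_id)
      if (is.na(i)) stop("outlier references unknown sample: ",
                         outliers$sample_id[k])
      jj <- assay_cols(ds, outliers$panel[k])
      if (!length(jj)) stop("outlier references unknown panel: ",
                            outliers$panel[k])
      sel[i, jj] <- TRUE
    }
  }
  if (!is.null(assay_chip_exclusions) && nrow(assay_chip_exclusions)) {
    for (k in seq_len(nrow(assay_chip_exclusions))) {
      j <- match(assay_chip_exclusions$assay_id[k], ds$assays$assay_id)
      if (is.na(j)) stop("exclusion references unknown assay: ",
                         assay_chip_exclusions$assay_id[k])
      panel <- ds$assays$panel[j]
      ii <- chips_on_panel(ds, panel) == assay_chip_exclusions$chip[k]
      sel[ii, j] <- TRUE
    }
  }

  sel <- sel & ds$mask != MASK_MAR  # already-missing cells stay as they are
  new_mask <- ds$mask
  new_mask[sel] <- MASK_MAR
  empty <- colSums(new_mask != MASK_MAR) == 0L & colSums(ds$mask != MASK_MAR) > 0L
  if (any(empty))
    stop("masking would empty assay ", ds$assays$assay_id[which(empty)[1]])

  truth_vals <- ds$values
  truth_vals[is.na(truth_vals)] <- 0  # placeholder at previously-MAR cells
  truth <- npx_truth(truth_vals, sel)
  ds$values[sel] <- NA_real_
  ds$mask <- new_mask
  list(dataset = validate_npx(ds), truth = truth, n_masked = sum(sel))
}
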