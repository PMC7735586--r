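#' @useDynLib peabench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var cor median mad sd rnorm runif qnorm pnorm pt
#'   prcomp quantile wilcox.test coef predict
#' @importFrom utils read.delim write.table
NULL

# Cell mask codes: every cell of an NPX matrix is in exactly one state.
MASK_OBSERVED <- 0L
MASK_MAR <- 1L
MASK_BELOW_LOD <- 2L

#' Cell mask codes for NPX datasets
#'
#' Each cell of an NPX matrix is in exactly one of three states:
#' `OBSERVED` (a measured, finite NPX value), `MAR_MISSING` (missing
#' completely at random, e.g. a failed chip; the value is unknown) and
#' `BELOW_LOD` (left-censored at the assay's limit of detection; after
#' [subtract_lod()] these cells carry the value 0).
#'
#' @return Named integer vector mapping state names to the codes used in
#'   mask matrices and in the mask flag file written by [write_npx()].
#' @export
#' @examples
#' mask_codes()
mask_codes <- function() {
  c(OBSERVED = MASK_OBSERVED, MAR_MISSING = MASK_MAR, BELOW_LOD = MASK_BELOW_LOD)
}

#' Construct an NPX dataset
#'
#' Container for a samples x assays matrix of NPX values (log2-scale
#' relative protein expression) together with the per-cell state mask and
#' assay/sample metadata. This is the central data structure consumed by
#' the preprocessing, QC, imputation and evaluation functions.
#'
#' @param values Numeric matrix, samples in rows, assays in columns.
#'   Row names are sample ids, column names assay ids. Cells whose mask
#'   state is `MAR_MISSING` must be `NA`; all other cells must be finite.
#' @param mask Integer matrix of the same dimension with values from
#'   [mask_codes()].
#' @param assays Data frame with columns `assay_id`, `protein_id`,
#'   `panel`, `lod` (one row per column of `values`, same order).
#'   Duplicate assays of one protein share `protein_id`.
#' @param samples Data frame with column `sample_id` (one row per row of
#'   `values`, same order) plus one integer column `chip_<panel>` per
#'   panel giving the 1-based chip assignment of each sample on that
#'   panel (chips hold at most 88 samples).
#' @return An object of class `npx_dataset`.
#' @export
npx_dataset <- function(values, mask, assays, samples) {
  ds <- structure(
    list(values = values, mask = mask, assays = assays, samples = samples),
    class = "npx_dataset"
  )
  validate_npx(ds)
  ds
}

#' Validate an NPX dataset
#'
#' Checks the structural invariants of an [npx_dataset()]: matching
#' dimensions and ids, unique assay and sample ids, a legal tri-state
#' mask, finite values at observed cells, `NA` at missing-at-random
#' cells, and chip capacity (no chip holds more than 88 samples).
#'
#' @param ds An `npx_dataset`.
#' @return `ds`, invisibly. Errors describe the offending row or column.
#' @export
validate_npx <- function(ds) {
  stopifnot(inherits(ds, "npx_dataset"))
  v <- ds$values
  m <- ds$mask
  if (!is.matrix(v) || !is.numeric(v)) stop("values must be a numeric matrix")
  if (!is.matrix(m) || !all(dim(m) == dim(v)))
    stop("mask must be a matrix with the same dimensions as values")
  if (!all(m %in% c(MASK_OBSERVED, MASK_MAR, MASK_BELOW_LOD)))
    stop("mask contains codes outside {OBSERVED, MAR_MISSING, BELOW_LOD}")

  a <- ds$assays
  s <- ds$samples
  need_a <- c("assay_id", "protein_id", "panel", "lod")
  if (!all(need_a %in% names(a)))
    stop("assay metadata must have columns: ", paste(need_a, collapse = ", "))
  if (anyDuplicated(a$assay_id))
    stop("duplicate assay_id: ", a$assay_id[duplicated(a$assay_id)][1])
  if (anyDuplicated(s$sample_id))
    stop("duplicate sample_id: ", s$sample_id[duplicated(s$sample_id)][1])
  if (nrow(a) != ncol(v))
    stop("assay metadata has ", nrow(a), " rows but values has ", ncol(v), " columns")
  if (nrow(s) != nrow(v))
    stop("sample metadata has ", nrow(s), " rows but values has ", nrow(v), " rows")
  if (!is.null(colnames(v)) && !identical(colnames(v), a$assay_id)) {
    bad <- setdiff(union(colnames(v), a$assay_id),
                   intersect(colnames(v), a$assay_id))
    stop("assay ids of values and metadata disagree",
         if (length(bad)) paste0(" (unmatched: ", paste(utils::head(bad, 5), collapse = ", "), ")"))
  }
  if (!is.null(rownames(v)) && !identical(rownames(v), s$sample_id))
    stop("sample ids of values and metadata disagree")

  panels <- unique(a$panel)
  chip_cols <- paste0("chip_", panels)
  miss <- setdiff(chip_cols, names(s))
  if (length(miss))
    stop("sample metadata lacks chip assignment column(s): ",
         paste(miss, collapse = ", "))
  for (cc in chip_cols) {
    chips <- s[[cc]]
    if (anyNA(chips) || any(chips < 1 | chips != floor(chips)))
      stop("chip assignments in ", cc, " must be positive integers")
    if (any(table(chips) > 88))
      stop("a chip in ", cc, " holds more than 88 samples")
  }

  obs <- m == MASK_OBSERVED
  if (any(!is.finite(v[obs]))) {
    j <- which(colSums(!is.finite(v) & obs) > 0)[1]
    stop("non-finite value at an OBSERVED cell in assay ", a$assay_id[j])
  }
  if (any(!is.na(v[m == MASK_MAR])))
    stop("MAR_MISSING cells must carry NA values")
  if (any(!is.finite(v[m == MASK_BELOW_LOD])))
    stop("BELOW_LOD cells must carry finite (censored) values")
  invisible(ds)
}

#' @export
print.npx_dataset <- function(x, ...) {
  tab <- table(factor(x$mask, levels = mask_codes(), labels = names(mask_codes())))
  cat(sprintf("npx_dataset: %d samples x %d assays, %d panel(s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$assays$panel))))
  cat(sprintf("  cells: %d observed, %d MAR missing, %d below LOD\n",
              tab[["OBSERVED"]], tab[["MAR_MISSING"]], tab[["BELOW_LOD"]]))
  invisible(x)
}

#' Ground truth paired with a masked NPX dataset
#'
#' Holds the complete value matrix and a logical `eval_mask` marking the
#' cells at which imputation is to be scored. The evaluated cells are a
#' subset of the paired dataset's `MAR_MISSING` cells (in the motivating
#' scenario they are the remeasured values of a failed chip; on synthetic
#' data they are the generator's hidden truth).
#'
#' @param values Complete numeric matrix (samples x assays).
#' @param eval_mask Logical matrix of the same dimension.
#' @return An object of class `npx_truth`.
#' @export
npx_truth <- function(values, eval_mask) {
  stopifnot(is.matrix(values), is.logical(eval_mask),
            all(dim(values) == dim(eval_mask)))
  if (any(!is.finite(values[eval_mask])))
    stop("ground truth must be finite at all evaluated cells")
  structure(list(values = values, eval_mask = eval_mask), class = "npx_truth")
}

#' @export
print.npx_truth <- function(x, ...) {
  cat(sprintf("npx_truth: %d x %d matrix, %d evaluated cells\n",
              nrow(x$values), ncol(x$values), sum(x$eval_mask)))
  invisible(x)
}

# Chip assignment of every sample on one panel.
chips_on_panel <- function(ds, panel) {
  cc <- paste0("chip_", panel)
  if (!cc %in% names(ds$samples)) stop("unknown panel: ", panel)
  ds$samples[[cc]]
}

# Column indices of the assays on one panel.
assay_cols <- function(ds, panel) which(ds$assays$panel == panel)

#' Subtract the limit of detection from all assays
#'
#' NPX processing sets values at or below the limit of detection (LOD) to
#' the LOD itself; subtracting the per-assay LOD re-expresses every assay
#' relative to its detection limit, so that censored cells carry the
#' value exactly 0. The transform is idempotent: afterwards every assay's
#' `lod` field is 0.
#'
#' @param ds An [npx_dataset()] whose assays all have a finite `lod`.
#' @return The transformed `npx_dataset`.
#' @export
subtract_lod <- function(ds) {
  validate_npx(ds)
  lod <- ds$assays$lod
  if (any(!is.finite(lod)))
    stop("missing LOD for assay ", ds$assays$assay_id[which(!is.finite(lod))[1]])
  ds$values <- sweep(ds$values, 2L, lod, `-`)
  ds$values[ds$mask == MASK_BELOW_LOD] <- 0
  ds$assays$lod <- 0
  ds
}

#' Intensity-based inter-plate normalization
#'
#' Aligns chip (plate) medians to the overall median by an additive
#' per-chip shift, separately within each panel. With
#' `scope = "per_assay"` (the convention for intensity normalization of
#' NPX data) each assay's chip medians are aligned to that assay's
#' overall median; with `scope = "per_chip_global"` a single shift per
#' chip aligns the chip's pooled median across the panel's assays.
#' Observed and below-LOD values shift together; the mask is unchanged.
#'
#' @param ds An [npx_dataset()] with chip assignments for every sample.
#' @param scope `"per_assay"` (default) or `"per_chip_global"`.
#' @param include_below_lod Should below-LOD (censored) cells enter the
#'   medians? Default `FALSE`: they are censored, not measured.
#' @return The normalized `npx_dataset`.
#' @export
interplate_normalize <- function(ds, scope = c("per_assay", "per_chip_global"),
                                 include_below_lod = FALSE) {
  scope <- match.arg(scope)
  validate_npx(ds)
  v <- ds$values
  use <- ds$mask == MASK_OBSERVED
  if (include_below_lod) use <- use | ds$mask == MASK_BELOW_LOD
  shiftable <- ds$mask != MASK_MAR

  for (panel in unique(ds$assays$panel)) {
    jj <- assay_cols(ds, panel)
    chips <- chips_on_panel(ds, panel)
    for (chip in sort(unique(chips))) {
      ii <- chips == chip
      if (!any(use[ii, jj, drop = FALSE]))
        stop("chip ", chip, " on panel ", panel, " has no usable values")
    }
    if (scope == "per_assay") {
      for (j in jj) {
        vals <- v[, j]
        ok <- use[, j]
        overall <- median(vals[ok])
        for (chip in unique(chips)) {
          ii <- chips == chip
          if (!any(ok & ii)) next  # assay unusable on this chip; skip shift
          shift <- overall - median(vals[ok & ii])
          sel <- ii & shiftable[, j]
          v[sel, j] <- v[sel, j] + shift
        }
      }
    } else {
      vals <- v[, jj, drop = FALSE]
      ok <- use[, jj, drop = FALSE]
      overall <- median(vals[ok])
      for (chip in unique(chips)) {
        ii <- chips == chip
        shift <- overall - median(vals[ii, , drop = FALSE][ok[ii, , drop = FALSE]])
        sel <- shiftable[, jj, drop = FALSE] & ii
        v[, jj][sel] <- v[, jj][sel] + shift
      }
    }
  }
  ds$values <- v
  ds
}
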