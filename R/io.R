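# Delimited-text readers/writers for NPX datasets.
#
# File dialect: TSV by default (CSV accepted via `sep`), "NA" as the
# missing-value sentinel, numerics written with full precision ("%.17g")
# so a write/read round trip restores doubles exactly.

read_table_strict <- function(path, sep = "\t", as_character = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE,
             na.strings = character(0),
             colClasses = if (as_character) "character" else NA)
}

parse_numeric_cell <- function(x, sentinel, what) {
  x[x == sentinel | x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop("non-numeric cell in ", what, " (value '", x[bad[1]], "')")
  out
}

#' Read an NPX dataset from delimited text files
#'
#' Reads a values table (first column `sample_id`, remaining columns one
#' per assay), an assay metadata table (`assay_id`, `protein_id`,
#' `panel`, `lod`) and a sample metadata table (`sample_id` plus one
#' `chip_<panel>` column per panel). Empty cells and the missing-value
#' sentinel become `MAR_MISSING`; an optional flag table of the same
#' shape as the values (entries from [mask_codes()], or just 0/1 below-LOD
#' indicators) marks `BELOW_LOD` cells.
#'
#' @param values_path,assay_meta_path,sample_meta_path File paths.
#' @param flags_path Optional path to a per-cell mask flag table.
#' @param sep Field separator (default tab; use "," for CSV).
#' @param sentinel String coding a missing value (default `"NA"`).
#' @return An [npx_dataset()].
#' @export
read_npx <- function(values_path, assay_meta_path, sample_meta_path,
                     flags_path = NULL, sep = "\t", sentinel = "NA") {
  vt <- read_table_strict(values_path, sep, as_character = TRUE)
  if (names(vt)[1] != "sample_id")
    stop("values table must have 'sample_id' as its first column")
  assays <- read_table_strict(assay_meta_path, sep)
  samples <- read_table_strict(sample_meta_path, sep)

  aid <- names(vt)[-1]
  if (!setequal(aid, assays$assay_id)) {
    bad <- c(setdiff(aid, assays$assay_id), setdiff(assays$assay_id, aid))
    stop("assay ids of values table and assay metadata disagree ",
         "(unmatched: ", paste(utils::head(bad, 5), collapse = ", "), ")")
  }
  assays <- assays[match(aid, assays$assay_id), , drop = FALSE]
  rownames(assays) <- NULL
  assays$lod <- parse_numeric_cell(as.character(assays$lod), sentinel, "assay lod")

  sid <- as.character(vt$sample_id)
  if (!setequal(sid, samples$sample_id)) {
    bad <- c(setdiff(sid, samples$sample_id), setdiff(samples$sample_id, sid))
    stop("sample ids of values table and sample metadata disagree ",
         "(unmatched: ", paste(utils::head(bad, 5), collapse = ", "), ")")
  }
  samples <- samples[match(sid, samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  samples$sample_id <- as.character(samples$sample_id)

  v <- matrix(NA_real_, nrow(vt), length(aid), dimnames = list(sid, aid))
  for (j in seq_along(aid))
    v[, j] <- parse_numeric_cell(as.character(vt[[j + 1L]]), sentinel,
                                 paste0("assay column ", aid[j]))
  mask <- matrix(MASK_OBSERVED, nrow(v), ncol(v), dimnames = dimnames(v))
  mask[is.na(v)] <- MASK_MAR

  if (!is.null(flags_path)) {
    ft <- read_table_strict(flags_path, sep, as_character = TRUE)
    if (names(ft)[1] != "sample_id" || !identical(names(ft)[-1], aid) ||
        nrow(ft) != nrow(vt))
      stop("flag table must have the same layout as the values table")
    f <- as.matrix(ft[match(sid, as.character(ft$sample_id)), -1, drop = FALSE])
    storage.mode(f) <- "integer"
    if (!all(f %in% c(MASK_OBSERVED, MASK_MAR, MASK_BELOW_LOD)))
      stop("flag table entries must be mask codes 0/1/2")
    mask[f == MASK_BELOW_LOD & mask != MASK_MAR] <- MASK_BELOW_LOD
    if (any(f == MASK_MAR & mask != MASK_MAR)) {
      mask[f == MASK_MAR] <- MASK_MAR
      v[f == MASK_MAR] <- NA_real_
    }
  }
  npx_dataset(v, mask, assays, samples)
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

write_one <- function(df, path, sep, sentinel) {
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              na = sentinel)
}

#' Write an NPX dataset to delimited text files
#'
#' Emits `values.tsv`, `mask_flags.tsv`, `assay_meta.tsv` and
#' `sample_meta.tsv` under `out_dir` such that [read_npx()] reproduces
#' the dataset exactly (numerics are written in full "%.17g" precision).
#'
#' @param ds An [npx_dataset()].
#' @param out_dir Output directory (created if absent).
#' @param sep Field separator.
#' @param sentinel Missing-value sentinel.
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_npx <- function(ds, out_dir, sep = "\t", sentinel = "NA") {
  validate_npx(ds)
  if (nrow(ds$values) == 0L || ncol(ds$values) == 0L)
    stop("refusing to write an empty dataset")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  sid <- ds$samples$sample_id
  vt <- data.frame(sample_id = sid, apply(ds$values, 2L, fmt_num),
                   check.names = FALSE)
  ft <- data.frame(sample_id = sid, ds$mask, check.names = FALSE)
  am <- ds$assays
  am$lod <- fmt_num(am$lod)

  paths <- c(values = file.path(out_dir, "values.tsv"),
             flags = file.path(out_dir, "mask_flags.tsv"),
             assays = file.path(out_dir, "assay_meta.tsv"),
             samples = file.path(out_dir, "sample_meta.tsv"))
  write_one(vt, paths[["values"]], sep, sentinel)
  write_one(ft, paths[["flags"]], sep, sentinel)
  write_one(am, paths[["assays"]], sep, sentinel)
  write_one(ds$samples, paths[["samples"]], sep, sentinel)
  invisible(paths)
}

#' Read back a dataset written by [write_npx()]
#'
#' @param dir Directory previously passed to [write_npx()].
#' @inheritParams read_npx
#' @return An [npx_dataset()].
#' @export
read_npx_dir <- function(dir, sep = "\t", sentinel = "NA") {
  read_npx(file.path(dir, "values.tsv"), file.path(dir, "assay_meta.tsv"),
           file.path(dir, "sample_meta.tsv"),
           flags_path = file.path(dir, "mask_flags.tsv"),
           sep = sep, sentinel = sentinel)
}
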