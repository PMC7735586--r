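test_that("constructor validates structure and reports the offender", {
  ds <- tiny_dataset()
  expect_s3_class(ds, "npx_dataset")

  bad <- ds
  bad$assays <- bad$assays[1:2, ]
  expect_error(validate_npx(bad), "2 rows")

  bad <- ds
  bad$assays$assay_id[2] <- "a1"
  expect_error(validate_npx(bad), "duplicate assay_id")

  bad <- ds
  bad$samples$chip_PanB <- NULL
  expect_error(validate_npx(bad), "chip_PanB")

  bad <- ds
  bad$values[1, 1] <- NA
  expect_error(validate_npx(bad), "OBSERVED")

  # chips hold at most 88 samples
  n <- 90
  v <- matrix(rnorm(n), n, 1, dimnames = list(paste0("s", 1:n), "a1"))
  expect_error(
    npx_dataset(v, matrix(MASK_OBSERVED_CODE, n, 1, dimnames = dimnames(v)),
                data.frame(assay_id = "a1", protein_id = "p1",
                           panel = "P", lod = 0),
                data.frame(sample_id = paste0("s", 1:n),
                           chip_P = rep(1L, n))),
    "more than 88")
})

test_that("read_npx parses values, sentinels and flag tables", {
  dir <- withr::local_tempdir()
  writeLines(c("sample_id\tx\ty",
               "s1\t1.5\t2.0",
               "s2\tNA\t3.0",
               "s3\t2.5\t4.0"), file.path(dir, "v.tsv"))
  writeLines(c("assay_id\tprotein_id\tpanel\tlod",
               "x\tpx\tP\t0", "y\tpy\tP\t1"), file.path(dir, "a.tsv"))
  writeLines(c("sample_id\tchip_P", "s1\t1", "s2\t1", "s3\t2"),
             file.path(dir, "s.tsv"))
  ds <- read_npx(file.path(dir, "v.tsv"), file.path(dir, "a.tsv"),
                 file.path(dir, "s.tsv"))
  expect_equal(sum(ds$mask == MASK_MAR_CODE), 1L)
  expect_equal(sum(ds$mask == MASK_OBSERVED_CODE), 5L)
  expect_true(is.na(ds$values[2, "x"]))
  expect_equal(ds$values[1, "y"], 2.0)

  # below-LOD flags
  writeLines(c("sample_id\tx\ty", "s1\t0\t2", "s2\t0\t0", "s3\t2\t0"),
             file.path(dir, "f.tsv"))
  ds2 <- read_npx(file.path(dir, "v.tsv"), file.path(dir, "a.tsv"),
                  file.path(dir, "s.tsv"), flags_path = file.path(dir, "f.tsv"))
  expect_equal(unname(ds2$mask[1, "y"]), MASK_BELOW_LOD_CODE)
  expect_equal(unname(ds2$mask[3, "x"]), MASK_BELOW_LOD_CODE)
  expect_equal(unname(ds2$mask[2, "x"]), MASK_MAR_CODE)

  # unmatched assay metadata is named
  writeLines(c("assay_id\tprotein_id\tpanel\tlod", "x\tpx\tP\t0"),
             file.path(dir, "a_short.tsv"))
  expect_error(read_npx(file.path(dir, "v.tsv"), file.path(dir, "a_short.tsv"),
                        file.path(dir, "s.tsv")), "y")

  # non-numeric cell is named
  writeLines(c("sample_id\tx\ty", "s1\t1.5\toops", "s2\t2\t3", "s3\t2.5\t4"),
             file.path(dir, "v_bad.tsv"))
  expect_error(read_npx(file.path(dir, "v_bad.tsv"), file.path(dir, "a.tsv"),
                        file.path(dir, "s.tsv")), "oops")
})

test_that("write/read round trip is lossless", {
  ds <- tiny_dataset()
  dir <- withr::local_tempdir()
  write_npx(ds, dir)
  ds2 <- read_npx_dir(dir)
  expect_equal(ds2$values, ds$values)
  expect_equal(unname(ds2$mask), unname(ds$mask))
  expect_equal(ds2$assays, ds$assays)
  expect_equal(ds2$samples, ds$samples)

  # irrational values survive full-precision round trip
  ds$values[1, 1] <- pi * 1e3
  ds$values[2, 2] <- sqrt(2) * 1e-7
  write_npx(ds, dir)
  expect_identical(read_npx_dir(dir)$values[1, 1], ds$values[1, 1])
  expect_identical(read_npx_dir(dir)$values[2, 2], ds$values[2, 2])

  # empty dataset refused
  empty <- ds
  empty$values <- ds$values[0, , drop = FALSE]
  empty$mask <- ds$mask[0, , drop = FALSE]
  empty$samples <- ds$samples[0, , drop = FALSE]
  expect_error(write_npx(empty, dir), "empty")
})

test_that("subtract_lod zeroes censored cells and is idempotent", {
  ds <- tiny_dataset()
  out <- subtract_lod(ds)
  # a1: lod 1 -> observed 5, 3.5 become 4, 2.5; censored cell exactly 0
  expect_equal(unname(out$values[1:2, "a1"]), c(4.0, 2.5))
  expect_identical(unname(out$values[3, "a1"]), 0)
  expect_equal(out$assays$lod, c(0, 0, 0))
  expect_equal(subtract_lod(out), out)

  # all-below-LOD assay becomes an all-zero column
  ds2 <- ds
  ds2$mask[, "a1"] <- MASK_BELOW_LOD_CODE
  ds2$values[, "a1"] <- ds2$assays$lod[1]
  expect_true(all(subtract_lod(ds2)$values[, "a1"] == 0))

  ds3 <- ds
  ds3$assays$lod[2] <- NA
  expect_error(subtract_lod(ds3), "a2")
})

test_that("interplate_normalize aligns chip medians to the overall median", {
  # two chips whose per-assay medians are 5 and 7 -> both end at 6
  n <- 20
  v <- matrix(rep(c(5, 7), each = n / 2), n, 2)
  v <- v + rep(c(-0.1, 0.1), n / 2)  # symmetric jitter keeps medians exact
  colnames(v) <- c("a1", "a2"); rownames(v) <- paste0("s", 1:n)
  ds <- npx_dataset(v, matrix(MASK_OBSERVED_CODE, n, 2, dimnames = dimnames(v)),
                    data.frame(assay_id = c("a1", "a2"),
                               protein_id = c("p1", "p2"),
                               panel = "P", lod = 0),
                    data.frame(sample_id = rownames(v),
                               chip_P = rep(1:2, each = n / 2)))
  out <- interplate_normalize(ds)
  for (chip in 1:2) for (j in 1:2)
    expect_equal(median(out$values[ds$samples$chip_P == chip, j]),
                 median(out$values[, j]))

  # single-chip dataset is unchanged
  ds1 <- ds
  ds1$samples$chip_P <- rep(1L, n)
  expect_equal(interplate_normalize(ds1)$values, ds1$values)
})

test_that("normalization drives every chip median to the overall median", {
  b <- unit_bundle(seed = 3, chip_effect_sd = 0.8, mar_panel = NULL,
                   mar_chip = NULL, extra_mar_rate = 0)
  out <- interplate_normalize(b$observed)
  for (panel in unique(out$assays$panel)) {
    jj <- which(out$assays$panel == panel)
    chips <- out$samples[[paste0("chip_", panel)]]
    for (j in jj) {
      ok <- out$mask[, j] == MASK_OBSERVED_CODE
      overall <- median(out$values[ok, j])
      for (chip in unique(chips)) {
        sel <- ok & chips == chip
        if (sum(sel) == 0) next
        expect_lt(abs(median(out$values[sel, j]) - overall), 1e-9)
      }
    }
  }
})

test_that("transforms are equivariant under sample relabeling", {
  b <- unit_bundle(seed = 4, chip_effect_sd = 0.5, mar_panel = NULL,
                   mar_chip = NULL, extra_mar_rate = 0)
  ds <- b$observed
  set.seed(9)
  perm <- sample(nrow(ds$values))
  dsp <- ds
  dsp$values <- ds$values[perm, , drop = FALSE]
  dsp$mask <- ds$mask[perm, , drop = FALSE]
  dsp$samples <- ds$samples[perm, , drop = FALSE]
  rownames(dsp$samples) <- NULL

  out <- interplate_normalize(subtract_lod(ds))
  outp <- interplate_normalize(subtract_lod(dsp))
  expect_equal(outp$values, out$values[perm, , drop = FALSE])
  expect_equal(unname(outp$mask), unname(out$mask[perm, , drop = FALSE]))
})
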