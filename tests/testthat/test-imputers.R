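make_column_ds <- function(values, mask = NULL) {
  n <- length(values)
  v <- cbind(a1 = values, a2 = seq_len(n) / n)
  rownames(v) <- paste0("s", seq_len(n))
  m <- matrix(MASK_OBSERVED_CODE, n, 2, dimnames = dimnames(v))
  m[is.na(values), 1] <- MASK_MAR_CODE
  if (!is.null(mask)) m[, 1] <- mask
  npx_dataset(v, m,
              data.frame(assay_id = c("a1", "a2"),
                         protein_id = c("p1", "p2"), panel = "P", lod = -99),
              data.frame(sample_id = rownames(v),
                         chip_P = rep(seq_len(ceiling(n / 80)),
                                      each = 80)[seq_len(n)]))
}

test_that("mean imputation fills column means and is identity without missing", {
  ds <- make_column_ds(c(1, 2, NA, 3))
  out <- impute_mean(ds)
  expect_equal(unname(out$values[3, 1]), 2.0)
  # observed cells untouched
  expect_equal(out$values[-3, ], ds$values[-3, ])

  full <- make_column_ds(c(1, 2, 2.5, 3))
  expect_equal(impute_mean(full)$values, full$values)

  empty <- make_column_ds(c(NA, NA, NA, NA))
  expect_error(impute_mean(empty), "observed")
})

test_that("random imputation draws from the observed multiset, reproducibly", {
  set.seed(3)
  vals <- c(rnorm(60), rep(NA, 40))
  ds <- make_column_ds(vals)
  spec <- imputer_spec("RANDOM", seed = 42)
  out1 <- impute_random(ds, spec)
  out2 <- impute_random(ds, spec)
  expect_identical(out1$values, out2$values)
  filled <- out1$values[is.na(vals), 1]
  expect_true(all(filled %in% vals[!is.na(vals)]))
  out3 <- impute_random(ds, imputer_spec("RANDOM", seed = 43))
  expect_false(identical(out1$values, out3$values))
})

test_that("truncated normal draws honor bounds and closed-form moments", {
  x <- truncnorm_draw(1e5, 0, 1, seed = 1)
  expect_lt(abs(mean(x)), 0.02)

  h <- truncnorm_draw(1e5, 0, 1, lo = 0, seed = 2)
  expect_true(all(h >= 0))
  expect_lt(abs(mean(h) - sqrt(2 / pi)), 0.02)  # half-normal mean

  b <- truncnorm_draw(1e4, 1, 2, lo = -0.5, hi = 0.7, seed = 3)
  expect_true(all(b >= -0.5 & b <= 0.7))

  expect_equal(truncnorm_draw(3, c(-5, 0, 5), 0, lo = -1, hi = 1),
               c(-1, 0, 1))
  expect_error(truncnorm_draw(1, 0, 1, lo = 2, hi = 1), "lo <= hi")
  expect_error(truncnorm_draw(1, 0, -1), "sigma")
})

test_that("iterative forest recovers a zero-noise duplicate assay", {
  fx <- duplicate_info_dataset(n = 300, n_miss = 50, seed = 6)
  imp <- impute_rf(fx$ds, fast_rf_spec(seed = 6))
  cells <- fx$truth$eval_mask[, 1]
  expect_gt(cor(imp$values[cells, 1], fx$truth$values[cells, 1]), 0.95)
  expect_true(all(is.finite(imp$oob_nrmse[1])))
  expect_lt(imp$oob_nrmse[["a1"]], 0.5)
})

test_that("forest imputation degenerates gracefully without information", {
  set.seed(7)
  n <- 400; p <- 6
  v <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", 1:n), paste0("a", 1:p)))
  truth <- v
  m <- matrix(MASK_OBSERVED_CODE, n, p, dimnames = dimnames(v))
  m[1:80, 1] <- MASK_MAR_CODE
  v[1:80, 1] <- NA
  ds <- npx_dataset(v, m,
                    data.frame(assay_id = colnames(v),
                               protein_id = paste0("p", 1:p),
                               panel = "P", lod = -99),
                    data.frame(sample_id = rownames(v),
                               chip_P = rep(1:5, each = 80)))
  imp <- suppressWarnings(impute_rf(ds, fast_rf_spec(seed = 7)))
  err <- imp$values[1:80, 1] - truth[1:80, 1]
  expect_lt(abs(cor(imp$values[1:80, 1], truth[1:80, 1])), 0.25)
  expect_lt(abs(nrmse(truth[1:80, 1], imp$values[1:80, 1]) - 1), 0.25)
  # near mean imputation: little variance in the filled cells
  expect_lt(var(imp$values[1:80, 1]) / var(truth[1:80, 1]), 0.5)
})

test_that("forest imputation is deterministic under seed", {
  fx <- duplicate_info_dataset(n = 150, n_miss = 30, seed = 8)
  i1 <- impute_rf(fx$ds, fast_rf_spec(seed = 5))
  i2 <- impute_rf(fx$ds, fast_rf_spec(seed = 5))
  expect_identical(i1$values, i2$values)
  expect_identical(i1$oob_nrmse, i2$oob_nrmse)
  i3 <- impute_rf(fx$ds, fast_rf_spec(seed = 6))
  expect_false(identical(i1$values, i3$values))
})

test_that("gibbs sampler respects truncation bounds", {
  fx <- duplicate_info_dataset(n = 150, n_miss = 30, seed = 9)
  spec <- fast_gibbs_spec(seed = 9, lo = -0.3, hi = 0.3)
  imp <- impute_gibbs_en(fx$ds, spec)
  cells <- fx$truth$eval_mask
  expect_true(all(imp$values[cells] >= -0.3 & imp$values[cells] <= 0.3))
})

test_that("gibbs sampler approaches the elastic-net fit as noise vanishes", {
  # exact linear dependence: residual sd ~ 0, draws collapse onto the
  # conditional mean, so imputed cells track the truth almost exactly
  set.seed(10)
  n <- 200
  x <- rnorm(n); z <- rnorm(n)
  v <- cbind(a1 = 2 * x - z, a2 = x, a3 = z, a4 = rnorm(n))
  rownames(v) <- paste0("s", 1:n)
  truth <- v
  m <- matrix(MASK_OBSERVED_CODE, n, 4, dimnames = dimnames(v))
  m[1:40, 1] <- MASK_MAR_CODE
  v[1:40, 1] <- NA
  ds <- npx_dataset(v, m,
                    data.frame(assay_id = colnames(v),
                               protein_id = paste0("p", 1:4),
                               panel = "P", lod = -99),
                    data.frame(sample_id = rownames(v),
                               chip_P = rep(1:4, each = 50)))
  imp <- impute_gibbs_en(ds, fast_gibbs_spec(seed = 10, fixed_lambda = 1e-4))
  expect_gt(cor(imp$values[1:40, 1], truth[1:40, 1]), 0.999)
})

test_that("gibbs sampler is deterministic under seed and traces sweeps", {
  fx <- duplicate_info_dataset(n = 150, n_miss = 30, seed = 11)
  i1 <- impute_gibbs_en(fx$ds, fast_gibbs_spec(seed = 4))
  i2 <- impute_gibbs_en(fx$ds, fast_gibbs_spec(seed = 4))
  expect_identical(i1$values, i2$values)
  expect_length(i1$trace, 6L)
  i3 <- impute_gibbs_en(fx$ds, fast_gibbs_spec(seed = 5))
  expect_false(identical(i1$values, i3$values))
})

test_that("no imputer touches observed or below-LOD cells", {
  b <- unit_bundle(seed = 26)
  ds <- b$observed
  keep <- ds$mask != MASK_MAR_CODE
  specs <- list(imputer_spec("MEAN"), imputer_spec("RANDOM", seed = 2),
                fast_rf_spec(seed = 2), fast_gibbs_spec(seed = 2))
  for (spec in specs) {
    out <- impute(ds, spec)
    expect_identical(out$values[keep], ds$values[keep])
    expect_true(all(is.finite(out$values)))
  }
})
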