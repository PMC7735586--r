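test_that("nrmse and rel_var match hand-computed values exactly", {
  expect_equal(nrmse(c(0, 2), c(1, 1)), sqrt(1 / 2), tolerance = 1e-12)
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  x <- c(0.3, 1.7, -2.2, 0.9)
  expect_equal(rel_var(x, x), 1.0)
  expect_equal(rel_var(x, 2 * x), 4.0, tolerance = 1e-12)
  expect_equal(rel_var(x, rep(5, 4)), 0.0)
  expect_error(nrmse(c(1, 1), c(1, 2)), "variance")
  expect_error(nrmse(1, 1), "at least 2")
  expect_error(rel_var(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("metrics obey shift/scale invariances and the mean-fill closed form", {
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(nrmse(x + 3, y + 3), nrmse(x, y))
    expect_equal(nrmse(2.5 * x, 2.5 * y), nrmse(x, y))
    expect_equal(rel_var(x + 3, y + 3), rel_var(x, y))
    expect_equal(rel_var(-1.7 * x, -1.7 * y), rel_var(x, y))
    # imputing every cell by the cells' own mean: nrmse = sqrt((n-1)/n)
    expect_equal(nrmse(x, rep(mean(x), n)), sqrt((n - 1) / n),
                 tolerance = 1e-12)
  }
})

test_that("evaluate_imputation scores eval cells only", {
  b <- unit_bundle(seed = 31)
  ds <- b$observed
  # perfect imputation: plant the truth at all masked cells
  perfect <- impute_mean(ds)
  perfect$values[b$truth$eval_mask] <- b$truth$values[b$truth$eval_mask]
  ev <- evaluate_imputation(perfect, b$truth, ds)
  expect_true(all(abs(ev$pearson - 1) < 1e-12, na.rm = TRUE))
  expect_true(all(ev$nrmse < 1e-12))
  expect_true(all(abs(ev$rel_var - 1) < 1e-12))
  expect_true(all(ev$n_eval_cells >= 3))

  # mean imputation: rel_var exactly 0 wherever >1 cell is filled
  ev_mean <- evaluate_imputation(impute_mean(ds), b$truth, ds)
  expect_true(all(ev_mean$rel_var == 0))
  expect_true(all(is.na(ev_mean$pearson)))

  # error_ratio appears when a measurement-error reference is given
  msd <- stats::setNames(rep(0.5, ncol(ds$values)), ds$assays$assay_id)
  ev_r <- evaluate_imputation(perfect, b$truth, ds, measurement_sd = msd)
  expect_true(all(ev_r$error_ratio < 1e-10))
})

test_that("random imputation scores near its calibration on large data", {
  cfg <- synth_config(n_samples = 500, panels = c(P1 = 10L, P2 = 10L),
                      n_chips = 10L, samples_per_chip = 50L,
                      n_latent_factors = 6L,
                      n_duplicate_proteins = 0L, n_triplicate_proteins = 0L,
                      censor_fractions = 0, mar_panel = NULL, mar_chip = NULL,
                      extra_mar_rate = 0.2, seed = 32)
  b <- synth_generate(cfg)
  ev <- evaluate_imputation(impute_random(b$observed,
                                          imputer_spec("RANDOM", seed = 1)),
                            b$truth, b$observed)
  expect_lt(abs(mean(ev$pearson)), 0.06)
  expect_lt(abs(mean(ev$nrmse) - sqrt(2)), 0.1)
  expect_lt(abs(mean(ev$rel_var) - 1), 0.15)
})

test_that("panel-subset conditions never beat the all-panels condition", {
  meds <- vapply(41:46, function(s) {
    b <- synth_generate(synth_config_small(
      n_samples = 200, assays_per_panel = 6, seed = s,
      extra_mar_rate = 0, censor_fractions = 0))
    res <- panel_subset_experiment(b, "Inflammation",
                                   list(rf = fast_rf_spec(seed = s)))
    tapply(res$pearson, res$condition, median)
  }, numeric(5))
  avg <- rowMeans(meds)
  expect_true(all(avg[["all_panels"]] >=
                    avg[setdiff(names(avg), "all_panels")] - 0.02))
})

test_that("panel subsets reveal where a target assay's information lives", {
  # hand-built world: the target assay on PanA duplicates an assay on
  # PanC; all other assays are noise, so only the (PanA, PanC) pair can
  # impute it
  set.seed(34)
  n <- 250
  sig <- rnorm(n)
  v <- cbind(t1 = sig, t2 = rnorm(n),
             b1 = rnorm(n), b2 = rnorm(n),
             c1 = sig + 0.05 * rnorm(n), c2 = rnorm(n))
  rownames(v) <- paste0("s", 1:n)
  truth <- v
  m <- matrix(MASK_OBSERVED_CODE, n, 6, dimnames = dimnames(v))
  m[1:50, "t1"] <- MASK_MAR_CODE
  v[1:50, "t1"] <- NA
  ds <- npx_dataset(v, m,
                    data.frame(assay_id = colnames(v),
                               protein_id = colnames(v),
                               panel = rep(c("PanA", "PanB", "PanC"), each = 2),
                               lod = -99),
                    data.frame(sample_id = rownames(v),
                               chip_PanA = rep(1:5, each = 50),
                               chip_PanB = rep(1:5, each = 50),
                               chip_PanC = rep(1:5, each = 50)))
  bundle <- structure(list(observed = ds,
                           truth = npx_truth(truth, m == MASK_MAR_CODE),
                           factor_loadings = matrix(0, 6, 1),
                           config = NULL),
                      class = "synth_bundle")
  res <- panel_subset_experiment(bundle, "PanA",
                                 list(rf = fast_rf_spec(seed = 34)))
  t1 <- res[res$assay_id == "t1", ]
  expect_gt(t1$pearson[t1$condition == "PanC"], 0.9)
  expect_gt(t1$pearson[t1$condition == "all_panels"], 0.9)
  expect_lt(abs(t1$pearson[t1$condition == "PanB"]), 0.4)

  # identical reruns agree
  res2 <- panel_subset_experiment(bundle, "PanA",
                                  list(rf = fast_rf_spec(seed = 34)))
  expect_identical(res, res2)
})

test_that("sample-size experiment: accuracy grows, variance ordering holds", {
  outs <- lapply(35:37, function(s) {
    b <- synth_generate(synth_config_small(n_samples = 400,
                                           assays_per_panel = 6, seed = s,
                                           extra_mar_rate = 0))
    sample_size_experiment(b, chips_to_keep = c(3L, 10L),
                           specs = list(rf = fast_rf_spec(seed = s),
                                        gibbs = fast_gibbs_spec(seed = s)))
  })
  rec <- do.call(rbind, lapply(outs, `[[`, "records"))
  med <- function(k, m, col)
    median(rec[[col]][rec$n_chips == k & rec$method == m], na.rm = TRUE)
  # medians pooled over 3 replicate worlds: accuracy must not fall with
  # sample size, and the variance-preservation ordering holds throughout
  expect_gt(med(10, "rf", "pearson"), med(3, "rf", "pearson") - 0.05)
  expect_gt(med(10, "gibbs", "pearson"), med(3, "gibbs", "pearson") - 0.05)
  for (k in c(3, 10))
    expect_gt(med(k, "gibbs", "rel_var"), med(k, "rf", "rel_var"))
  comp <- outs[[1]]$comparisons
  expect_s3_class(comp, "data.frame")
  expect_true(all(comp$p_pearson >= 0 & comp$p_pearson <= 1))
  b <- synth_generate(synth_config_small(n_samples = 400,
                                         assays_per_panel = 6, seed = 35,
                                         extra_mar_rate = 0))

  # keeping every chip reproduces the plain benchmark bit-identically
  sub_all <- peabench:::restrict_bundle(b, keep_chips = 1:10,
                                        chip_panel = "Inflammation")
  i_full <- impute_rf(b$observed, fast_rf_spec(seed = 35))
  i_sub <- impute_rf(sub_all$observed, fast_rf_spec(seed = 35))
  expect_identical(i_sub$values, i_full$values)
})
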