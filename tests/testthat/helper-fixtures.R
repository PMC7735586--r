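# Shared fixtures. Everything is built in code at test time.

# Hand-built 4-sample x 3-assay dataset on two panels, with one MAR and
# one below-LOD cell. LODs: a1 = 1, a2 = 0, a3 = 2.
tiny_dataset <- function() {
  v <- matrix(c(5.0, 3.5, 1.0, 4.0,
                2.0, 2.5, 3.0, NA,
                6.0, 7.0, 5.5, 6.5),
              nrow = 4, dimnames = list(paste0("s", 1:4), c("a1", "a2", "a3")))
  m <- matrix(MASK_OBSERVED_CODE, 4, 3, dimnames = dimnames(v))
  m[3, 1] <- MASK_BELOW_LOD_CODE  # a1 value 1.0 == LOD
  m[4, 2] <- MASK_MAR_CODE
  assays <- data.frame(assay_id = c("a1", "a2", "a3"),
                       protein_id = c("p1", "p2", "p3"),
                       panel = c("PanA", "PanA", "PanB"),
                       lod = c(1, 0, 2), stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = paste0("s", 1:4),
                        chip_PanA = c(1L, 1L, 2L, 2L),
                        chip_PanB = c(2L, 1L, 2L, 1L),
                        stringsAsFactors = FALSE)
  npx_dataset(v, m, assays, samples)
}

MASK_OBSERVED_CODE <- mask_codes()[["OBSERVED"]]
MASK_MAR_CODE <- mask_codes()[["MAR_MISSING"]]
MASK_BELOW_LOD_CODE <- mask_codes()[["BELOW_LOD"]]

# A dataset with p independent-ish columns where the first assay is an
# exact copy of the second (zero-noise duplicate) and `n_miss` of its
# cells are masked MAR.
duplicate_info_dataset <- function(n = 300, p = 6, n_miss = 50, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  v <- cbind(x, x, matrix(rnorm(n * (p - 2)), n, p - 2))
  colnames(v) <- paste0("a", seq_len(p))
  rownames(v) <- paste0("s", seq_len(n))
  m <- matrix(MASK_OBSERVED_CODE, n, p, dimnames = dimnames(v))
  hide <- seq_len(n_miss)
  truth <- v
  m[hide, 1] <- MASK_MAR_CODE
  v[hide, 1] <- NA_real_
  assays <- data.frame(assay_id = colnames(v),
                       protein_id = paste0("pr", seq_len(p)),
                       panel = rep(c("PanA", "PanB"), length.out = p),
                       lod = -99, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = rownames(v),
                        chip_PanA = rep(1:4, length.out = n),
                        chip_PanB = rep(1:4, length.out = n),
                        stringsAsFactors = FALSE)
  list(ds = npx_dataset(v, m, assays, samples),
       truth = npx_truth(truth, m == MASK_MAR_CODE))
}

# Fast imputer specs for unit tests (acceptance uses the defaults).
fast_rf_spec <- function(seed = 1, ...)
  imputer_spec("RF_ITERATIVE", seed = seed,
               rf = utils::modifyList(list(n_trees = 50L, max_iter = 5L), list(...)))

fast_gibbs_spec <- function(seed = 1, ...)
  imputer_spec("GIBBS_EN", seed = seed,
               gibbs = utils::modifyList(
                 list(outer_iters = 6L, regularization = "fixed",
                      fixed_lambda = 0.05), list(...)))

# Small synthetic world for unit tests: 200 samples, 5 panels x 8 assays.
unit_bundle <- function(seed = 1, ...) {
  synth_generate(synth_config_small(n_samples = 200L, assays_per_panel = 8L,
                                    seed = seed, ...))
}
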