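# Synthetic NPX data generator.
#
# World model: a linear Gaussian latent-factor model over proteins.
# For sample i and protein p, the true signal is
#   t_ip = sum_k lambda_pk f_ik + u_ip,  f ~ N(0,1), u ~ N(0, sd_u^2)
# with panel-structured loadings (assays on the same panel preferentially
# load on that panel's factor pool, the rest on a shared pool). Duplicate
# assays of one protein observe the identical t_ip plus independent
# measurement noise, so their expected concordance follows the
# attenuation law var(t) / (var(t) + sd_dup^2). Per-assay left-censoring
# is imposed at the configured quantile of the assay's marginal
# distribution (the LOD); whole-chip and scattered MCAR masking hides
# cells whose truth is retained for evaluation.

#' Configuration for the synthetic NPX generator
#'
#' Defaults emulate the structure of a large PEA study: 802 samples on
#' 10 chips (the masked chip holding 86 samples), five panels totaling
#' 458 assays (444 unique proteins; 12 duplicates and 1 triplicate),
#' duplicate-assay concordance near 0.88, a below-LOD census in which
#' roughly 287/458 assays have no censored values, 108/458 have under
#' 25% and the remaining 63 between 25% and 98%, and one whole
#' 86-sample x 91-assay chip masked missing-completely-at-random.
#'
#' @param n_samples Number of samples.
#' @param panels Named integer vector: assays per panel.
#' @param n_chips Number of chips per panel.
#' @param chip_capacity Maximum samples per chip (assay-plate format).
#' @param samples_per_chip Samples placed on each chip before the last;
#'   the last chip takes the remainder.
#' @param n_latent_factors Total latent factors (split between per-panel
#'   pools and a shared pool).
#' @param loading_range Interval from which non-zero loadings are drawn.
#' @param loadings_per_assay Number of factors each assay loads on.
#' @param p_shared_factor Probability that a loading goes to the shared
#'   pool rather than the assay's panel pool.
#' @param unique_noise_sd SD of the protein-level unique term (NPX units).
#' @param n_duplicate_proteins,n_triplicate_proteins Number of proteins
#'   measured on 2 resp. 3 panels.
#' @param duplicate_noise_sd Measurement-noise SD added independently to
#'   each duplicate assay; `NULL` (default) derives it per protein from
#'   the attenuation law to give expected duplicate correlation
#'   `duplicate_target_cor`.
#' @param duplicate_target_cor Target expected duplicate concordance.
#' @param censor_bin_probs Probabilities of the three censoring bins
#'   (none, under 25%, 25-98%); defaults 287:108:63 out of 458.
#' @param censor_fractions Optional explicit per-assay censoring
#'   fractions (recycled to the assay count), overriding the bin
#'   sampler; useful for controlled censoring experiments.
#' @param mar_panel,mar_chip Panel name and chip index masked wholly
#'   missing-at-random (`NULL` to disable).
#' @param extra_mar_rate Fraction of remaining cells masked MCAR.
#' @param chip_effect_sd SD of an optional additive per-chip shift
#'   (default 0: chip effects already normalized away).
#' @param seed Integer seed; the bundle is bit-identical under a fixed
#'   seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 802L,
                         panels = c(Inflammation = 91L, ImmuneResponse = 92L,
                                    CVD2 = 92L, CVD3 = 92L,
                                    Cardiometabolic = 91L),
                         n_chips = 10L,
                         chip_capacity = 88L,
                         samples_per_chip = 86L,
                         n_latent_factors = 30L,
                         loading_range = c(0.3, 0.9),
                         loadings_per_assay = 3L,
                         p_shared_factor = 0.35,
                         unique_noise_sd = 0.6,
                         n_duplicate_proteins = 12L,
                         n_triplicate_proteins = 1L,
                         duplicate_noise_sd = NULL,
                         duplicate_target_cor = 0.884,
                         censor_bin_probs = c(none = 287, low = 108, high = 63) / 458,
                         censor_fractions = NULL,
                         mar_panel = "Inflammation",
                         mar_chip = 7L,
                         extra_mar_rate = 0.003,
                         chip_effect_sd = 0,
                         seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(names(cfg$panels)) || any(names(cfg$panels) == ""))
    stop("panels must be a named vector")
  if (cfg$n_chips * cfg$chip_capacity < cfg$n_samples)
    stop("chip capacity infeasible: ", cfg$n_chips, " chips x ",
         cfg$chip_capacity, " < ", cfg$n_samples, " samples")
  if (cfg$samples_per_chip > cfg$chip_capacity)
    stop("samples_per_chip exceeds chip_capacity")
  if ((cfg$n_chips - 1L) * cfg$samples_per_chip +
      cfg$chip_capacity < cfg$n_samples)
    stop("samples do not fit on the configured chips")
  if (abs(sum(cfg$censor_bin_probs) - 1) > 1e-8)
    stop("censor_bin_probs must sum to 1")
  if (!is.null(cfg$censor_fractions) &&
      any(cfg$censor_fractions < 0 | cfg$censor_fractions > 0.98))
    stop("censoring fractions must lie in [0, 0.98]")
  n_dup_assays <- 2L * cfg$n_duplicate_proteins + 3L * cfg$n_triplicate_proteins
  if (n_dup_assays > sum(cfg$panels))
    stop("more duplicate assays than assay slots")
  if (length(cfg$panels) < 2L &&
      (cfg$n_duplicate_proteins + cfg$n_triplicate_proteins) > 0L)
    stop("duplicate proteins require at least 2 panels")
  structure(cfg, class = "synth_config")
}

#' Small-scale generator configuration for tests and benchmarks
#'
#' A scaled-down stated world preserving the full-size structure: five
#' panels of 12 assays each (60 total), 2 duplicate proteins and 1
#' triplicate, one whole masked chip, and the same censoring census.
#'
#' @param n_samples Number of samples (default 800).
#' @param assays_per_panel Assays per panel (default 12).
#' @param ... Further overrides passed to [synth_config()].
#' @return A `synth_config`.
#' @export
synth_config_small <- function(n_samples = 800L, assays_per_panel = 12L, ...) {
  args <- list(
    n_samples = n_samples,
    panels = stats::setNames(rep(as.integer(assays_per_panel), 5L),
                             c("Inflammation", "ImmuneResponse", "CVD2",
                               "CVD3", "Cardiometabolic")),
    n_chips = 10L,
    samples_per_chip = as.integer(ceiling(n_samples / 10)),
    chip_capacity = max(88L, as.integer(ceiling(n_samples / 10))),
    n_latent_factors = 12L,
    n_duplicate_proteins = 2L,
    n_triplicate_proteins = 1L
  )
  do.call(synth_config, utils::modifyList(args, list(...), keep.null = TRUE))
}

# Draw per-assay censoring fractions from the three-bin census.
draw_censor_fractions <- function(n, probs) {
  bin <- sample.int(3L, n, replace = TRUE, prob = probs)
  frac <- numeric(n)
  frac[bin == 2L] <- runif(sum(bin == 2L), 0.01, 0.25)
  frac[bin == 3L] <- runif(sum(bin == 3L), 0.25, 0.98)
  frac
}

#' Generate a synthetic NPX bundle
#'
#' Draws a complete ground-truth matrix from the latent-factor model,
#' censors each assay at its configured LOD quantile (censored cells are
#' reported at the LOD, the NPX-software convention), assigns samples to
#' chips independently per panel, and hides the configured whole chip
#' plus scattered MCAR cells. The hidden truth is retained, below-LOD
#' truth included, so censoring-related properties remain testable.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `synth_bundle` with elements `observed` (an
#'   [npx_dataset()]), `truth` (an [npx_truth()]; `eval_mask` marks the
#'   MAR-hidden cells), `factor_loadings` (assays x factors matrix) and
#'   `config`.
#' @export
synth_generate <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)

  n <- cfg$n_samples
  panels <- cfg$panels
  panel_names <- names(panels)
  p_assay <- sum(panels)
  n_factors <- cfg$n_latent_factors

  # --- assay bookkeeping: duplicates span >= 2 distinct panels ---------
  assay_panel <- rep(panel_names, times = panels)
  n_dup <- cfg$n_duplicate_proteins
  n_tri <- cfg$n_triplicate_proteins
  group_sizes <- c(rep(2L, n_dup), rep(3L, n_tri))
  slot_pool <- seq_len(p_assay)
  protein_of_assay <- integer(p_assay)
  next_protein <- 1L
  for (g in group_sizes) {
    pans <- sample(panel_names, g, replace = FALSE)
    slots <- vapply(pans, function(pn) {
      free <- slot_pool[assay_panel[slot_pool] == pn & protein_of_assay[slot_pool] == 0L]
      if (!length(free)) stop("cannot place duplicate assays; panels too small")
      free[sample.int(length(free), 1L)]
    }, integer(1))
    protein_of_assay[slots] <- next_protein
    next_protein <- next_protein + 1L
  }
  singles <- which(protein_of_assay == 0L)
  protein_of_assay[singles] <- seq(next_protein, length.out = length(singles))
  n_proteins <- max(protein_of_assay)

  # --- latent-factor loadings at the protein level ---------------------
  # Factor pools: one slice per panel plus a shared slice.
  n_shared <- max(1L, round(n_factors / (length(panels) + 1)))
  per_panel <- n_factors - n_shared
  pool_of_factor <- c(rep(panel_names, length.out = per_panel),
                      rep("shared", n_shared))
  # Home panel of a protein = panel of its first assay.
  home_panel <- assay_panel[match(seq_len(n_proteins), protein_of_assay)]
  lambda_protein <- matrix(0, n_proteins, n_factors)
  for (p in seq_len(n_proteins)) {
    k <- min(cfg$loadings_per_assay, n_factors)
    from_shared <- runif(k) < cfg$p_shared_factor
    home_pool <- which(pool_of_factor == home_panel[p])
    shared_pool <- which(pool_of_factor == "shared")
    if (!length(home_pool)) home_pool <- shared_pool
    fac <- integer(k)
    for (m in seq_len(k)) {
      pool <- if (from_shared[m]) shared_pool else home_pool
      fac[m] <- pool[sample.int(length(pool), 1L)]
    }
    fac <- unique(fac)
    lambda_protein[p, fac] <- runif(length(fac), cfg$loading_range[1],
                                    cfg$loading_range[2]) *
      sample(c(-1, 1), length(fac), replace = TRUE)
  }

  # --- truth matrix ----------------------------------------------------
  f <- matrix(rnorm(n * n_factors), n, n_factors)
  signal_protein <- f %*% t(lambda_protein) +
    matrix(rnorm(n * n_proteins, sd = cfg$unique_noise_sd), n, n_proteins)

  dup_group <- protein_of_assay %in% which(tabulate(protein_of_assay) > 1L)
  signal_var <- rowSums(lambda_protein^2) + cfg$unique_noise_sd^2
  truth <- signal_protein[, protein_of_assay, drop = FALSE]
  if (any(dup_group)) {
    if (is.null(cfg$duplicate_noise_sd)) {
      rho <- cfg$duplicate_target_cor
      sd_dup <- sqrt(signal_var[protein_of_assay] * (1 - rho) / rho)
    } else {
      sd_dup <- rep(cfg$duplicate_noise_sd, p_assay)
    }
    jdx <- which(dup_group)
    truth[, jdx] <- truth[, jdx] +
      matrix(rnorm(n * length(jdx)), n, length(jdx)) *
      rep(sd_dup[jdx], each = n)
  }

  assay_id <- sprintf("A%03d_%s", seq_len(p_assay), assay_panel)
  protein_id <- sprintf("P%03d", protein_of_assay)
  dimnames(truth) <- list(sprintf("S%04d", seq_len(n)), assay_id)

  # --- chips: randomized independently per panel -----------------------
  sizes <- rep(cfg$samples_per_chip, cfg$n_chips - 1L)
  sizes <- c(sizes, n - sum(sizes))
  if (sizes[cfg$n_chips] < 0) stop("infeasible chip sizes")
  chip_labels <- rep(seq_len(cfg$n_chips), times = sizes)
  samples <- data.frame(sample_id = rownames(truth),
                        stringsAsFactors = FALSE)
  for (pn in panel_names)
    samples[[paste0("chip_", pn)]] <- sample(chip_labels)

  # --- optional chip effects (exercises interplate_normalize) ----------
  values <- truth
  if (cfg$chip_effect_sd > 0) {
    for (pn in panel_names) {
      jj <- which(assay_panel == pn)
      eff <- rnorm(cfg$n_chips, sd = cfg$chip_effect_sd)
      values[, jj] <- values[, jj] + eff[samples[[paste0("chip_", pn)]]]
    }
  }

  # --- left-censoring at the per-assay LOD quantile --------------------
  cens_frac <- if (!is.null(cfg$censor_fractions))
    rep_len(cfg$censor_fractions, p_assay) else
    draw_censor_fractions(p_assay, cfg$censor_bin_probs)
  lod <- vapply(seq_len(p_assay), function(j) {
    if (cens_frac[j] <= 0) return(min(values[, j]) - 1)  # below all values
    as.numeric(quantile(values[, j], cens_frac[j], type = 7))
  }, numeric(1))
  mask <- matrix(MASK_OBSERVED, n, p_assay, dimnames = dimnames(truth))
  for (j in seq_len(p_assay)) {
    if (cens_frac[j] <= 0) next
    cens <- values[, j] <= lod[j]
    mask[cens, j] <- MASK_BELOW_LOD
    values[cens, j] <- lod[j]  # NPX convention: censored cells report the LOD
  }

  # --- MCAR masking ----------------------------------------------------
  if (!is.null(cfg$mar_panel) && !is.null(cfg$mar_chip)) {
    if (!cfg$mar_panel %in% panel_names) stop("unknown mar_panel")
    jj <- which(assay_panel == cfg$mar_panel)
    ii <- samples[[paste0("chip_", cfg$mar_panel)]] == cfg$mar_chip
    mask[ii, jj] <- MASK_MAR
  }
  if (cfg$extra_mar_rate > 0) {
    candidates <- which(mask != MASK_MAR)
    k <- round(cfg$extra_mar_rate * length(mask))
    if (k > 0)
      mask[candidates[sample.int(length(candidates), min(k, length(candidates)))]] <- MASK_MAR
  }
  values[mask == MASK_MAR] <- NA_real_

  assays <- data.frame(assay_id = assay_id, protein_id = protein_id,
                       panel = assay_panel, lod = lod,
                       stringsAsFactors = FALSE)
  observed <- npx_dataset(values, mask, assays, samples)
  eval_mask <- mask == MASK_MAR
  lambda_assay <- lambda_protein[protein_of_assay, , drop = FALSE]
  rownames(lambda_assay) <- assay_id

  structure(list(observed = observed,
                 truth = npx_truth(truth, eval_mask),
                 factor_loadings = lambda_assay,
                 config = cfg),
            class = "synth_bundle")
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat("synth_bundle\n")
  print(x$observed)
  cat(sprintf("  hidden truth cells: %d\n", sum(x$truth$eval_mask)))
  invisible(x)
}

#' Per-assay below-LOD fraction
#'
#' For each assay, the fraction of its non-MAR cells that are below the
#' limit of detection. Fully observed assays return 0.
#'
#' @param ds An [npx_dataset()].
#' @return Named numeric vector in `[0, 1]`, one entry per assay.
#' @export
census_below_lod <- function(ds) {
  validate_npx(ds)
  non_mar <- colSums(ds$mask != MASK_MAR)
  if (any(non_mar == 0L))
    stop("assay with zero non-MAR cells: ",
         ds$assays$assay_id[which(non_mar == 0L)[1]])
  stats::setNames(colSums(ds$mask == MASK_BELOW_LOD) / non_mar,
                  ds$assays$assay_id)
}

#' Factor communality of each assay
#'
#' Sum of squared factor loadings per assay under the generator's model;
#' the share of an assay's variance explained by latent factors shared
#' with other assays, i.e. the information available for imputation.
#'
#' @param bundle A `synth_bundle`.
#' @return Named numeric vector, one entry per assay.
#' @export
communality <- function(bundle) {
  stopifnot(inherits(bundle, "synth_bundle"))
  rowSums(bundle$factor_loadings^2)
}
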