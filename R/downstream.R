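# Simulation of imputation effects on univariate regression:
# power, bias, and average absolute coefficient difference for the
# complete, complete-case, and imputed versions of each protein.
#
# Outcome model per replicate: Y = beta * x_C + eps, eps ~ N(0, sigma^2),
# simulated from the complete data. The protein enters the regression
# either as independent variable (Y ~ x) or as dependent variable
# (x ~ Y); the same simulated Y is shared by all four datasets of a
# replicate, so per-replicate estimate differences isolate the effect of
# missingness handling.

#' Configuration for the downstream regression simulation
#'
#' @param beta True regression coefficient (default 0.01, the full-size
#'   scenario; 0.02 suits a two-chip scenario).
#' @param noise_sd SD of the outcome noise. The statistical power
#'   depends entirely on `noise_sd` relative to the protein variance;
#'   `NULL` (default) calibrates it per protein so that complete-data
#'   power lands near `target_power`, the maximally discriminative
#'   regime for comparing datasets.
#' @param target_power Complete-data power aimed for when `noise_sd`
#'   is `NULL` (default 0.5).
#' @param n_reps Simulation replicates (default 1000).
#' @param alpha Significance cutoff (default 0.05).
#' @param scenario `"PROTEIN_INDEPENDENT"` (regress `Y ~ x`) or
#'   `"PROTEIN_DEPENDENT"` (regress `x ~ Y`).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(beta = 0.01, noise_sd = NULL, target_power = 0.5,
                       n_reps = 1000L, alpha = 0.05,
                       scenario = c("PROTEIN_INDEPENDENT", "PROTEIN_DEPENDENT"),
                       seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(alpha > 0, alpha < 1, n_reps >= 1)
  structure(list(beta = beta, noise_sd = noise_sd,
                 target_power = target_power, n_reps = as.integer(n_reps),
                 alpha = alpha, scenario = scenario, seed = as.integer(seed)),
            class = "sim_config")
}

# sigma such that a two-sided slope test on (x, Y = beta x + eps) has
# approximately `power` at level alpha: solve the normal approximation
# beta * sd(x) * sqrt(n) / sigma = z_{1-alpha/2} + z_{power}.
calibrate_noise_sd <- function(x, beta, alpha, power) {
  if (beta == 0) return(1)  # null model: any positive sigma works
  z <- qnorm(1 - alpha / 2) + qnorm(power)
  abs(beta) * sd(x) * sqrt(length(x)) / z
}

#' Simulate outcomes from complete protein data
#'
#' `Y = beta * x + eps`, `eps ~ N(0, sigma^2)` i.i.d., one column per
#' replicate.
#'
#' @param x_complete Finite numeric vector of protein values.
#' @param cfg A [sim_config()]; a `NULL` `noise_sd` is calibrated from
#'   `x_complete` (see [sim_config()]).
#' @return Matrix `length(x) x n_reps` of simulated outcomes.
#' @export
simulate_outcome <- function(x_complete, cfg) {
  stopifnot(inherits(cfg, "sim_config"), all(is.finite(x_complete)))
  sigma <- cfg$noise_sd
  if (is.null(sigma))
    sigma <- calibrate_noise_sd(x_complete, cfg$beta, cfg$alpha,
                                cfg$target_power)
  set.seed(cfg$seed)
  n <- length(x_complete)
  cfg$beta * x_complete +
    matrix(rnorm(n * cfg$n_reps, sd = sigma), n, cfg$n_reps)
}

#' Univariate ordinary least squares with missing-data row dropping
#'
#' Fits the slope of `Y ~ x` (`PROTEIN_INDEPENDENT`) or `x ~ Y`
#' (`PROTEIN_DEPENDENT`) by OLS, silently dropping rows where `x` is
#' missing — this row dropping is what complete-case analysis means
#' here. Returns the slope estimate, the two-sided t-test p-value of
#' the slope, and the number of rows used.
#'
#' @param x Numeric vector, possibly with `NA` entries.
#' @param y Numeric vector of the same length (no missing values).
#' @param scenario `"PROTEIN_INDEPENDENT"` or `"PROTEIN_DEPENDENT"`.
#' @return List with `estimate`, `p_value`, `n_used`.
#' @export
fit_univariate <- function(x, y,
                           scenario = c("PROTEIN_INDEPENDENT",
                                        "PROTEIN_DEPENDENT")) {
  scenario <- match.arg(scenario)
  ok <- !is.na(x)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 jointly present pairs")
  if (scenario == "PROTEIN_DEPENDENT") { tmp <- x; x <- y; y <- tmp }
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate regressor")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  resid <- y - mean(y) - slope * (x - mean(x))
  se <- sqrt(sum(resid^2) / (n - 2L) / sxx)
  tval <- slope / se
  list(estimate = slope, p_value = 2 * pt(-abs(tval), df = n - 2L),
       n_used = n)
}

# Vectorized slope + p-value of y ~ x for a fixed regressor x and many
# outcome columns Y (n x reps). Returns reps-length estimate and p.
ols_many_y <- function(x, Y) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  Yc <- sweep(Y, 2L, colMeans(Y))
  slope <- as.numeric(crossprod(xc, Yc)) / sxx
  rss <- colSums(Yc^2) - slope^2 * sxx
  se <- sqrt(pmax(rss, 0) / (n - 2L) / sxx)
  tval <- slope / se
  list(estimate = slope, p_value = 2 * pt(-abs(tval), df = n - 2L))
}

# Vectorized slope + p-value of x ~ y where the regressor is each column
# of Y and the response is the fixed x.
ols_many_x <- function(x, Y) {
  n <- length(x)
  xc <- x - mean(x)
  Yc <- sweep(Y, 2L, colMeans(Y))
  syy <- colSums(Yc^2)
  sxy <- as.numeric(crossprod(xc, Yc))
  slope <- sxy / syy
  rss <- sum(xc^2) - slope^2 * syy
  se <- sqrt(pmax(rss, 0) / (n - 2L) / syy)
  tval <- slope / se
  list(estimate = slope, p_value = 2 * pt(-abs(tval), df = n - 2L))
}

fit_many <- function(x, Y, scenario) {
  ok <- !is.na(x)
  if (sum(ok) < 3L) stop("need at least 3 jointly present pairs")
  x <- x[ok]
  Y <- Y[ok, , drop = FALSE]
  if (scenario == "PROTEIN_DEPENDENT") ols_many_x(x, Y) else ols_many_y(x, Y)
}

#' Downstream regression simulation for one protein
#'
#' Per replicate, one outcome vector is simulated from the complete
#' data and the regression is fitted with each of the four versions of
#' the protein: complete, complete-case (missing cells kept missing,
#' rows dropped), and the two imputations. Power is the fraction of
#' replicates with `p < alpha`; bias and average absolute difference
#' compare each dataset's estimate with the complete-data estimate of
#' the same replicate.
#'
#' @param x_complete Complete protein vector.
#' @param x_masked Same vector with the originally-masked cells `NA`.
#' @param x_rf,x_gibbs Imputed versions (same length, differing from
#'   `x_complete` only at originally-masked positions).
#' @param cfg A [sim_config()].
#' @return Data frame, one row per dataset in `COMPLETE`,
#'   `COMPLETE_CASE`, `RF`, `GIBBS`: `power`, `bias`, `avg_abs_diff`,
#'   `est_variance`, `mean_estimate`, `n_used`.
#' @export
run_simulation <- function(x_complete, x_masked, x_rf, x_gibbs, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- length(x_complete)
  vecs <- list(COMPLETE = x_complete, COMPLETE_CASE = x_masked,
               RF = x_rf, GIBBS = x_gibbs)
  if (any(vapply(vecs, length, 1L) != n))
    stop("all four protein vectors must share length")
  masked_pos <- is.na(x_masked)
  for (nm in c("RF", "GIBBS"))
    if (any(vecs[[nm]][!masked_pos] != x_complete[!masked_pos]))
      stop(nm, " imputation differs from the complete data at ",
           "non-masked positions")

  Y <- simulate_outcome(x_complete, cfg)
  fits <- lapply(vecs, fit_many, Y = Y, scenario = cfg$scenario)
  est_c <- fits$COMPLETE$estimate
  rows <- lapply(names(vecs), function(nm) {
    f <- fits[[nm]]
    data.frame(dataset = nm,
               power = mean(f$p_value < cfg$alpha),
               bias = mean(f$estimate - est_c),
               avg_abs_diff = mean(abs(f$estimate - est_c)),
               est_variance = var(f$estimate),
               mean_estimate = mean(f$estimate),
               n_used = sum(!is.na(vecs[[nm]])),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Downstream simulation across all evaluated assays
#'
#' Runs [run_simulation()] for every assay with masked cells, taking
#' the complete vector from the ground truth and the imputed vectors
#' from two imputations of the masked dataset.
#'
#' @param bundle A `synth_bundle`.
#' @param imp_rf,imp_gibbs `npx_imputed` objects for the bundle's
#'   masked dataset.
#' @param cfg A [sim_config()]; each assay derives its replicate seed
#'   from `cfg$seed` so assays are independent but reproducible.
#' @param min_cells Minimum masked cells for an assay to enter.
#' @return Data frame of [run_simulation()] rows with `assay_id`
#'   prepended.
#' @export
run_simulation_all <- function(bundle, imp_rf, imp_gibbs, cfg,
                               min_cells = 3L) {
  ds <- bundle$observed
  cols <- which(colSums(bundle$truth$eval_mask) >= min_cells)
  out <- list()
  for (j in cols) {
    cfg_j <- cfg
    cfg_j$seed <- cfg$seed + j
    x_complete <- bundle$truth$values[, j]
    x_masked <- x_complete
    x_masked[ds$mask[, j] == MASK_MAR] <- NA_real_
    x_rf <- x_complete; x_gibbs <- x_complete
    sel <- ds$mask[, j] == MASK_MAR
    x_rf[sel] <- imp_rf$values[sel, j]
    x_gibbs[sel] <- imp_gibbs$values[sel, j]
    r <- run_simulation(x_complete, x_masked, x_rf, x_gibbs, cfg_j)
    r <- cbind(assay_id = ds$assays$assay_id[j], r,
               stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- r
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Trend of downstream metrics against imputation accuracy
#'
#' Least-squares line of each metric (power, bias, average absolute
#' difference) versus per-assay imputation accuracy (Pearson), per
#' dataset, fitted over assays with below-LOD fraction under 0.25.
#' For the imputed datasets, the accuracy at which their power (and
#' average-absolute-difference) line crosses the complete-case line is
#' reported when it falls inside `[0, 1]` — the empirical accuracy
#' threshold above which imputing beats dropping rows.
#'
#' @param results Output of [run_simulation_all()].
#' @param accuracies Named per-assay Pearson accuracy (typically from
#'   [evaluate_imputation()] of the better imputation).
#' @param frac_below_lod Named per-assay below-LOD fraction.
#' @param lod_cutoff Exclusion threshold (default 0.25).
#' @return List with `fits` (slope/intercept per metric x dataset) and
#'   `crossings` (per metric x imputed dataset, accuracy of the
#'   crossing with `COMPLETE_CASE`, `NA` when outside `[0, 1]`).
#' @export
trend_analysis <- function(results, accuracies, frac_below_lod,
                           lod_cutoff = 0.25) {
  keep_assays <- names(frac_below_lod)[frac_below_lod < lod_cutoff]
  keep_assays <- intersect(keep_assays, names(accuracies))
  res <- results[results$assay_id %in% keep_assays, , drop = FALSE]
  if (length(unique(res$assay_id)) < 5L)
    stop("need >= 5 assays below the below-LOD cutoff")
  acc <- accuracies[res$assay_id]
  if (stats::sd(acc) == 0) stop("degenerate accuracy spread")

  fits <- list()
  for (metric in c("power", "bias", "avg_abs_diff")) {
    for (dsn in unique(res$dataset)) {
      sub <- res$dataset == dsn
      fit <- stats::lm.fit(cbind(1, acc[sub]), res[[metric]][sub])
      fits[[length(fits) + 1L]] <- data.frame(
        metric = metric, dataset = dsn,
        intercept = fit$coefficients[1], slope = fit$coefficients[2],
        stringsAsFactors = FALSE)
    }
  }
  fits <- do.call(rbind, fits)
  rownames(fits) <- NULL

  crossings <- list()
  for (metric in c("power", "avg_abs_diff")) {
    cc <- fits[fits$metric == metric & fits$dataset == "COMPLETE_CASE", ]
    for (dsn in setdiff(unique(fits$dataset), c("COMPLETE", "COMPLETE_CASE"))) {
      im <- fits[fits$metric == metric & fits$dataset == dsn, ]
      dslope <- im$slope - cc$slope
      x <- if (abs(dslope) < 1e-12) NA_real_ else
        (cc$intercept - im$intercept) / dslope
      crossings[[length(crossings) + 1L]] <- data.frame(
        metric = metric, dataset = dsn,
        crossing = if (!is.na(x) && x >= 0 && x <= 1) x else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  list(fits = fits, crossings = do.call(rbind, crossings))
}
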