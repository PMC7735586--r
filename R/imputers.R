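# The four imputation algorithms.
#
# All imputers fill only MAR_MISSING cells; observed and below-LOD cells
# pass through bit-identically. Below-LOD cells (value 0 after the LOD
# transform) are treated as observed data during MCAR imputation,
# mirroring the zero-coded preprocessing convention.

#' Imputation method specification
#'
#' @param method One of `"MEAN"`, `"RANDOM"`, `"RF_ITERATIVE"`,
#'   `"GIBBS_EN"`.
#' @param seed Integer seed; `RANDOM`, `RF_ITERATIVE` and `GIBBS_EN` are
#'   deterministic under a fixed seed.
#' @param rf Random-forest options: `n_trees` (default 100), `max_iter`
#'   (default 10; iteration stops earlier when the update statistic
#'   first increases), `min_node` terminal node size, `min_obs` minimum
#'   observed rows per imputed assay, `mtry` (default
#'   `floor(sqrt(p))`, the missForest convention).
#' @param gibbs Gibbs-sampler options: `outer_iters` sweeps (default
#'   10), `draws_per_cell` truncated-normal draws per cell per sweep
#'   (their mean is the sweep's update; default 10, so the returned
#'   posterior-mean estimate carries negligible Monte-Carlo error —
#'   lower it toward 1 for maximal variance retention in the chain),
#'   `burn_in_fraction`
#'   of sweeps discarded before averaging (default 0.5), `lo`/`hi`
#'   truncation bounds (scalar or per-cell matrix; default unbounded,
#'   the missing-completely-at-random usage), `elastic_net_mixing`
#'   alpha in `[0, 1]` (default 0.5), `regularization` `"cv"`
#'   (per-assay, per-sweep cross-validated penalty) or `"fixed"`, and
#'   `fixed_lambda` for the latter.
#' @return A list of class `imputer_spec`.
#' @export
imputer_spec <- function(method = c("MEAN", "RANDOM", "RF_ITERATIVE", "GIBBS_EN"),
                         seed = 1L,
                         rf = list(),
                         gibbs = list()) {
  method <- match.arg(method)
  rf_def <- list(n_trees = 100L, max_iter = 10L, min_node = 5L,
                 min_obs = 10L, mtry = NULL)
  gb_def <- list(outer_iters = 10L, draws_per_cell = 10L,
                 burn_in_fraction = 0.5, lo = -Inf, hi = Inf,
                 elastic_net_mixing = 0.5, regularization = "cv",
                 fixed_lambda = 0.05)
  bad <- setdiff(names(rf), names(rf_def))
  if (length(bad)) stop("unknown rf option: ", bad[1])
  bad <- setdiff(names(gibbs), names(gb_def))
  if (length(bad)) stop("unknown gibbs option: ", bad[1])
  rf <- utils::modifyList(rf_def, rf)
  gibbs <- utils::modifyList(gb_def, gibbs)
  if (gibbs$burn_in_fraction < 0 || gibbs$burn_in_fraction >= 1)
    stop("burn_in_fraction must be in [0, 1)")
  if (any(gibbs$lo > gibbs$hi)) stop("gibbs bounds must satisfy lo <= hi")
  if (gibbs$elastic_net_mixing < 0 || gibbs$elastic_net_mixing > 1)
    stop("elastic_net_mixing must be in [0, 1]")
  structure(list(method = method, seed = as.integer(seed), rf = rf,
                 gibbs = gibbs),
            class = "imputer_spec")
}

new_imputed <- function(ds, values, spec, oob_nrmse = NULL, trace = NULL) {
  keep <- ds$mask != MASK_MAR
  values[keep] <- ds$values[keep]  # non-interference, enforced
  if (any(!is.finite(values)))
    stop("imputer produced non-finite values")
  structure(list(values = values, method = spec, oob_nrmse = oob_nrmse,
                 trace = trace, assays = ds$assays, samples = ds$samples),
            class = "npx_imputed")
}

#' @export
print.npx_imputed <- function(x, ...) {
  cat(sprintf("npx_imputed: %d x %d matrix, method %s\n",
              nrow(x$values), ncol(x$values), x$method$method))
  invisible(x)
}

check_imputable <- function(ds, min_obs = 1L) {
  miss <- ds$mask == MASK_MAR
  n_obs <- colSums(!miss)
  bad <- which(colSums(miss) > 0L & n_obs < min_obs)
  if (length(bad))
    stop("assay ", ds$assays$assay_id[bad[1]], " has ", n_obs[bad[1]],
         " observed values (need >= ", min_obs, ")")
  miss
}

#' Mean imputation
#'
#' Fills each missing-at-random cell with the mean of its assay's
#' non-missing values. Accurate on average but collapses the variance
#' of the filled cells to zero (relative variance 0), the textbook
#' variance-reduction extreme.
#'
#' @param ds An [npx_dataset()].
#' @param spec Optional [imputer_spec()] echo.
#' @return An `npx_imputed` object.
#' @export
impute_mean <- function(ds, spec = imputer_spec("MEAN")) {
  validate_npx(ds)
  miss <- check_imputable(ds)
  v <- ds$values
  for (j in which(colSums(miss) > 0L))
    v[miss[, j], j] <- mean(v[!miss[, j], j])
  new_imputed(ds, v, spec)
}

#' Random-draw imputation
#'
#' Fills each missing-at-random cell with a uniform draw (with
#' replacement) from its assay's non-missing values. Inaccurate (NRMSE
#' near sqrt(2)) but variance-preserving (relative variance near 1) —
#' the opposite extreme to mean imputation.
#'
#' @inheritParams impute_mean
#' @param spec An [imputer_spec()]; only its `seed` is used.
#' @return An `npx_imputed` object; deterministic under the spec's seed.
#' @export
impute_random <- function(ds, spec = imputer_spec("RANDOM")) {
  validate_npx(ds)
  miss <- check_imputable(ds)
  set.seed(spec$seed)
  v <- ds$values
  for (j in which(colSums(miss) > 0L)) {
    obs <- v[!miss[, j], j]
    v[miss[, j], j] <- obs[sample.int(length(obs), sum(miss[, j]),
                                      replace = TRUE)]
  }
  new_imputed(ds, v, spec)
}

oob_nrmse_from <- function(y, oob) {
  ok <- !is.na(oob)
  if (sum(ok) < 3L || var(y[ok]) == 0) return(NA_real_)
  sqrt(mean((y[ok] - oob[ok])^2) / var(y[ok]))
}

#' Iterative random-forest imputation
#'
#' The missForest-style algorithm: initialize missing cells with column
#' means; visiting assays in order of ascending missingness, repeatedly
#' regress each incomplete assay on all others (predictors taken from
#' the current completed matrix) with a random forest fitted on the
#' assay's non-missing rows, and replace its missing cells with the
#' forest predictions. Iteration stops when the relative update
#' statistic `sum((new - old)^2) / sum(new^2)` over imputed cells first
#' increases (the previous iteration's matrix is returned) or at
#' `max_iter` (with a warning). The final forests' out-of-bag
#' predictions yield a per-assay NRMSE estimate of imputation accuracy.
#'
#' @inheritParams impute_mean
#' @param spec An [imputer_spec()] with method `"RF_ITERATIVE"`.
#' @return An `npx_imputed` with `oob_nrmse` (named per-assay vector,
#'   `NA` for assays without missing cells) and `trace` (per-iteration
#'   update statistic).
#' @export
impute_rf <- function(ds, spec = imputer_spec("RF_ITERATIVE")) {
  validate_npx(ds)
  if (ncol(ds$values) < 2L) stop("random-forest imputation needs >= 2 assays")
  miss <- check_imputable(ds, spec$rf$min_obs)
  v <- ds$values
  cols <- which(colSums(miss) > 0L)
  if (!length(cols)) return(new_imputed(ds, v, spec))
  cols <- cols[order(colSums(miss)[cols])]  # ascending missingness
  for (j in cols) v[miss[, j], j] <- mean(v[!miss[, j], j])

  p <- ncol(v)
  mtry <- spec$rf$mtry
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p - 1L)))  # missForest default
  oob <- rep(NA_real_, p)
  names(oob) <- ds$assays$assay_id
  delta_prev <- Inf
  trace <- numeric(0)
  prev_v <- v
  prev_oob <- oob

  for (it in seq_len(spec$rf$max_iter)) {
    old_v <- v
    old_oob <- oob
    for (j in cols) {
      obs_j <- !miss[, j]
      fit <- .rf_fit_predict(v[obs_j, -j, drop = FALSE], v[obs_j, j],
                             v[miss[, j], -j, drop = FALSE],
                             spec$rf$n_trees, mtry, spec$rf$min_node,
                             seed = spec$seed + 7919L * it + j)
      v[miss[, j], j] <- fit$pred
      oob[j] <- oob_nrmse_from(v[obs_j, j], fit$oob)
    }
    delta <- sum((v[miss] - old_v[miss])^2) / sum(v[miss]^2)
    trace <- c(trace, delta)
    if (delta > delta_prev) {
      # the update degraded: return the previous iteration's state
      v <- old_v
      oob <- old_oob
      break
    }
    delta_prev <- delta
    if (it == spec$rf$max_iter && spec$rf$max_iter > 1L)
      warning("random-forest imputation stopped at max_iter without ",
              "convergence-criterion increase")
  }
  new_imputed(ds, v, spec, oob_nrmse = oob, trace = trace)
}

#' Draws from a truncated normal distribution
#'
#' Inverse-CDF sampling from `N(mu, sigma^2)` conditioned on
#' `[lo, hi]`. With `sigma = 0` the draw is `mu` clamped to the bounds.
#' All arguments recycle to the output length.
#'
#' @param n Number of draws.
#' @param mu,sigma Mean and SD of the parent normal (`sigma >= 0`).
#' @param lo,hi Truncation bounds (`lo <= hi`; infinite for one- or
#'   un-truncated draws).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` draws, each within `[lo, hi]`.
#' @export
truncnorm_draw <- function(n, mu = 0, sigma = 1, lo = -Inf, hi = Inf,
                           seed = NULL) {
  if (any(sigma < 0)) stop("sigma must be >= 0")
  if (any(lo > hi)) stop("bounds must satisfy lo <= hi")
  if (!is.null(seed)) set.seed(seed)
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  lo <- rep_len(lo, n); hi <- rep_len(hi, n)
  out <- numeric(n)
  degen <- sigma == 0
  out[degen] <- pmin(pmax(mu[degen], lo[degen]), hi[degen])
  if (any(!degen)) {
    i <- !degen
    plo <- pnorm(lo[i], mu[i], sigma[i])
    phi <- pnorm(hi[i], mu[i], sigma[i])
    u <- plo + runif(sum(i)) * (phi - plo)
    d <- qnorm(u, mu[i], sigma[i])
    out[i] <- pmin(pmax(d, lo[i]), hi[i])  # guard tail round-off
  }
  out
}

# Resolve a scalar-or-matrix bound for the MAR cells of assay j.
bound_for <- function(b, miss_j, j) {
  if (is.matrix(b)) b[miss_j, j] else b
}

#' Gibbs-sampler imputation with elastic-net conditional means
#'
#' The GSimp-style algorithm: initialize missing cells (column means
#' when unbounded; the lower bound when truncation bounds are finite),
#' then sweep: for each incomplete assay, fit an elastic net of that
#' assay on all others over its non-missing rows (predictors from the
#' current completed matrix) and redraw each missing cell from a normal
#' with mean the elastic-net prediction and SD the root-mean-square
#' deviation between the fitted and observed values of that assay,
#' truncated to `[lo, hi]` (no truncation in the
#' missing-completely-at-random usage). The returned value per cell is
#' the mean of its post-burn-in draws; the trace records the mean
#' absolute update per sweep. Drawing rather than plugging in the
#' conditional mean is what preserves the variance of the imputed
#' values.
#'
#' @inheritParams impute_mean
#' @param spec An [imputer_spec()] with method `"GIBBS_EN"`.
#' @return An `npx_imputed` with a per-sweep `trace`.
#' @export
impute_gibbs_en <- function(ds, spec = imputer_spec("GIBBS_EN")) {
  validate_npx(ds)
  if (ncol(ds$values) < 2L) stop("elastic-net imputation needs >= 2 assays")
  miss <- check_imputable(ds, spec$rf$min_obs)
  gb <- spec$gibbs
  set.seed(spec$seed)
  v <- ds$values
  cols <- which(colSums(miss) > 0L)
  if (!length(cols)) return(new_imputed(ds, v, spec))

  for (j in cols) {
    lo_j <- bound_for(gb$lo, miss[, j], j)
    init <- if (all(is.infinite(lo_j))) mean(v[!miss[, j], j]) else
      pmax(lo_j, min(v[!miss[, j], j]))
    v[miss[, j], j] <- init
  }

  n_keep <- 0L
  acc <- matrix(0, nrow(v), ncol(v))
  burn_until <- floor(gb$burn_in_fraction * gb$outer_iters)
  trace <- numeric(gb$outer_iters)

  for (sweep in seq_len(gb$outer_iters)) {
    upd <- 0; upd_n <- 0L
    for (j in cols) {
      obs_j <- !miss[, j]
      y <- v[obs_j, j]
      xo <- v[obs_j, -j, drop = FALSE]
      xm <- v[miss[, j], -j, drop = FALSE]
      mu_sd <- tryCatch({
        if (gb$regularization == "cv") {
          fit <- glmnet::cv.glmnet(xo, y, alpha = gb$elastic_net_mixing,
                                   nfolds = 5L)
          s <- "lambda.min"
        } else {
          fit <- glmnet::glmnet(xo, y, alpha = gb$elastic_net_mixing,
                                lambda = gb$fixed_lambda)
          s <- gb$fixed_lambda
        }
        fitted_obs <- as.numeric(predict(fit, xo, s = s))
        list(mu = as.numeric(predict(fit, xm, s = s)),
             sd = sqrt(mean((fitted_obs - y)^2)))
      }, error = function(e) {
        message("elastic-net fit failed for assay ", ds$assays$assay_id[j],
                " (", conditionMessage(e), "); falling back to column mean")
        list(mu = rep(mean(y), sum(miss[, j])), sd = 0)
      })
      lo_j <- bound_for(gb$lo, miss[, j], j)
      hi_j <- bound_for(gb$hi, miss[, j], j)
      k <- sum(miss[, j])
      draws <- matrix(truncnorm_draw(k * gb$draws_per_cell,
                                     mu = rep(mu_sd$mu, gb$draws_per_cell),
                                     sigma = mu_sd$sd,
                                     lo = rep_len(lo_j, k),
                                     hi = rep_len(hi_j, k)),
                      k, gb$draws_per_cell)
      new_vals <- rowMeans(draws)
      upd <- upd + sum(abs(new_vals - v[miss[, j], j]))
      upd_n <- upd_n + k
      v[miss[, j], j] <- new_vals
    }
    trace[sweep] <- upd / upd_n
    if (sweep > burn_until) {
      acc[miss] <- acc[miss] + v[miss]
      n_keep <- n_keep + 1L
    }
  }
  v[miss] <- acc[miss] / n_keep
  new_imputed(ds, v, spec, trace = trace)
}

#' Impute an NPX dataset
#'
#' Dispatches to the imputer named in the spec.
#'
#' @param ds An [npx_dataset()].
#' @param spec An [imputer_spec()].
#' @return An `npx_imputed` object.
#' @export
impute <- function(ds, spec) {
  stopifnot(inherits(spec, "imputer_spec"))
  switch(spec$method,
         MEAN = impute_mean(ds, spec),
         RANDOM = impute_random(ds, spec),
         RF_ITERATIVE = impute_rf(ds, spec),
         GIBBS_EN = impute_gibbs_en(ds, spec))
}
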