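# Causal estimators for a harmonized instrument set.
#
# All methods operate on per-SNP Wald ratios ratio_j = beta_out_j /
# beta_exp_j with first-order inverse-variance weights
# w_j = beta_exp_j^2 / se_out_j^2 (equivalently, a weighted regression of
# beta_out on beta_exp with weights 1/se_out^2).

Z95 <- stats::qnorm(0.975) # 1.959964...

new_mr_estimate <- function(method, beta, se, pval, n_snps,
                            egger_intercept = NA_real_,
                            egger_intercept_se = NA_real_,
                            egger_intercept_p = NA_real_) {
  ci_low <- beta - Z95 * se
  ci_high <- beta + Z95 * se
  structure(list(method = method, beta = beta, se = se,
                 ci_low = ci_low, ci_high = ci_high, pval = pval,
                 or_ = exp(beta), or_ci_low = exp(ci_low),
                 or_ci_high = exp(ci_high), n_snps = n_snps,
                 egger_intercept = egger_intercept,
                 egger_intercept_se = egger_intercept_se,
                 egger_intercept_p = egger_intercept_p),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "<mr_estimate> %s (k=%d): beta %.4f (se %.4f), 95%% CI [%.4f, %.4f], p %.3g\n",
    x$method, x$n_snps, x$beta, x$se, x$ci_low, x$ci_high, x$pval))
  cat(sprintf("  OR %.4f [%.4f, %.4f]\n", x$or_, x$or_ci_low, x$or_ci_high))
  if (!is.na(x$egger_intercept)) {
    cat(sprintf("  intercept %.4g (se %.4g), p %.3g\n", x$egger_intercept,
                x$egger_intercept_se, x$egger_intercept_p))
  }
  invisible(x)
}

check_set <- function(set, min_snps, method) {
  stopifnot(is.data.frame(set))
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  stopifnot(all(need %in% names(set)))
  if (nrow(set) < min_snps) {
    stop(sprintf("%s requires at least %d instruments (got %d)",
                 method, min_snps, nrow(set)))
  }
  invisible(set)
}

#' Wald ratio for a single instrument
#'
#' `beta = beta_out / beta_exp` with the first-order standard error
#' `|se_out / beta_exp|`.
#'
#' @param pair one-row data.frame (or list) with `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`.
#' @return An `mr_estimate` with `method = "wald"`.
#' @export
wald_ratio <- function(pair) {
  if (is.data.frame(pair)) pair <- as.list(pair[1L, ])
  if (pair$beta_exp == 0) stop("wald ratio undefined: beta_exp is 0")
  beta <- pair$beta_out / pair$beta_exp
  se <- abs(pair$se_out / pair$beta_exp)
  pval <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("wald", beta, se, pval, 1L)
}

#' Inverse-variance weighted estimator
#'
#' Meta-analysis of per-SNP Wald ratios with weights
#' `w_j = beta_exp_j^2 / se_out_j^2`; identical to zero-intercept weighted
#' least squares of `beta_out` on `beta_exp` with weights `1/se_out^2`.
#' The multiplicative random-effects variant inflates the fixed-effect
#' standard error by `sqrt(max(1, Q/(k-1)))` where Q is Cochran's
#' heterogeneity statistic.
#'
#' @param set an [harmonize()] instrument set (>= 2 rows).
#' @param random_effects use the multiplicative random-effects SE
#'   (default; the primary analysis convention).
#' @return An `mr_estimate` (`method` `"ivw_mre"` or `"ivw_fe"`) with the
#'   heterogeneity statistic in `attr(, "Q")`.
#' @export
mr_ivw <- function(set, random_effects = TRUE) {
  check_set(set, 2L, "IVW")
  w <- set$beta_exp^2 / set$se_out^2
  ratio <- set$beta_out / set$beta_exp
  beta <- sum(w * ratio) / sum(w)
  se_fe <- 1 / sqrt(sum(w))
  q <- sum(w * (ratio - beta)^2)
  k <- nrow(set)
  se <- if (random_effects) se_fe * sqrt(max(1, q / (k - 1))) else se_fe
  pval <- 2 * stats::pnorm(-abs(beta / se))
  est <- new_mr_estimate(if (random_effects) "ivw_mre" else "ivw_fe",
                         beta, se, pval, k)
  attr(est, "Q") <- q
  est
}

#' MR-Egger regression
#'
#' Weighted least squares of `beta_out` on `beta_exp` with an intercept
#' and weights `1/se_out^2`, after orienting every pair so that
#' `beta_exp >= 0`. The slope is the causal estimate; the intercept
#' estimates the average directional pleiotropic effect and its two-sided
#' test is the pleiotropy diagnostic. Standard errors use a
#' multiplicative dispersion floored at 1, with t-tests on k-2 degrees of
#' freedom.
#'
#' @param set an instrument set (>= 3 rows).
#' @return An `mr_estimate` with `method = "egger"` and intercept fields.
#' @export
mr_egger <- function(set) {
  check_set(set, 3L, "MR-Egger")
  flip <- sign(set$beta_exp)
  flip[flip == 0] <- 1
  bx <- set$beta_exp * flip
  by <- set$beta_out * flip
  w <- 1 / set$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  k <- nrow(set)
  # multiplicative random-effects: dispersion floored at 1
  infl <- if (sm$sigma > 0) 1 / min(sm$sigma, 1) else 1
  slope <- sm$coefficients["bx", "Estimate"]
  slope_se <- sm$coefficients["bx", "Std. Error"] * infl
  inter <- sm$coefficients["(Intercept)", "Estimate"]
  inter_se <- sm$coefficients["(Intercept)", "Std. Error"] * infl
  slope_p <- 2 * stats::pt(-abs(slope / slope_se), df = k - 2)
  inter_p <- 2 * stats::pt(-abs(inter / inter_se), df = k - 2)
  new_mr_estimate("egger", slope, slope_se, slope_p, k,
                  egger_intercept = inter, egger_intercept_se = inter_se,
                  egger_intercept_p = inter_p)
}

# weighted median of values x with weights w: smallest x whose cumulative
# normalized weight reaches 0.5; interpolate only at an exact boundary
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  cw <- cumsum(w)
  i <- which(cw >= 0.5)[1]
  if (abs(cw[i] - 0.5) < 1e-12 && i < length(x)) {
    return((x[i] + x[i + 1]) / 2)
  }
  x[i]
}

boot_se <- function(set, point_fun, n_boot, seed) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  k <- nrow(set)
  ests <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(k, set$beta_exp, set$se_exp)
    by <- stats::rnorm(k, set$beta_out, set$se_out)
    point_fun(bx, by)
  }, numeric(1))
  stats::sd(ests)
}

#' Weighted median estimator
#'
#' The weighted median of the per-SNP Wald ratios under inverse-variance
#' weights: consistent when instruments carrying at least half the total
#' weight are valid. The standard error comes from a parametric bootstrap
#' resampling `(beta_exp_j, beta_out_j)` from their normal sampling
#' distributions.
#'
#' @param set an instrument set (>= 3 rows).
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap (required, for reproducibility).
#' @return An `mr_estimate` with `method = "weighted_median"`.
#' @export
mr_weighted_median <- function(set, n_boot = 1000L, seed) {
  check_set(set, 3L, "weighted median")
  w <- set$beta_exp^2 / set$se_out^2
  beta <- weighted_median_point(set$beta_out / set$beta_exp, w)
  se <- boot_se(set, function(bx, by) {
    weighted_median_point(by / bx, bx^2 / set$se_out^2)
  }, n_boot, seed)
  pval <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("weighted_median", beta, se, pval, nrow(set))
}

# weighted normal-kernel density mode of ratios; bandwidth from a
# MAD-based scale so outliers do not widen the kernel
mode_point <- function(ratio, w, bandwidth_factor) {
  wm <- weighted_median_point(ratio, w)
  mad_w <- weighted_median_point(abs(ratio - wm), w)
  s <- 1.4826 * mad_w
  if (s <= 0) s <- stats::sd(ratio)
  if (is.na(s) || s <= 0) return(ratio[which.max(w)])
  h <- bandwidth_factor * 0.9 * s * length(ratio)^(-1 / 5)
  dens <- function(x) {
    vapply(x, function(xi) sum(w * stats::dnorm((xi - ratio) / h)), numeric(1))
  }
  # coarse grid then local refinement around the best point
  grid <- seq(min(ratio) - h, max(ratio) + h, length.out = 512L)
  best <- grid[which.max(dens(grid))]
  opt <- stats::optimize(dens, interval = c(best - 2 * h, best + 2 * h),
                         maximum = TRUE, tol = 1e-10)
  opt$maximum
}

#' Weighted mode estimator
#'
#' Returns the maximizer of a weighted normal-kernel density over the
#' per-SNP Wald ratios (bandwidth = `bandwidth_factor` times a weighted
#' MAD-based scale, with Silverman's n^(-1/5) factor): consistent when the
#' largest group of instruments sharing a causal estimate is valid.
#' Bootstrap standard error as in [mr_weighted_median()].
#'
#' @param set an instrument set (>= 3 rows).
#' @param bandwidth_factor kernel bandwidth multiplier (default 1).
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return An `mr_estimate` with `method = "weighted_mode"`.
#' @export
mr_weighted_mode <- function(set, bandwidth_factor = 1, n_boot = 1000L, seed) {
  check_set(set, 3L, "weighted mode")
  stopifnot(bandwidth_factor > 0)
  w <- set$beta_exp^2 / set$se_out^2
  ratio <- set$beta_out / set$beta_exp
  if (length(unique(ratio)) == 1L) {
    beta <- ratio[1]
  } else {
    beta <- mode_point(ratio, w, bandwidth_factor)
  }
  se <- boot_se(set, function(bx, by) {
    r <- by / bx
    if (length(unique(r)) == 1L) r[1]
    else mode_point(r, bx^2 / set$se_out^2, bandwidth_factor)
  }, n_boot, seed)
  pval <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("weighted_mode", beta, se, pval, nrow(set))
}

#' Populate the odds-ratio scale of an estimate
#'
#' For binary outcomes effects are log odds ratios; this exponentiates the
#' point estimate and its confidence limits.
#'
#' @param estimate an `mr_estimate`.
#' @return The estimate with `or_`, `or_ci_low`, `or_ci_high` populated.
#' @export
to_odds_scale <- function(estimate) {
  stopifnot(inherits(estimate, "mr_estimate"))
  estimate$or_ <- exp(estimate$beta)
  estimate$or_ci_low <- exp(estimate$ci_low)
  estimate$or_ci_high <- exp(estimate$ci_high)
  estimate
}

#' Run all four estimators on an instrument set
#'
#' @param set an instrument set.
#' @param methods which methods to run.
#' @param n_boot,seed bootstrap controls for median/mode.
#' @param bandwidth_factor weighted-mode bandwidth multiplier.
#' @return Named list of `mr_estimate` objects.
#' @export
mr_all <- function(set, methods = c("ivw_mre", "egger", "weighted_median",
                                    "weighted_mode"),
                   n_boot = 1000L, seed = 1L, bandwidth_factor = 1) {
  out <- list()
  for (mth in methods) {
    out[[mth]] <- switch(mth,
      ivw_fe = mr_ivw(set, random_effects = FALSE),
      ivw_mre = mr_ivw(set, random_effects = TRUE),
      egger = mr_egger(set),
      weighted_median = mr_weighted_median(set, n_boot, seed),
      weighted_mode = mr_weighted_mode(set, bandwidth_factor, n_boot, seed),
      stop("unknown method: ", mth))
  }
  out
}

#' Flatten estimates into a results table
#'
#' @param estimates list of `mr_estimate` objects (e.g. from [mr_all()]).
#' @param exposure_id,outcome_id identifiers for the table.
#' @return data.frame, one row per method, with beta/CI/p and OR columns
#'   plus the Egger intercept fields.
#' @export
estimates_table <- function(estimates, exposure_id = NA, outcome_id = NA) {
  rows <- lapply(estimates, function(e) {
    data.frame(exposure_id = exposure_id, outcome_id = outcome_id,
               method = e$method, n_snps = e$n_snps, beta = e$beta,
               se = e$se, ci_low = e$ci_low, ci_high = e$ci_high,
               pval = e$pval, or = e$or_, or_ci_low = e$or_ci_low,
               or_ci_high = e$or_ci_high,
               egger_intercept = e$egger_intercept,
               egger_intercept_p = e$egger_intercept_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
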