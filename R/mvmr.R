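# Multivariable MR and the two-step mediation decomposition.
#
# Mediation model: exposure X -> mediator M -> outcome Y, with a possible
# direct X -> Y path.
#   step 1: univariable MR of M on X gives beta_a;
#   step 2: multivariable MR of Y on (X, M) jointly gives the conditional
#           mediator effect beta_b;
#   step 3: mediation effect = beta_a * beta_b,
#           direct effect   = total effect - mediation effect,
#           proportion      = mediation / total * 100%.

#' Assemble a multivariable MR input
#'
#' Harmonizes mediator and outcome tables to the exposure's effect
#' alleles over a given SNP set and keeps complete rows.
#'
#' @param exposure,mediator,outcome [sumstats] tables.
#' @param snps SNP ids to use (typically the jointly clumped union of
#'   exposure and mediator instruments).
#' @return An `mvmr_input` data.frame with columns `snp`, `beta_exp`,
#'   `se_exp`, `beta_med`, `se_med`, `beta_out`, `se_out`.
#' @export
mvmr_input <- function(exposure, mediator, outcome, snps) {
  keep <- exposure$snp %in% snps
  exp_sub <- exposure[keep, , drop = FALSE]
  hm <- harmonize(exp_sub, mediator)
  ho <- harmonize(exp_sub, outcome)
  shared <- intersect(hm$snp, ho$snp)
  im <- match(shared, hm$snp)
  io <- match(shared, ho$snp)
  out <- data.frame(snp = shared,
                    beta_exp = hm$beta_exp[im], se_exp = hm$se_exp[im],
                    beta_med = hm$beta_out[im], se_med = hm$se_out[im],
                    beta_out = ho$beta_out[io], se_out = ho$se_out[io],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("mvmr_input", "data.frame")
  out
}

#' Multivariable IVW regression
#'
#' Zero-intercept weighted least squares of `beta_out` on `beta_exp` and
#' `beta_med` jointly, weights `1/se_out^2`. The mediator coefficient is
#' the conditional (direct-of-mediator) effect beta_b; the exposure
#' coefficient is its direct effect given the mediator. Standard errors
#' use a multiplicative random-effects inflation `sqrt(max(1, Q/(k-2)))`.
#'
#' @param input an [mvmr_input()] data.frame (>= 3 complete rows).
#' @return list with `beta_exposure`, `se_exposure`, `pval_exposure`,
#'   `beta_mediator`, `se_mediator`, `pval_mediator`, `q`, `n_snps`.
#' @export
mvmr_ivw <- function(input) {
  stopifnot(is.data.frame(input),
            all(c("beta_exp", "beta_med", "beta_out", "se_out") %in%
                  names(input)))
  input <- input[stats::complete.cases(
    input[, c("beta_exp", "beta_med", "beta_out", "se_out")]), ,
    drop = FALSE]
  k <- nrow(input)
  if (k < 3L) stop("multivariable IVW requires at least 3 complete rows")
  if (all(input$beta_med == 0)) {
    # degenerate second column: reduces to univariable IVW of the exposure
    uni <- mr_ivw(data.frame(beta_exp = input$beta_exp, se_exp = NA,
                             beta_out = input$beta_out,
                             se_out = input$se_out))
    return(list(beta_exposure = uni$beta, se_exposure = uni$se,
                pval_exposure = uni$pval,
                beta_mediator = NA_real_, se_mediator = NA_real_,
                pval_mediator = NA_real_,
                q = attr(uni, "Q"), n_snps = k))
  }
  X <- cbind(exposure = input$beta_exp, mediator = input$beta_med)
  if (qr(X)$rank < 2L) {
    stop("rank-deficient design: exposure and mediator instrument effects ",
         "are collinear")
  }
  w <- 1 / input$se_out^2
  fit <- stats::lm(input$beta_out ~ 0 + X, weights = w)
  sm <- summary(fit)
  q <- sum(w * stats::residuals(fit)^2)
  infl <- sqrt(max(1, q / (k - 2)))
  co <- sm$coefficients
  b <- co[, "Estimate"]
  # unscale lm's residual sigma, then apply the floored inflation
  se <- if (sm$sigma > 0) co[, "Std. Error"] / sm$sigma * infl
        else co[, "Std. Error"]
  p <- 2 * stats::pnorm(-abs(b / se))
  list(beta_exposure = unname(b[1]), se_exposure = unname(se[1]),
       pval_exposure = unname(p[1]),
       beta_mediator = unname(b[2]), se_mediator = unname(se[2]),
       pval_mediator = unname(p[2]),
       q = q, n_snps = k)
}

#' Mediation decomposition from step estimates
#'
#' Combines the exposure-to-mediator effect (`beta_a`), the conditional
#' mediator-to-outcome effect (`beta_b`) and the total effect into the
#' product-of-coefficients decomposition:
#' mediation = `beta_a * beta_b` with the delta-method (Sobel) variance
#' `beta_a^2 var_b + beta_b^2 var_a`; direct = total - mediation (exact
#' identity); proportion = mediation/total x 100 with a delta-method CI
#' treating the mediation and total estimates as independent. Following
#' the usual reporting convention, the proportion CI is suppressed when
#' the mediation-effect CI spans zero (the proportion's sign is then
#' undetermined).
#'
#' @param beta_a,se_a exposure -> mediator estimate and SE.
#' @param beta_b,se_b conditional mediator -> outcome estimate and SE.
#' @param total,se_total total-effect estimate and SE.
#' @param ids optional named list/vector with `exposure_id`,
#'   `mediator_id`, `outcome_id`.
#' @return A `mediation_result` list: `total_effect`, `se_total`,
#'   `beta_a`, `se_a`, `beta_b`, `se_b`, `mediation_effect`,
#'   `mediation_se`, `mediation_ci_low/high`, `mediation_pval`,
#'   `direct_effect`, `proportion_mediated`,
#'   `proportion_ci_low/high` (NA when suppressed or total is 0).
#' @export
mediate <- function(beta_a, se_a, beta_b, se_b, total, se_total,
                    ids = NULL) {
  med <- beta_a * beta_b
  med_var <- beta_a^2 * se_b^2 + beta_b^2 * se_a^2
  med_se <- sqrt(med_var)
  ci_low <- med - Z95 * med_se
  ci_high <- med + Z95 * med_se
  pval <- if (med_se > 0) 2 * stats::pnorm(-abs(med / med_se)) else NA_real_
  direct <- total - med
  if (total != 0) {
    prop <- med / total * 100
    prop_se <- 100 * sqrt(med_var / total^2 +
                            med^2 * se_total^2 / total^4)
    spans_zero <- ci_low <= 0 && ci_high >= 0
    prop_ci_low <- if (spans_zero) NA_real_ else prop - Z95 * prop_se
    prop_ci_high <- if (spans_zero) NA_real_ else prop + Z95 * prop_se
  } else {
    prop <- NA_real_
    prop_se <- NA_real_
    prop_ci_low <- NA_real_
    prop_ci_high <- NA_real_
  }
  structure(list(
    exposure_id = ids$exposure_id, mediator_id = ids$mediator_id,
    outcome_id = ids$outcome_id,
    total_effect = total, se_total = se_total,
    beta_a = beta_a, se_a = se_a, beta_b = beta_b, se_b = se_b,
    mediation_effect = med, mediation_se = med_se,
    mediation_ci_low = ci_low, mediation_ci_high = ci_high,
    mediation_pval = pval,
    direct_effect = direct,
    proportion_mediated = prop, proportion_se = prop_se,
    proportion_ci_low = prop_ci_low, proportion_ci_high = prop_ci_high),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> total %.4f; mediation %.4f [%.4f, %.4f] p %.3g\n",
              x$total_effect, x$mediation_effect, x$mediation_ci_low,
              x$mediation_ci_high, x$mediation_pval))
  cat(sprintf("  direct %.4f; proportion mediated %s\n", x$direct_effect,
              if (is.na(x$proportion_mediated)) "undefined"
              else sprintf("%.2f%%", x$proportion_mediated)))
  invisible(x)
}

# jointly clump the union of exposure- and mediator-significant SNPs,
# ranking by the better of the two p-values
joint_instruments <- function(exposure, mediator, outcome, r2_lookup,
                              exp_config, med_config) {
  iv_exp <- select_instruments(exposure, outcome, r2_lookup, exp_config)
  iv_med <- select_instruments(mediator, outcome, r2_lookup, med_config)
  snps <- union(iv_exp$snp, iv_med$snp)
  if (length(snps) == 0L) return(character(0))
  keep <- exposure$snp %in% snps
  joint <- exposure[keep, , drop = FALSE]
  med_p <- mediator$pval[match(joint$snp, mediator$snp)]
  joint$pval <- pmin(joint$pval, med_p, na.rm = TRUE)
  clumped <- ld_clump(joint, r2_lookup, exp_config)
  clumped$snp
}

#' Two-step MR mediation pipeline
#'
#' Runs the full decomposition of an exposure's effect on an outcome
#' through one continuous mediator:
#' step 1, univariable MR exposure -> mediator (genome-wide instrument
#' threshold) for `beta_a`; step 2, multivariable MR of the outcome on
#' exposure and mediator jointly — instruments are the jointly clumped
#' union of exposure instruments and mediator instruments (the mediator
#' selected at its relaxed threshold) — for `beta_b`; step 3, the total
#' effect from univariable exposure -> outcome IVW, combined by
#' [mediate()].
#'
#' @param exposure,mediator,outcome [sumstats] tables.
#' @param r2_lookup pairwise r-squared source.
#' @param exp_config selection config for the exposure (default
#'   `p < 5e-8`).
#' @param med_config selection config for the mediator-as-exposure
#'   (default relaxed `p < 5e-5`).
#' @return A `mediation_result`; intermediate estimates are attached as
#'   `attr(, "steps")` (`beta_a` estimate, `mvmr` fit, `total` estimate,
#'   sensitivity reports for the univariable steps).
#' @export
run_mediation_pipeline <- function(exposure, mediator, outcome, r2_lookup,
                                   exp_config = selection_config(),
                                   med_config = selection_config(
                                     p_threshold = 5e-5)) {
  # step 1: exposure -> mediator. No outcome-association exclusion here:
  # instruments are expected to associate with the mediator through the
  # exposure, so censoring mediator-associated SNPs would remove exactly
  # the informative instruments.
  iv1 <- select_instruments(exposure, NULL, r2_lookup, exp_config)
  if (nrow(iv1) < 2L) stop("mediation step 1: no usable exposure instruments")
  set1 <- harmonize(iv1, mediator)
  if (nrow(set1) < 2L) stop("mediation step 1: no usable exposure instruments")
  est_a <- mr_ivw(set1, random_effects = TRUE)

  # step 2: MVMR outcome ~ exposure + mediator
  snps <- joint_instruments(exposure, mediator, outcome, r2_lookup,
                            exp_config, med_config)
  if (length(snps) < 3L) stop("mediation step 2: no usable joint instruments")
  mv_in <- mvmr_input(exposure, mediator, outcome, snps)
  mv <- mvmr_ivw(mv_in)

  # step 3: total effect, exposure -> outcome
  iv3 <- select_instruments(exposure, outcome, r2_lookup, exp_config)
  if (nrow(iv3) < 2L) stop("mediation step 3: no usable exposure instruments")
  set3 <- harmonize(iv3, outcome)
  if (nrow(set3) < 2L) stop("mediation step 3: no usable exposure instruments")
  est_total <- mr_ivw(set3, random_effects = TRUE)

  res <- mediate(beta_a = est_a$beta, se_a = est_a$se,
                 beta_b = mv$beta_mediator, se_b = mv$se_mediator,
                 total = est_total$beta, se_total = est_total$se,
                 ids = list(exposure_id = trait_id(exposure),
                            mediator_id = trait_id(mediator),
                            outcome_id = trait_id(outcome)))
  attr(res, "steps") <- list(
    beta_a = est_a, mvmr = mv, total = est_total,
    sensitivity_step1 = if (nrow(set1) >= 3L) sensitivity_report(set1),
    sensitivity_step3 = if (nrow(set3) >= 3L) sensitivity_report(set3))
  res
}

#' Write mediation results to TSV
#'
#' One row per decomposition, mirroring the standard reporting layout:
#' exposure, mediator, outcome, total/direct/mediation effects with the
#' mediation CI and p, and the mediation proportion with its CI.
#'
#' @param results a `mediation_result` or list of them.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_mediation_results <- function(results, path) {
  if (inherits(results, "mediation_result")) results <- list(results)
  rows <- lapply(results, function(x) {
    data.frame(exposure = x$exposure_id %||% NA,
               mediator = x$mediator_id %||% NA,
               outcome = x$outcome_id %||% NA,
               total_effect = x$total_effect,
               direct_effect = x$direct_effect,
               mediation_effect = x$mediation_effect,
               mediation_ci_low = x$mediation_ci_low,
               mediation_ci_high = x$mediation_ci_high,
               pval = x$mediation_pval,
               proportion = x$proportion_mediated,
               proportion_ci_low = x$proportion_ci_low,
               proportion_ci_high = x$proportion_ci_high,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
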