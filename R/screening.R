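# Batch MR across many exposure-outcome pairs with FDR tiering, and the
# reverse-direction orchestration.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `adj_p(i) = min over j >= i of m * p(j) / j`
#' on the sorted p-values, capped at 1 and mapped back to input order.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return vector of adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  stopifnot(all(pvals > 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Assign an evidence tier from raw and adjusted p-values
#'
#' `highly_correlative` when `adj_pval < 0.05`; `suggestive` when
#' `pval < 0.05` and `0.05 <= adj_pval < 0.2`; otherwise `null`.
#'
#' @param pval,adj_pval raw and FDR-adjusted p-values (vectorized).
#' @return character vector of tiers.
#' @export
assign_tier <- function(pval, adj_pval) {
  ifelse(adj_pval < 0.05, "highly_correlative",
         ifelse(pval < 0.05 & adj_pval < 0.2, "suggestive", "null"))
}

screen_one <- function(exposure, outcome, r2_lookup, config, methods,
                       n_boot, seed, with_sensitivity) {
  iv <- select_instruments(exposure, outcome, r2_lookup, config)
  base <- data.frame(exposure_id = trait_id(exposure),
                     outcome_id = trait_id(outcome),
                     n_snps = nrow(iv), beta = NA_real_, se = NA_real_,
                     ci_low = NA_real_, ci_high = NA_real_,
                     pval = NA_real_, or = NA_real_,
                     or_ci_low = NA_real_, or_ci_high = NA_real_,
                     reason = NA_character_, stringsAsFactors = FALSE)
  if (nrow(iv) < 2L) {
    base$reason <- "insufficient_instruments"
    return(list(row = base, details = NULL))
  }
  set <- harmonize(iv, outcome)
  if (nrow(set) < 2L) {
    base$n_snps <- nrow(set)
    base$reason <- "insufficient_instruments_after_harmonization"
    return(list(row = base, details = NULL))
  }
  ests <- tryCatch(mr_all(set, methods = methods, n_boot = n_boot,
                          seed = seed),
                   error = function(e) NULL)
  if (is.null(ests)) {
    base$reason <- "estimation_failed"
    return(list(row = base, details = NULL))
  }
  primary <- ests[["ivw_mre"]]
  if (is.null(primary)) primary <- ests[[1]]
  base$n_snps <- primary$n_snps
  base$beta <- primary$beta; base$se <- primary$se
  base$ci_low <- primary$ci_low; base$ci_high <- primary$ci_high
  base$pval <- primary$pval
  base$or <- primary$or_; base$or_ci_low <- primary$or_ci_low
  base$or_ci_high <- primary$or_ci_high
  sens <- if (with_sensitivity && nrow(set) >= 3L) {
    tryCatch(sensitivity_report(set), error = function(e) NULL)
  }
  list(row = base, details = list(estimates = ests, sensitivity = sens,
                                  set = set))
}

#' Screen many exposures against outcomes with FDR tiering
#'
#' For every exposure-outcome pair: select instruments, harmonize,
#' estimate (random-effects IVW as the primary analysis, plus any other
#' requested methods), and run the sensitivity battery. IVW p-values are
#' then FDR-adjusted within each outcome's family of exposures (or
#' globally) and tiers assigned via [assign_tier()]. Pairs without a
#' usable instrument set are reported with tier `null` and a reason code.
#'
#' @param exposures,outcomes lists of [sumstats] tables.
#' @param r2_lookup pairwise r-squared source (see [ld_clump()]).
#' @param config a [selection_config] applied to every exposure.
#' @param methods estimator methods to run per pair (the first available
#'   IVW result feeds the FDR adjustment).
#' @param fdr_family `"per_outcome"` (adjust across exposures within each
#'   outcome) or `"global"`.
#' @param n_boot,seed bootstrap controls passed to the estimators.
#' @param with_sensitivity also compute the sensitivity battery per pair.
#' @return A `screen_result` data.frame (one row per pair) with IVW
#'   fields, `adj_pval`, `tier` and `reason`; per-pair estimator and
#'   sensitivity objects are in `attr(, "details")`.
#' @export
mr_screen <- function(exposures, outcomes, r2_lookup,
                      config = selection_config(),
                      methods = c("ivw_mre", "egger", "weighted_median",
                                  "weighted_mode"),
                      fdr_family = c("per_outcome", "global"),
                      n_boot = 1000L, seed = 1L, with_sensitivity = TRUE) {
  fdr_family <- match.arg(fdr_family)
  if (inherits(exposures, "sumstats")) exposures <- list(exposures)
  if (inherits(outcomes, "sumstats")) outcomes <- list(outcomes)
  if (length(exposures) == 0L || length(outcomes) == 0L) {
    out <- data.frame()
    class(out) <- c("screen_result", "data.frame")
    return(out)
  }
  rows <- list()
  details <- list()
  for (out_tab in outcomes) {
    for (exp_tab in exposures) {
      res <- screen_one(exp_tab, out_tab, r2_lookup, config, methods,
                        n_boot, seed, with_sensitivity)
      key <- paste(res$row$exposure_id, res$row$outcome_id, sep = "|")
      rows[[key]] <- res$row
      details[[key]] <- res$details
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$adj_pval <- NA_real_
  ok <- !is.na(tab$pval)
  if (fdr_family == "per_outcome") {
    for (oid in unique(tab$outcome_id)) {
      sel <- ok & tab$outcome_id == oid
      if (any(sel)) tab$adj_pval[sel] <- bh_fdr(tab$pval[sel])
    }
  } else if (any(ok)) {
    tab$adj_pval[ok] <- bh_fdr(tab$pval[ok])
  }
  tab$tier <- "null"
  tab$tier[ok] <- assign_tier(tab$pval[ok], tab$adj_pval[ok])
  class(tab) <- c("screen_result", "data.frame")
  attr(tab, "details") <- details
  tab
}

#' Reverse-direction screen
#'
#' Runs the identical screening machinery with exposure and outcome roles
#' swapped, typically with a relaxed instrument p-value threshold because
#' disease traits yield few genome-wide-significant instruments.
#'
#' @param outcomes_as_exposures,exposures_as_outcomes lists of [sumstats]
#'   tables in their swapped roles.
#' @param r2_lookup,config,methods,fdr_family,n_boot,seed,with_sensitivity
#'   as in [mr_screen()].
#' @return A `screen_result` data.frame.
#' @export
reverse_screen <- function(outcomes_as_exposures, exposures_as_outcomes,
                           r2_lookup,
                           config = selection_config(p_threshold = 5e-5),
                           methods = c("ivw_mre", "egger",
                                       "weighted_median", "weighted_mode"),
                           fdr_family = c("per_outcome", "global"),
                           n_boot = 1000L, seed = 1L,
                           with_sensitivity = TRUE) {
  mr_screen(outcomes_as_exposures, exposures_as_outcomes, r2_lookup,
            config = config, methods = methods, fdr_family = fdr_family,
            n_boot = n_boot, seed = seed,
            with_sensitivity = with_sensitivity)
}
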