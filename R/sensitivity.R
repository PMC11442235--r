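# Heterogeneity, pleiotropy, influence and directionality diagnostics.

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum_j w_j (ratio_j - beta_IVW_FE)^2` with first-order IVW weights;
#' p-value from a chi-square distribution on k-1 degrees of freedom.
#' `p > 0.05` is conventionally read as no heterogeneity.
#'
#' @param set an instrument set (>= 2 rows).
#' @return list with `q`, `df`, `pval`.
#' @export
cochran_q <- function(set) {
  check_set(set, 2L, "Cochran's Q")
  fe <- mr_ivw(set, random_effects = FALSE)
  q <- attr(fe, "Q")
  df <- nrow(set) - 1L
  list(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Leave-one-out analysis
#'
#' Re-estimates the causal effect with each SNP removed in turn, using the
#' random-effects IVW to match the primary analysis. A SNP is flagged as
#' influential when the full-set estimate falls outside the 95%
#' confidence interval of the estimate computed without it — i.e. the
#' remaining instruments are incompatible with the estimate that SNP
#' helped produce. (Testing the leave-one-out point estimate against the
#' full-set random-effects CI instead would almost never flag a single
#' outlier, because the outlier itself inflates that CI.)
#'
#' @param set an instrument set (>= 3 rows).
#' @return data.frame with one row per SNP: `snp`, `beta_without`,
#'   `se_without`, `pval_without`, `influential`.
#' @export
leave_one_out <- function(set) {
  check_set(set, 3L, "leave-one-out")
  full <- mr_ivw(set, random_effects = TRUE)
  rows <- lapply(seq_len(nrow(set)), function(i) {
    e <- mr_ivw(set[-i, , drop = FALSE], random_effects = TRUE)
    data.frame(snp = if ("snp" %in% names(set)) set$snp[i] else as.character(i),
               beta_without = e$beta, se_without = e$se,
               pval_without = e$pval,
               influential = full$beta < e$ci_low | full$beta > e$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# per-SNP variance explained from the Wald statistic: r2 = t^2/(t^2 + n - 2)
steiger_r2 <- function(beta, se, n) {
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure versus
#' the outcome. Per SNP, `r^2 = t^2 / (t^2 + n - 2)` from the Wald
#' statistic; summed across instruments. Direction is
#' `exposure_to_outcome` when the exposure sum is larger. The p-value is
#' the two-sided z-test comparing the Fisher-transformed multiple
#' correlations. Binary outcomes should supply the effective sample size
#' `4/(1/n_case + 1/n_control)` (taken automatically from the set when
#' case/control counts are present).
#'
#' @param set an instrument set.
#' @param n_exp,n_out sample sizes; defaults taken from the set's columns.
#' @return list with `direction`, `pval`, `r2_exp`, `r2_out`,
#'   `inconclusive` (TRUE when the sums are effectively tied).
#' @export
steiger_test <- function(set, n_exp = NULL, n_out = NULL) {
  check_set(set, 1L, "Steiger test")
  if (is.null(n_exp)) {
    if (!"n_exp" %in% names(set)) stop("exposure sample size unknown")
    n_exp <- stats::median(set$n_exp)
  }
  if (is.null(n_out)) {
    if (all(c("n_case_out", "n_control_out") %in% names(set)) &&
        !anyNA(set$n_case_out)) {
      n_out <- stats::median(effective_n(set$n_case_out, set$n_control_out))
    } else if ("n_out" %in% names(set)) {
      n_out <- stats::median(set$n_out)
    } else {
      stop("outcome sample size unknown")
    }
  }
  r2_exp <- sum(steiger_r2(set$beta_exp, set$se_exp, n_exp))
  r2_out <- sum(steiger_r2(set$beta_out, set$se_out, n_out))
  r2_exp <- min(r2_exp, 0.999)
  r2_out <- min(r2_out, 0.999)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  pval <- 2 * stats::pnorm(-abs(z))
  list(direction = if (r2_exp > r2_out) "exposure_to_outcome"
                   else "outcome_to_exposure",
       pval = pval, r2_exp = r2_exp, r2_out = r2_out,
       inconclusive = abs(r2_exp - r2_out) < 1e-12 || pval > 0.05)
}

#' Funnel-plot data
#'
#' Tidy per-SNP table of Wald ratios against their precision; asymmetry
#' around the pooled estimate suggests directional pleiotropy. No
#' inference is performed.
#'
#' @param set an instrument set (>= 1 row).
#' @return data.frame with `snp`, `ratio`, `precision` (= 1/se of the
#'   ratio).
#' @export
funnel_data <- function(set) {
  check_set(set, 1L, "funnel data")
  data.frame(snp = if ("snp" %in% names(set)) set$snp
                   else as.character(seq_len(nrow(set))),
             ratio = set$beta_out / set$beta_exp,
             precision = abs(set$beta_exp / set$se_out),
             stringsAsFactors = FALSE)
}

#' Full sensitivity battery
#'
#' Bundles Cochran's Q, the MR-Egger intercept test, leave-one-out
#' re-estimation and the Steiger directionality test for one analysis.
#'
#' @param set an instrument set (>= 3 rows).
#' @param n_exp,n_out sample sizes for the Steiger test (defaulted from
#'   the set).
#' @return A `sensitivity_report` list: `cochran_q`, `q_df`, `q_pval`,
#'   `egger_intercept`, `egger_intercept_se`, `egger_intercept_p`,
#'   `leave_one_out` (data.frame), `steiger_direction`, `steiger_pval`.
#' @export
sensitivity_report <- function(set, n_exp = NULL, n_out = NULL) {
  q <- cochran_q(set)
  eg <- mr_egger(set)
  loo <- leave_one_out(set)
  st <- steiger_test(set, n_exp, n_out)
  structure(list(cochran_q = q$q, q_df = q$df, q_pval = q$pval,
                 egger_intercept = eg$egger_intercept,
                 egger_intercept_se = eg$egger_intercept_se,
                 egger_intercept_p = eg$egger_intercept_p,
                 leave_one_out = loo,
                 steiger_direction = st$direction,
                 steiger_pval = st$pval),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> Q %.3f (df %d, p %.3g); intercept %.4g (p %.3g)\n",
              x$cochran_q, x$q_df, x$q_pval, x$egger_intercept,
              x$egger_intercept_p))
  cat(sprintf("  Steiger: %s (p %.3g); %d/%d influential SNP(s)\n",
              x$steiger_direction, x$steiger_pval,
              sum(x$leave_one_out$influential), nrow(x$leave_one_out)))
  invisible(x)
}

#' Write a sensitivity report (and its leave-one-out table) to TSV
#' @param report a `sensitivity_report`.
#' @param path main TSV path; the leave-one-out table goes to
#'   `<path base>_loo.tsv`.
#' @return `path`, invisibly.
#' @export
write_sensitivity_report <- function(report, path) {
  main <- data.frame(cochran_q = report$cochran_q, q_df = report$q_df,
                     q_pval = report$q_pval,
                     egger_intercept = report$egger_intercept,
                     egger_intercept_se = report$egger_intercept_se,
                     egger_intercept_p = report$egger_intercept_p,
                     steiger_direction = report$steiger_direction,
                     steiger_pval = report$steiger_pval)
  utils::write.table(main, path, sep = "\t", quote = FALSE, row.names = FALSE)
  loo_path <- paste0(sub("\\.tsv$", "", path), "_loo.tsv")
  utils::write.table(report$leave_one_out, loo_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
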