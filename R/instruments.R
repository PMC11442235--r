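# Instrumental-variable selection: significance filter, greedy LD
# clumping, F-statistic screen, outcome-association exclusion, and a
# user-supplied confounder exclusion list.

#' Instrument-selection configuration
#'
#' Defaults follow standard genome-wide practice: exposure association at
#' `p < 5e-8`, clumping at `r^2 < 0.001` within a 10,000 kb window,
#' instrument strength `F > 10`, and removal of SNPs associated with the
#' outcome at `p < 1e-5`. For a weakly-instrumented trait used as exposure
#' (e.g. a mediator), relax `p_threshold` to `5e-5`.
#'
#' @param p_threshold exposure-association significance cutoff.
#' @param clump_r2 LD threshold; pairs at or above it are clumped.
#' @param clump_kb clumping window in kilobases.
#' @param f_min minimum per-SNP F-statistic.
#' @param outcome_p_exclude SNPs with outcome p below this are excluded.
#' @param exclusion_list character vector of snp ids to drop (e.g. SNPs
#'   associated with known confounders).
#' @return A `selection_config` list.
#' @export
selection_config <- function(p_threshold = 5e-8, clump_r2 = 0.001,
                             clump_kb = 10000, f_min = 10,
                             outcome_p_exclude = 1e-5,
                             exclusion_list = character()) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            clump_r2 >= 0, clump_r2 <= 1, clump_kb > 0, f_min >= 0)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_kb = clump_kb, f_min = f_min,
                 outcome_p_exclude = outcome_p_exclude,
                 exclusion_list = as.character(exclusion_list)),
            class = "selection_config")
}

#' Filter records by association p-value
#'
#' @param table a [sumstats] object.
#' @param threshold records with `pval < threshold` are retained.
#' @return The filtered [sumstats], original order preserved.
#' @export
filter_by_pvalue <- function(table, threshold) {
  stopifnot(inherits(table, "sumstats"), threshold > 0, threshold <= 1)
  table[table$pval < threshold, , drop = FALSE]
}

#' Per-SNP F-statistic
#'
#' Instrument strength from summary statistics via the squared Wald
#' statistic, `F = (beta/se)^2`. `F < 10` conventionally flags a weak
#' instrument.
#'
#' @param beta effect estimate(s), or a [sumstats]/data.frame with `beta`
#'   and `se` columns.
#' @param se standard error(s); ignored when `beta` is a table.
#' @return Numeric vector of F values.
#' @export
f_statistic <- function(beta, se = NULL) {
  if (is.data.frame(beta)) {
    se <- beta$se
    beta <- beta$beta
  }
  stopifnot(all(se > 0))
  (beta / se)^2
}

# resolve pairwise r2 from either a named matrix or a long-format
# data.frame(snp_a, snp_b, r2); NA when the pair is absent
r2_of_pair <- function(r2_lookup, a, b) {
  if (is.matrix(r2_lookup)) {
    if (a %in% rownames(r2_lookup) && b %in% colnames(r2_lookup)) {
      return(r2_lookup[a, b])
    }
    return(NA_real_)
  }
  if (is.data.frame(r2_lookup)) {
    hit <- (r2_lookup[[1]] == a & r2_lookup[[2]] == b) |
      (r2_lookup[[1]] == b & r2_lookup[[2]] == a)
    if (any(hit)) return(max(r2_lookup[[3]][hit]))
    return(NA_real_)
  }
  stop("r2_lookup must be a named matrix or a 3-column data.frame")
}

#' Read a long-format LD table
#'
#' @param path TSV with columns `snp_a`, `snp_b`, `r2`.
#' @return data.frame usable as `r2_lookup` in [ld_clump()].
#' @export
read_r2_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 3)
  df
}

#' Greedy LD clumping
#'
#' Standard greedy clumping: repeatedly accept the remaining SNP with the
#' smallest p-value (ties broken by chromosome then position) and discard
#' every other SNP on the same chromosome closer than `clump_kb` kilobases
#' whose r-squared with it is at or above `clump_r2`. A missing r-squared
#' for an in-window pair is treated conservatively as 1 (removal) and
#' counted in the `n_missing_r2` attribute.
#'
#' @param table a [sumstats] object.
#' @param r2_lookup pairwise r-squared source: a matrix with SNP-id
#'   dimnames (e.g. [ld_r2_matrix()]) or a data.frame
#'   `(snp_a, snp_b, r2)`.
#' @param config a [selection_config] supplying `clump_r2` and `clump_kb`.
#' @return The clumped [sumstats], sorted by genomic coordinate, with
#'   attribute `n_missing_r2`.
#' @export
ld_clump <- function(table, r2_lookup, config = selection_config()) {
  stopifnot(inherits(table, "sumstats"))
  if (nrow(table) <= 1L) {
    attr(table, "n_missing_r2") <- 0L
    return(table)
  }
  df <- as.data.frame(table)
  chr_num <- suppressWarnings(as.numeric(df$chr))
  chr_key <- if (anyNA(chr_num)) rank(df$chr, ties.method = "min") else chr_num
  ord <- order(df$pval, chr_key, df$pos)
  alive <- rep(TRUE, nrow(df))
  keep <- logical(nrow(df))
  n_missing <- 0L
  window_bp <- config$clump_kb * 1000
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive & df$chr == df$chr[i] &
                    abs(df$pos - df$pos[i]) < window_bp)
    for (j in cand) {
      r2 <- r2_of_pair(r2_lookup, df$snp[i], df$snp[j])
      if (is.na(r2)) {
        r2 <- 1
        n_missing <- n_missing + 1L
      }
      if (r2 >= config$clump_r2) alive[j] <- FALSE
    }
  }
  out <- table[keep, , drop = FALSE]
  out <- out[order(suppressWarnings(as.numeric(out$chr)), out$chr, out$pos), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (n_missing > 0L) {
    message(sprintf("ld_clump: %d in-window pair(s) had no r2; treated as 1",
                    n_missing))
  }
  attr(out, "n_missing_r2") <- n_missing
  out
}

#' Select instruments for a two-sample MR analysis
#'
#' Applies, in order: exposure p-value filter, LD clumping, F-statistic
#' screen, removal of SNPs associated with the outcome
#' (`pval < outcome_p_exclude`), and removal of `exclusion_list` members.
#' Per-stage removal counts are attached as a stage log.
#'
#' @param exposure exposure [sumstats].
#' @param outcome outcome [sumstats] (used only for the outcome-association
#'   exclusion; pass `NULL` to skip that stage).
#' @param r2_lookup pairwise r-squared source, as in [ld_clump()].
#' @param config a [selection_config].
#' @return The selected [sumstats]; `attr(, "stage_log")` is a data.frame
#'   with columns `stage`, `removed`, `remaining`. A zero-SNP result is
#'   returned (not an error) so callers can decide how to proceed.
#' @export
select_instruments <- function(exposure, outcome = NULL, r2_lookup,
                               config = selection_config()) {
  stopifnot(inherits(exposure, "sumstats"))
  log_stage <- function(log, stage, before, after) {
    rbind(log, data.frame(stage = stage, removed = before - after,
                          remaining = after, stringsAsFactors = FALSE))
  }
  log <- data.frame(stage = character(), removed = integer(),
                    remaining = integer(), stringsAsFactors = FALSE)
  n0 <- nrow(exposure)

  cur <- filter_by_pvalue(exposure, config$p_threshold)
  log <- log_stage(log, "pvalue_filter", n0, nrow(cur))

  n1 <- nrow(cur)
  cur <- ld_clump(cur, r2_lookup, config)
  log <- log_stage(log, "ld_clump", n1, nrow(cur))

  n2 <- nrow(cur)
  cur <- cur[f_statistic(cur) >= config$f_min, , drop = FALSE]
  log <- log_stage(log, "f_statistic", n2, nrow(cur))

  n3 <- nrow(cur)
  if (!is.null(outcome)) {
    out_p <- outcome$pval[match(cur$snp, outcome$snp)]
    drop_out <- !is.na(out_p) & out_p < config$outcome_p_exclude
    cur <- cur[!drop_out, , drop = FALSE]
  }
  log <- log_stage(log, "outcome_association", n3, nrow(cur))

  n4 <- nrow(cur)
  cur <- cur[!(cur$snp %in% config$exclusion_list), , drop = FALSE]
  log <- log_stage(log, "exclusion_list", n4, nrow(cur))

  rownames(cur) <- NULL
  attr(cur, "stage_log") <- log
  cur
}

#' Write a selection stage log to TSV
#' @param table output of [select_instruments()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_stage_log <- function(table, path) {
  log <- attr(table, "stage_log", exact = TRUE)
  stopifnot(!is.null(log))
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
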