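# Effect-allele harmonization between an exposure and an outcome table.
#
# For each SNP present in both tables the outcome record is re-oriented to
# the exposure's effect allele: identical orientation is kept; swapped
# alleles flip the outcome beta's sign and complement its frequency;
# strand-complemented codings are complemented first. Palindromic (A/T,
# G/C) SNPs cannot be oriented from alleles alone and are resolved from
# allele frequencies when both are outside the ambiguity zone, else
# dropped.

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) COMPLEMENT[ea] == oa

# eaf zone within which a palindromic SNP's orientation is ambiguous
PALINDROME_EAF_ZONE <- c(0.42, 0.58)

#' Harmonize exposure and outcome effect alleles
#'
#' Aligns the two tables so `beta_exp` and `beta_out` refer to the same
#' effect allele at every shared SNP. Per-SNP actions:
#' \describe{
#'   \item{kept}{alleles already aligned (directly or after strand
#'     complement).}
#'   \item{flipped}{outcome alleles were swapped; `beta_out` negated and
#'     `eaf_out` complemented.}
#'   \item{dropped_palindromic}{A/T or G/C SNP whose orientation could not
#'     be resolved: an allele frequency missing or inside
#'     `[0.42, 0.58]`. When both frequencies are informative, the minor
#'     allele decides: frequencies on the same side of 0.5 mean the
#'     codings already agree, opposite sides mean a flip.}
#'   \item{dropped_mismatch}{allele pairs irreconcilable even after
#'     strand complement.}
#' }
#'
#' @param exposure,outcome [sumstats] tables sharing >= 0 SNP ids.
#' @return An `instrument_set`: a data.frame of kept/flipped pairs with
#'   columns `snp, chr, pos, beta_exp, se_exp, pval_exp, eaf_exp, n_exp,
#'   beta_out, se_out, pval_out, eaf_out, n_out, n_case_out,
#'   n_control_out, action`; attributes `exposure_id`, `outcome_id`, and
#'   `audit` (data.frame `snp`, `action` over the full intersection).
#' @export
harmonize <- function(exposure, outcome) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  shared <- intersect(exposure$snp, outcome$snp)
  ei <- match(shared, exposure$snp)
  oi <- match(shared, outcome$snp)

  n <- length(shared)
  action <- character(n)
  beta_out <- outcome$beta[oi]
  eaf_out <- outcome$eaf[oi]

  for (k in seq_len(n)) {
    ea1 <- exposure$ea[ei[k]]; oa1 <- exposure$oa[ei[k]]
    ea2 <- outcome$ea[oi[k]]; oa2 <- outcome$oa[oi[k]]
    if (is_palindromic(ea1, oa1)) {
      if (!setequal(c(ea2, oa2), c(ea1, oa1))) {
        action[k] <- "dropped_mismatch"
        next
      }
      fe <- exposure$eaf[ei[k]]; fo <- outcome$eaf[oi[k]]
      if (is.na(fe) || is.na(fo) ||
          (fe >= PALINDROME_EAF_ZONE[1] && fe <= PALINDROME_EAF_ZONE[2]) ||
          (fo >= PALINDROME_EAF_ZONE[1] && fo <= PALINDROME_EAF_ZONE[2])) {
        action[k] <- "dropped_palindromic"
      } else if ((fe < 0.5) == (fo < 0.5)) {
        action[k] <- "kept"
      } else {
        action[k] <- "flipped"
        beta_out[k] <- -beta_out[k]
        eaf_out[k] <- 1 - eaf_out[k]
      }
      next
    }
    # non-palindromic: try direct, swapped, then strand-complemented
    if (ea2 == ea1 && oa2 == oa1) {
      action[k] <- "kept"
    } else if (ea2 == oa1 && oa2 == ea1) {
      action[k] <- "flipped"
      beta_out[k] <- -beta_out[k]
      eaf_out[k] <- 1 - eaf_out[k]
    } else {
      cea2 <- COMPLEMENT[[ea2]]; coa2 <- COMPLEMENT[[oa2]]
      if (cea2 == ea1 && coa2 == oa1) {
        action[k] <- "kept"
      } else if (cea2 == oa1 && coa2 == ea1) {
        action[k] <- "flipped"
        beta_out[k] <- -beta_out[k]
        eaf_out[k] <- 1 - eaf_out[k]
      } else {
        action[k] <- "dropped_mismatch"
      }
    }
  }

  keep <- action %in% c("kept", "flipped")
  pairs <- data.frame(
    snp = shared[keep],
    chr = exposure$chr[ei[keep]], pos = exposure$pos[ei[keep]],
    beta_exp = exposure$beta[ei[keep]], se_exp = exposure$se[ei[keep]],
    pval_exp = exposure$pval[ei[keep]], eaf_exp = exposure$eaf[ei[keep]],
    n_exp = exposure$n[ei[keep]],
    beta_out = beta_out[keep], se_out = outcome$se[oi[keep]],
    pval_out = outcome$pval[oi[keep]], eaf_out = eaf_out[keep],
    n_out = outcome$n[oi[keep]],
    n_case_out = outcome$n_case[oi[keep]],
    n_control_out = outcome$n_control[oi[keep]],
    action = action[keep],
    stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  structure(pairs,
            class = c("instrument_set", "data.frame"),
            exposure_id = trait_id(exposure),
            outcome_id = trait_id(outcome),
            outcome_type = trait_type(outcome),
            audit = data.frame(snp = shared, action = action,
                               stringsAsFactors = FALSE))
}

#' @export
print.instrument_set <- function(x, ...) {
  aud <- attr(x, "audit", exact = TRUE)
  cat(sprintf("<instrument_set> %s -> %s: %d pairs (%d flipped; %d dropped)\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"), nrow(x),
              sum(x$action == "flipped"),
              sum(!aud$action %in% c("kept", "flipped"))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Write a harmonization audit to TSV
#' @param set an `instrument_set` from [harmonize()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_harmonization_audit <- function(set, path) {
  aud <- attr(set, "audit", exact = TRUE)
  stopifnot(!is.null(aud))
  utils::write.table(aud, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
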