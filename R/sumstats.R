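# GWAS summary-statistics tables: construction, validation, TSV read/write.
#
# A `sumstats` object is a data.frame with the canonical columns
#   snp, chr, pos, ea, oa, eaf, beta, se, pval, n, n_case, n_control
# and attributes `trait_id` and `trait_type` ("continuous" or "binary").
# Positions are 1-based; alleles are single upper-case ACGT characters;
# betas are log-odds for binary traits and SD units for continuous traits.

SUMSTATS_COLS <- c("snp", "chr", "pos", "ea", "oa", "eaf",
                   "beta", "se", "pval", "n", "n_case", "n_control")
MANDATORY_COLS <- c("snp", "chr", "pos", "ea", "oa", "beta", "se", "pval", "n")

#' Construct a summary-statistics table
#'
#' Builds a validated `sumstats` object from per-SNP association records.
#' Rows violating the record invariants (single-character ACGT alleles,
#' distinct effect/other allele, `se > 0`, `pval` in (0, 1], `pos >= 1`,
#' `n > 0`, `eaf` in (0, 1) or `NA`) are dropped with a message.
#'
#' @param df data.frame carrying at least the mandatory canonical columns
#'   `snp, chr, pos, ea, oa, beta, se, pval, n`; `eaf`, `n_case`,
#'   `n_control` are optional and filled with `NA` when absent.
#' @param trait_id character scalar identifying the trait.
#' @param trait_type `"continuous"` or `"binary"`. Binary traits must carry
#'   `n_case` and `n_control`.
#' @param quiet suppress the dropped-row message.
#' @return A `sumstats` data.frame; the number of dropped rows is stored in
#'   `attr(x, "n_dropped")`.
#' @export
sumstats <- function(df, trait_id, trait_type = c("continuous", "binary"),
                     quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(MANDATORY_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (opt in c("eaf", "n_case", "n_control")) {
    if (!opt %in% names(df)) df[[opt]] <- NA_real_
  }
  df <- df[SUMSTATS_COLS]
  df$snp <- as.character(df$snp)
  df$chr <- as.character(df$chr)
  df$ea <- toupper(as.character(df$ea))
  df$oa <- toupper(as.character(df$oa))
  for (num in c("pos", "eaf", "beta", "se", "pval", "n", "n_case", "n_control")) {
    df[[num]] <- suppressWarnings(as.numeric(df[[num]]))
  }

  ok <- !is.na(df$snp) & nzchar(df$snp) &
    df$ea %in% c("A", "C", "G", "T") &
    df$oa %in% c("A", "C", "G", "T") &
    df$ea != df$oa &
    !is.na(df$pos) & df$pos >= 1 &
    !is.na(df$beta) &
    !is.na(df$se) & df$se > 0 &
    !is.na(df$pval) & df$pval > 0 & df$pval <= 1 &
    !is.na(df$n) & df$n > 0 &
    (is.na(df$eaf) | (df$eaf > 0 & df$eaf < 1))
  n_dropped <- sum(!ok)
  if (n_dropped > 0L && !quiet) {
    message(sprintf("sumstats('%s'): dropped %d invalid record(s)",
                    trait_id, n_dropped))
  }
  df <- df[ok, , drop = FALSE]
  if (anyDuplicated(df$snp)) stop("duplicate snp ids in table: ", trait_id)
  if (trait_type == "binary" &&
      (all(is.na(df$n_case)) || all(is.na(df$n_control))) && nrow(df) > 0L) {
    stop("binary trait '", trait_id, "' requires n_case and n_control")
  }
  rownames(df) <- NULL
  structure(df,
            class = c("sumstats", "data.frame"),
            trait_id = trait_id, trait_type = trait_type,
            n_dropped = n_dropped)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait '%s' (%s), %d SNPs\n",
              trait_id(x), trait_type(x), nrow(x)))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Trait identifier / type accessors
#' @param x a `sumstats` object.
#' @return `trait_id()` the trait identifier; `trait_type()` `"continuous"`
#'   or `"binary"`.
#' @export
trait_id <- function(x) attr(x, "trait_id", exact = TRUE)

#' @rdname trait_id
#' @export
trait_type <- function(x) attr(x, "trait_type", exact = TRUE)

# keep sumstats attributes through row subsetting
#' @export
`[.sumstats` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && identical(names(out), SUMSTATS_COLS)) {
    attr(out, "trait_id") <- trait_id(x)
    attr(out, "trait_type") <- trait_type(x)
    class(out) <- c("sumstats", "data.frame")
  }
  out
}

#' Read a GWAS summary-statistics table from TSV
#'
#' Parses a tab-separated file into a [sumstats] object. Column names are
#' resolved through `dialect`, a named character vector mapping canonical
#' names to the file's column names (e.g. `c(snp = "rsid", pval = "P")`),
#' so heterogeneous source formats can be ingested without editing files.
#' Rows that fail the record invariants (including unparseable numerics)
#' are dropped and counted.
#'
#' @param path file path to a tab-separated table with one header line;
#'   missing `eaf` encoded as `"NA"`.
#' @param trait_id trait identifier; defaults to the file name sans extension.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param dialect optional named character vector, canonical -> file column.
#' @param quiet suppress the dropped-row message.
#' @return A [sumstats] object preserving file row order.
#' @export
read_sumstats <- function(path, trait_id = NULL,
                          trait_type = c("continuous", "binary"),
                          dialect = NULL, quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(trait_id)) {
    trait_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "", check.names = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      file_col <- dialect[[canon]]
      if (!file_col %in% names(df)) {
        stop("dialect maps '", canon, "' to missing column '", file_col, "'")
      }
      names(df)[names(df) == file_col] <- canon
    }
  }
  missing_cols <- setdiff(MANDATORY_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  sumstats(df, trait_id = trait_id, trait_type = trait_type, quiet = quiet)
}

#' Write a summary-statistics table to TSV
#'
#' Serializes with the fixed canonical header
#' `snp chr pos ea oa eaf beta se pval n n_case n_control` (tab-separated).
#' Floats are written with 17 significant digits so that
#' `read_sumstats(write_sumstats(x))` reproduces every field exactly.
#'
#' @param table a [sumstats] object.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "sumstats"))
  df <- as.data.frame(table)
  fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out <- data.frame(
    snp = df$snp, chr = df$chr, pos = fmt_num(df$pos),
    ea = df$ea, oa = df$oa, eaf = fmt_num(df$eaf),
    beta = fmt_num(df$beta), se = fmt_num(df$se), pval = fmt_num(df$pval),
    n = fmt_num(df$n), n_case = fmt_num(df$n_case),
    n_control = fmt_num(df$n_control),
    stringsAsFactors = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(SUMSTATS_COLS, collapse = "\t"), con)
  if (nrow(out) > 0L) {
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  }
  invisible(path)
}

# effective sample size for a binary trait on the log-odds scale
effective_n <- function(n_case, n_control) 4 / (1 / n_case + 1 / n_control)
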