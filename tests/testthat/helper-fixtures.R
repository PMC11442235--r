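# Shared fixtures: small hand-built tables and instrument sets.

# a minimal valid sumstats data.frame; override any column via ...
toy_rows <- function(n = 5, ...) {
  df <- data.frame(
    snp = sprintf("rs%d", seq_len(n)),
    chr = "1",
    pos = seq_len(n) * 1e6,
    ea = rep_len(c("A", "C", "G", "T", "A"), n),
    oa = rep_len(c("G", "T", "A", "C", "C"), n),
    eaf = rep_len(c(0.1, 0.25, 0.3, 0.35, 0.2), n),
    beta = seq_len(n) / 100,
    se = 0.01,
    pval = rep_len(c(1e-9, 1e-7, 1e-4, 0.05, 0.5), n),
    n = 10000,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

toy_sumstats <- function(n = 5, trait_id = "toy", ...) {
  sumstats(toy_rows(n, ...), trait_id = trait_id, quiet = TRUE)
}

# a bare instrument set for the estimators (no harmonization involved)
make_set <- function(beta_exp, beta_out, se_exp = 0.01, se_out = 0.01,
                     snp = NULL) {
  k <- length(beta_exp)
  data.frame(snp = snp %||% sprintf("rs%d", seq_len(k)),
             beta_exp = beta_exp, se_exp = rep_len(se_exp, k),
             beta_out = beta_out, se_out = rep_len(se_out, k),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# an independent weighted-median oracle used by mode tests: smallest value
# whose cumulative normalized weight reaches 0.5 (midpoint at an exact tie)
oracle_wmedian <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  i <- which(cw >= 0.5)[1]
  if (abs(cw[i] - 0.5) < 1e-12 && i < length(x)) (x[i] + x[i + 1]) / 2 else x[i]
}

# simulated triple + LD matrix at a fixed seed, memoised per test file
sim_fixture <- local({
  cache <- list()
  function(seed = 11, ...) {
    key <- paste(seed, deparse(list(...)), collapse = "|")
    if (is.null(cache[[key]])) {
      cfg <- sim_config(seed = seed, ...)
      sim <- simulate_triple(cfg)
      sim$r2 <- ld_r2_matrix(sim$truth)
      cache[[key]] <<- sim
    }
    cache[[key]]
  }
})
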