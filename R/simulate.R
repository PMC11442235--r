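# Summary-statistics simulator with known causal truth.
#
# Structural model (exposure X, mediator M, binary outcome Y):
#   instrument SNP j has exposure effect alpha_j ~ N(0, inst_sd^2);
#   mediator-specific SNPs carry gamma_j ~ N(0, gamma_sd^2) on M only;
#   per-SNP true effects
#     exposure:  alpha_j
#     mediator:  beta_a * alpha_j + gamma_j
#     outcome:   (delta + beta_a * beta_b) * alpha_j + beta_b * gamma_j
#                + pleiotropy_j
# so the total causal effect of X on Y is delta + beta_a*beta_b and the
# mediated part is beta_a*beta_b. Observed betas add sampling noise with
# SE = 1/sqrt(2 n maf (1-maf)) (binary traits use the effective sample
# size 4/(1/n_case + 1/n_control)); within an LD block the noise is
# equicorrelated at ld_r2. Blocks span well under the clumping window and
# are separated by more than it, so greedy clumping should keep exactly
# one SNP per block.

#' Simulation configuration
#'
#' @param n_snps total number of SNPs in each table.
#' @param n_instruments number of SNPs with a nonzero exposure effect
#'   (placed first, spread across LD blocks).
#' @param n_med_instruments number of additional SNPs with a
#'   mediator-specific effect (zero exposure effect); needed for the
#'   mediator coefficient to be identifiable in multivariable MR.
#' @param maf_range interval in (0, 0.5] from which minor-allele
#'   frequencies are drawn uniformly.
#' @param n_exp,n_med sample sizes of the exposure and mediator GWAS.
#' @param n_case,n_control outcome case/control counts (binary outcome).
#' @param beta_a true exposure -> mediator effect.
#' @param beta_b true mediator -> outcome effect (log-odds per SD).
#' @param delta true direct exposure -> outcome effect.
#' @param inst_sd SD of instrument exposure effects (default 0.05 gives
#'   F-statistics straddling the F > 10 cutoff at realistic sample sizes).
#' @param gamma_sd SD of mediator-specific effects.
#' @param pleio_mode `"none"`, `"balanced"` (zero-mean per-SNP outcome
#'   effects), or `"directional"` (mean `pleio_mean`).
#' @param pleio_sd,pleio_mean SD and mean of per-SNP pleiotropic outcome
#'   effects.
#' @param ld_block_size SNPs per LD block.
#' @param ld_r2 within-block squared correlation (pairwise r-squared).
#' @param palindromic_frac fraction of SNPs given strand-ambiguous A/T or
#'   G/C allele pairs.
#' @param flip_frac fraction of outcome records written with swapped
#'   effect/other alleles (beta negated, eaf complemented) to exercise
#'   harmonization.
#' @param seed RNG seed; all stochastic output derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps = 200L, n_instruments = 50L,
                       n_med_instruments = 0L,
                       maf_range = c(0.05, 0.5),
                       n_exp = 50000, n_med = 50000,
                       n_case = 8000, n_control = 190000,
                       beta_a = 0.3, beta_b = 0.4, delta = 0.2,
                       inst_sd = 0.05, gamma_sd = 0.05,
                       pleio_mode = c("none", "balanced", "directional"),
                       pleio_sd = 0.02, pleio_mean = 0.02,
                       ld_block_size = 1L, ld_r2 = 0.8,
                       palindromic_frac = 0, flip_frac = 0,
                       seed = 1L) {
  pleio_mode <- match.arg(pleio_mode)
  cfg <- list(n_snps = as.integer(n_snps),
              n_instruments = as.integer(n_instruments),
              n_med_instruments = as.integer(n_med_instruments),
              maf_range = as.numeric(maf_range),
              n_exp = n_exp, n_med = n_med,
              n_case = n_case, n_control = n_control,
              beta_a = beta_a, beta_b = beta_b, delta = delta,
              inst_sd = inst_sd, gamma_sd = gamma_sd,
              pleio_mode = pleio_mode, pleio_sd = pleio_sd,
              pleio_mean = if (pleio_mode == "directional") pleio_mean else 0,
              ld_block_size = as.integer(ld_block_size), ld_r2 = ld_r2,
              palindromic_frac = palindromic_frac, flip_frac = flip_frac,
              seed = as.integer(seed))
  stopifnot(cfg$n_instruments + cfg$n_med_instruments <= cfg$n_snps,
            cfg$maf_range[1] > 0, cfg$maf_range[2] <= 0.5,
            cfg$maf_range[1] <= cfg$maf_range[2],
            cfg$ld_r2 >= 0, cfg$ld_r2 <= 1,
            cfg$palindromic_frac >= 0, cfg$palindromic_frac <= 1,
            cfg$flip_frac >= 0, cfg$flip_frac <= 1,
            cfg$n_exp > 0, cfg$n_med > 0, cfg$n_case > 0, cfg$n_control > 0,
            cfg$ld_block_size >= 1)
  class(cfg) <- "sim_config"
  cfg
}

# genome layout: blocks < 10,000 kb wide, separated by > 10,000 kb
BLOCK_SPACING_BP <- 1.5e7 # 15,000 kb between block starts
WITHIN_BLOCK_BP <- 5e3    # 5 kb between SNPs inside a block
BLOCKS_PER_CHROM <- 15L

#' Simulate an exposure/mediator/outcome summary-statistics triple
#'
#' Generates three [sumstats] tables from the structural model described in
#' [sim_config], along with a `sim_truth` object recording the generating
#' parameters and per-SNP true effects for recovery tests.
#'
#' @param config a [sim_config].
#' @return A list with elements `exposure`, `mediator`, `outcome`
#'   ([sumstats] tables) and `truth` (`sim_truth`: per-SNP true effects,
#'   block assignment, `total_effect = delta + beta_a*beta_b`,
#'   `mediation_effect = beta_a*beta_b`, and the config).
#' @export
simulate_triple <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  m <- config$n_snps
  block <- ((seq_len(m) - 1L) %/% config$ld_block_size) + 1L
  n_blocks <- max(block)
  chr_of_block <- ((seq_len(n_blocks) - 1L) %/% BLOCKS_PER_CHROM) + 1L
  block_start <- (((seq_len(n_blocks) - 1L) %% BLOCKS_PER_CHROM)) *
    BLOCK_SPACING_BP + 1e6
  within_idx <- seq_len(m) - (block - 1L) * config$ld_block_size
  chr <- as.character(chr_of_block[block])
  pos <- block_start[block] + (within_idx - 1L) * WITHIN_BLOCK_BP
  snp <- sprintf("rs%07d", seq_len(m))

  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  eaf <- ifelse(stats::runif(m) < 0.5, maf, 1 - maf)

  # allele pairs; a palindromic_frac subset is strand-ambiguous
  pal <- stats::runif(m) < config$palindromic_frac
  pal_pairs <- matrix(c("A", "T", "G", "C"), ncol = 2, byrow = TRUE)
  npal_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                         "G", "A", "C", "A", "G", "T", "C", "T"),
                       ncol = 2, byrow = TRUE)
  ea <- oa <- character(m)
  pick_pal <- sample(nrow(pal_pairs), m, replace = TRUE)
  pick_npal <- sample(nrow(npal_pairs), m, replace = TRUE)
  ea[pal] <- pal_pairs[pick_pal[pal], 1]; oa[pal] <- pal_pairs[pick_pal[pal], 2]
  ea[!pal] <- npal_pairs[pick_npal[!pal], 1]
  oa[!pal] <- npal_pairs[pick_npal[!pal], 2]

  # spread exposure instruments across blocks (one per block first pass)
  inst_order <- order(within_idx, block)
  is_inst <- logical(m)
  is_inst[inst_order[seq_len(config$n_instruments)]] <- TRUE
  is_ginst <- logical(m)
  if (config$n_med_instruments > 0L) {
    free <- inst_order[!is_inst[inst_order]]
    is_ginst[free[seq_len(config$n_med_instruments)]] <- TRUE
  }
  alpha <- ifelse(is_inst, stats::rnorm(m, 0, config$inst_sd), 0)
  gamma <- ifelse(is_ginst, stats::rnorm(m, 0, config$gamma_sd), 0)
  # pleiotropy rides on the instruments, oriented to the
  # exposure-increasing allele (the convention under which a nonzero mean
  # is "directional" and detectable by the Egger intercept)
  pleio <- switch(config$pleio_mode,
    none = rep(0, m),
    balanced = stats::rnorm(m, 0, config$pleio_sd),
    directional = stats::rnorm(m, config$pleio_mean, config$pleio_sd))
  pleio <- pleio * ifelse(alpha < 0, -1, 1)
  pleio[!is_inst] <- 0

  true_exp <- alpha
  true_med <- config$beta_a * alpha + gamma
  total_effect <- config$delta + config$beta_a * config$beta_b
  true_out <- total_effect * alpha + config$beta_b * gamma + pleio

  # block-equicorrelated noise: z = sqrt(r2)*shared + sqrt(1-r2)*own
  block_noise <- function() {
    shared <- stats::rnorm(n_blocks)[block]
    own <- stats::rnorm(m)
    sqrt(config$ld_r2) * shared + sqrt(1 - config$ld_r2) * own
  }
  se_of <- function(n_eff) 1 / sqrt(2 * n_eff * maf * (1 - maf))
  observe <- function(true_beta, n_eff) {
    se <- se_of(n_eff)
    beta <- true_beta + se * block_noise()
    pval <- 2 * stats::pnorm(-abs(beta / se))
    pval[pval == 0] <- .Machine$double.xmin
    list(beta = beta, se = se, pval = pval)
  }

  n_out_eff <- effective_n(config$n_case, config$n_control)
  obs_exp <- observe(true_exp, config$n_exp)
  obs_med <- observe(true_med, config$n_med)
  obs_out <- observe(true_out, n_out_eff)

  mk <- function(obs, id, type, n, n_case = NA, n_control = NA) {
    sumstats(data.frame(snp = snp, chr = chr, pos = pos, ea = ea, oa = oa,
                        eaf = eaf, beta = obs$beta, se = obs$se,
                        pval = obs$pval, n = n,
                        n_case = n_case, n_control = n_control,
                        stringsAsFactors = FALSE),
             trait_id = id, trait_type = type, quiet = TRUE)
  }
  exposure <- mk(obs_exp, "sim_exposure", "continuous", config$n_exp)
  mediator <- mk(obs_med, "sim_mediator", "continuous", config$n_med)
  outcome <- mk(obs_out, "sim_outcome", "binary",
                config$n_case + config$n_control,
                config$n_case, config$n_control)

  # introduce allele-coding flips into the outcome table
  if (config$flip_frac > 0) {
    fl <- which(stats::runif(m) < config$flip_frac)
    tmp <- outcome$ea[fl]
    outcome$ea[fl] <- outcome$oa[fl]
    outcome$oa[fl] <- tmp
    outcome$beta[fl] <- -outcome$beta[fl]
    outcome$eaf[fl] <- 1 - outcome$eaf[fl]
  }

  truth <- structure(list(
    snp = snp, block = block, chr = chr, pos = pos, maf = maf,
    is_instrument = is_inst, is_med_instrument = is_ginst,
    true_exp = true_exp, true_med = true_med, true_out = true_out,
    pleio = pleio,
    total_effect = total_effect,
    mediation_effect = config$beta_a * config$beta_b,
    config = config), class = "sim_truth")
  list(exposure = exposure, mediator = mediator, outcome = outcome,
       truth = truth)
}

#' Pairwise LD matrix implied by a simulation
#'
#' Returns the block-diagonal matrix of pairwise r-squared values for all
#' simulated SNPs: `ld_r2` within a block, 0 between blocks, 1 on the
#' diagonal. Row/column names are SNP ids, so the matrix plugs directly
#' into [ld_clump()].
#'
#' @param truth a `sim_truth` from [simulate_triple()].
#' @return A symmetric numeric matrix with SNP-id dimnames.
#' @export
ld_r2_matrix <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  m <- length(truth$snp)
  r2 <- outer(truth$block, truth$block, "==") * truth$config$ld_r2
  diag(r2) <- 1
  dimnames(r2) <- list(truth$snp, truth$snp)
  r2
}

#' Serialize simulation truth to TSV
#'
#' Writes the per-SNP true effects alongside the generating parameters so a
#' simulated dataset can be archived next to its three sumstats files.
#'
#' @param truth a `sim_truth`.
#' @param path destination TSV path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  df <- data.frame(snp = truth$snp, chr = truth$chr, pos = truth$pos,
                   block = truth$block,
                   is_instrument = truth$is_instrument,
                   is_med_instrument = truth$is_med_instrument,
                   true_exp = truth$true_exp, true_med = truth$true_med,
                   true_out = truth$true_out, pleio = truth$pleio)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
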