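Package: mrpipe
Title: Two-Sample Mendelian Randomization Screening and Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Maternal Health", "Genetics Group", email = "mrpipe@example.org",
           role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) workflow for
    GWAS summary statistics: instrument selection (p-value filtering, greedy
    LD clumping, F-statistic screening, outcome-association and confounder
    exclusion), effect-allele harmonization with palindromic-SNP resolution,
    four causal estimators (inverse-variance weighted, MR-Egger, weighted
    median, weighted mode), a sensitivity battery (Cochran's Q, Egger
    intercept, leave-one-out, Steiger directionality, funnel data),
    FDR-tiered multi-exposure screening with reverse-MR orchestration,
    multivariable MR, and a two-step mediation decomposition of total effects
    into direct and mediated components. Includes a summary-statistics
    simulator with known causal truth (LD blocks, pleiotropy modes, allele
    coding inconsistencies) so every stage can be validated against a known
    generating model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
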