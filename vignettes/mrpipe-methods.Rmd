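---
title: "Methods: two-sample MR screening and mediation in mrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening and mediation in mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The model

Two-sample Mendelian randomization treats genetic variants as
instrumental variables for an exposure $X$ on an outcome $Y$. For SNP
$j$ with exposure association $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) and
outcome association $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$), the Wald ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the causal
effect under the three instrumental assumptions (relevance, no
confounding of the instrument, no pathway to the outcome other than
through the exposure). The package combines ratios four ways:

* **IVW** — $\hat\theta = \sum w_j \hat\theta_j / \sum w_j$ with
  first-order weights $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$;
  algebraically the zero-intercept weighted least-squares slope of
  $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ with weights $1/\sigma_{Yj}^2$.
  The fixed-effect SE is $1/\sqrt{\sum w_j}$; the multiplicative
  random-effects SE (the primary analysis here) multiplies it by
  $\sqrt{\max(1, Q/(k-1))}$, so heterogeneity can widen but never
  narrow the interval.
* **MR-Egger** — the same regression with an intercept, fitted after
  orienting every pair so $\hat\beta_{Xj} \ge 0$. The slope is the
  causal estimate under the InSIDE assumption; the intercept estimates
  the mean directional pleiotropic effect and its two-sided $t$-test
  ($k-2$ df) is the pleiotropy diagnostic. SEs carry the same
  multiplicative dispersion floored at 1.
* **Weighted median** — the weighted 50% quantile of the ratios:
  consistent while instruments carrying at least half the total weight
  are valid. We use the step-function quantile (smallest ratio whose
  cumulative normalized weight reaches 0.5, interpolating only at an
  exact boundary): unlike midpoint-interpolated variants, a single SNP
  holding a majority of the weight then returns exactly its own ratio,
  which is the behaviour the estimator's theory promises.
* **Weighted mode** — the maximizer of a weighted normal-kernel density
  over the ratios. The bandwidth is
  $1.4826\,\mathrm{wMAD} \times 0.9\,k^{-1/5}$ times a user factor
  (default 1): a MAD-based scale so that outlying ratios do not widen
  the kernel; degenerate zero-MAD sets fall back to the SD, then to the
  highest-weight ratio. Median and mode SEs come from a parametric
  bootstrap (default 1000 draws, caller-supplied seed) resampling
  $(\hat\beta_{Xj}, \hat\beta_{Yj})$ from their normal sampling
  distributions.

Binary outcomes are analyzed on the log-odds scale throughout and
reported as $\mathrm{OR} = e^{\hat\theta}$ with
$\mathrm{CI} = e^{\hat\theta \pm 1.959964\,\mathrm{SE}}$.

## Instrument selection

`select_instruments()` applies, in order: significance filter
(`p_threshold`, default $5\times10^{-8}$; a relaxed $5\times10^{-5}$ is
conventional for weakly instrumented traits used as exposures, e.g. a
protein mediator), greedy LD clumping, F-statistic screen, removal of
SNPs associated with the outcome, and a user-supplied exclusion list
standing in for confounder-database lookups. Each stage logs removals.

Clumping is the standard greedy algorithm: accept the remaining SNP with
the smallest p (ties by chromosome, then position — determinism), drop
every SNP on the same chromosome strictly closer than `clump_kb`
(default 10,000 kb) whose $r^2$ with it is at or above `clump_r2`
(default 0.001), repeat. A pair inside the window with no available
$r^2$ is treated as $r^2 = 1$ (conservative removal) and counted. The
per-SNP F-statistic is the squared Wald statistic $(\beta/\sigma)^2$,
the form computable from summary data alone; $F > 10$ is the
conventional weak-instrument floor.

One caution established while validating on simulations: the
outcome-association exclusion (`p < 1e-5`) cannot distinguish
association *through the exposure* from horizontal pleiotropy. When the
true causal effect is strong or the outcome GWAS very large, it censors
the most informative instruments and biases estimates toward zero. For
exactly this reason the mediation pipeline's first step
(exposure → mediator) does not apply the exclusion against the
mediator: valid instruments are *expected* to associate with the
mediator via the exposure.

## Harmonization

Effect alleles are aligned to the exposure's coding: identical
orientation is kept; swapped alleles negate the outcome beta and
complement its EAF; strand-complemented codings are complemented first;
anything irreconcilable is dropped as a mismatch. Palindromic (A/T,
G/C) SNPs carry no orientation information in their alleles and are
resolved from allele frequencies: if either EAF is missing or inside
[0.42, 0.58] the SNP is dropped; otherwise frequencies on the same side
of 0.5 mean the codings agree and opposite sides mean a flip. The zone
bounds follow the field's reference implementation. Harmonization is
idempotent: re-harmonizing aligned data changes nothing.

## Sensitivity battery

Cochran's $Q = \sum_j w_j(\hat\theta_j - \hat\theta_{FE})^2$ with
$\chi^2_{k-1}$ p-value (p > 0.05 read as no heterogeneity); the Egger
intercept test as above; leave-one-out re-estimation with random-effects
IVW (matching the primary analysis); and the Steiger directionality
test, with per-SNP variance explained $r^2 = t^2/(t^2+n-2)$ summed over
instruments on each side (binary traits use the effective sample size
$4/(1/n_\mathrm{case}+1/n_\mathrm{control})$) and a two-sided z-test on
the difference of Fisher-transformed correlations.

**Leave-one-out influence flag.** A SNP is flagged when the full-set
estimate lies outside the 95% CI of the estimate computed without it.
The superficially more natural rule — flag when the leave-one-out
estimate exits the full-set CI — fails in precisely the case the
diagnostic exists for: a single outlier inflates the full-set
random-effects CI so much that no removal can leave it. The adopted
rule flags a planted outlier exactly and flags nothing in homogeneous
sets.

## Screening and FDR tiers

`mr_screen()` runs selection, harmonization, estimation and sensitivity
per exposure–outcome pair, then adjusts the primary (IVW) p-values by
Benjamini–Hochberg within each outcome's family of exposures (the
family structure is exposed as `fdr_family`, per-outcome by default;
pooling across outcomes is a defensible alternative the source analyses
leave ambiguous). Tiers: `highly_correlative` iff adjusted p < 0.05;
`suggestive` iff raw p < 0.05 and 0.05 ≤ adjusted p < 0.2 (boundary
0.05 deliberately lands in `suggestive`, matching the stated strict
inequality); otherwise `null`. Pairs without a usable instrument set
are reported with a reason code rather than dropped. Reverse MR is the
same machinery with the roles swapped and, typically, the relaxed
instrument threshold; the outcome-association exclusion then works in
our favour, removing the forward-direction instruments that would
otherwise leak association back.

## Multivariable MR and mediation

With a mediator $M$ on the path $X \to M \to Y$, `mvmr_ivw()` fits the
zero-intercept WLS of $\hat\beta_{Yj}$ on
$(\hat\beta_{Xj}, \hat\beta_{Mj})$ jointly with weights
$1/\sigma_{Yj}^2$; the mediator coefficient is the conditional effect
$\beta_b$, SEs inflated by $\sqrt{\max(1, Q/(k-2))}$. An all-zero
mediator column degenerates cleanly to univariable IVW; truly collinear
designs are a named error. MVMR instruments are the jointly clumped
(by the better p-value) union of exposure instruments at $5\times10^{-8}$
and mediator instruments at $5\times10^{-5}$ — the construction is not
pinned down by the source methodology, and the union-then-clump rule is
the common practical choice.

`mediate()` combines $\beta_a$ (univariable exposure → mediator MR),
$\beta_b$, and the total effect (univariable exposure → outcome MR):
mediation $= \beta_a\beta_b$ with the delta-method (Sobel) variance
$\beta_a^2\sigma_b^2 + \beta_b^2\sigma_a^2$; direct $=$ total $-$
mediation (an exact identity, by construction); proportion $=$
mediation/total $\times 100\%$ with a delta-method CI treating the
mediation and total estimates as independent (they come from
non-overlapping estimation steps in this design; documented as an
approximation). The delta method was chosen over bootstrap because it
is deterministic and directly testable against a Monte-Carlo oracle;
when the mediation CI spans zero the proportion CI is suppressed (its
sign is then undetermined — the same convention as the source tables),
and a zero total effect leaves the proportion undefined.

## The simulator: what it emulates, and what it does not

`simulate_triple()` draws per-SNP exposure effects
$\alpha_j \sim N(0, 0.05^2)$ for the instrument SNPs — at realistic
sample sizes this puts F-statistics on both sides of the selection
cutoffs, so the filters are genuinely exercised — and, optionally,
mediator-specific effects $\gamma_j \sim N(0, 0.05^2)$ on further SNPs.
True effects follow the structural model: mediator
$\beta_a\alpha_j + \gamma_j$, outcome
$(\delta + \beta_a\beta_b)\alpha_j + \beta_b\gamma_j + p_j$, so the
total exposure effect is $\delta + \beta_a\beta_b$ and the mediated
share $\beta_a\beta_b$ exactly. Observed betas add noise with
$\mathrm{SE} = 1/\sqrt{2n\,\mathrm{maf}(1-\mathrm{maf})}$ (binary
traits on the log-odds scale with effective $n$) — the standard
summary-statistic approximation, since the source gives no SE model.
Pleiotropy $p_j$ is zero, balanced ($N(0, \sigma_p^2)$) or directional
($N(\mu_p, \sigma_p^2)$), and is planted **on the exposure-increasing
allele**: the Egger intercept is defined under that orientation, and a
sign-symmetric plant would cancel to zero mean and be undetectable by
construction. LD blocks are equicorrelated noise blocks (pairwise
$r^2$ = `ld_r2`) spanning well under 10,000 kb and separated by 15,000
kb, so greedy clumping should keep exactly one SNP per block — a
per-block argmin-p oracle used by the tests. A `flip_frac` of outcome
records is written with swapped alleles (beta negated, EAF
complemented) and `palindromic_frac` of SNPs are A/T or G/C pairs, to
exercise harmonization.

The mediator-specific SNPs deserve a note: with the component at its
zero default the MVMR design matrix is exactly collinear
(mediator effects are $\beta_a \times$ exposure effects SNP-for-SNP) and
$\beta_b$ is unidentifiable. Recovery worlds therefore use 50 of them,
mirroring a well-instrumented protein mediator (the source's mediator
had ~300 instruments at the relaxed threshold).

Deliberately not modelled: individual genotypes, realistic allele
frequency spectra, population stratification, sample overlap between
exposure and outcome GWAS. A green recovery test therefore establishes
correctness of the estimators and plumbing under the stated structural
model — not robustness to confounding structures the generator cannot
produce.

## Numerical and calibration notes

* 95% intervals use $z = 1.959964$ everywhere; Egger and MVMR p-values
  use $t$ with $k-2$ df, IVW uses the normal.
* Selection on the exposure dataset induces winner's curse: at
  $n = 50{,}000$ with instrument SD 0.05, recovered effects attenuate a
  few percent, and the attenuation compounds in the mediation product
  (observed mean $\approx 0.106$ against a truth of 0.12 in the
  acceptance world). This is a property of the procedure itself — the
  same-sample selection the field practices — not of the estimators;
  at the stated world it stays within the 3-SE recovery criterion.
  Pushed to extreme sample sizes the outcome-association exclusion adds
  a second censoring mechanism (see above), which is why the recovery
  criteria are run at their stated sizes rather than in an $n \to
  \infty$ limit.
* All randomness flows from explicit seeds (`sim_config(seed=)`,
  bootstrap `seed`), and `simulate_triple()` restores the caller's RNG
  state.
* Ratio estimators guard degenerate inputs: a zero exposure beta is an
  error for a single Wald ratio; sub-minimum instrument counts raise
  named errors; zero-residual (exact-fit) regressions report exact
  coefficients with unscaled SEs rather than NaN.

## Known limitations

The proportion-mediated CI ignores the (small) dependence between the
mediation and total estimates; no MR-PRESSO-style outlier correction or
radial/Rucker model selection is provided; LD is block-equicorrelated
rather than reference-panel realistic; and the CLI's `r2` input is a
long-format pair table, not a reference panel.
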