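# the four causal estimators and the odds-ratio reporting scale

test_that("wald ratio arithmetic and its delta-method SE", {
  est <- wald_ratio(list(beta_exp = 0.1, se_exp = 0.005,
                         beta_out = 0.02, se_out = 0.01))
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.1)
  expect_equal(wald_ratio(list(beta_exp = 0.1, se_exp = 0.005,
                               beta_out = 0, se_out = 0.01))$beta, 0)
  expect_error(wald_ratio(list(beta_exp = 0, se_exp = 0.005,
                               beta_out = 0.1, se_out = 0.01)), "beta_exp")

  # Monte-Carlo oracle: ratio of normals with a strong denominator
  set.seed(401)
  draws <- rnorm(1e6, 0.02, 0.01) / rnorm(1e6, 0.1, 0.005)
  expect_lt(abs(sd(draws) - est$se) / est$se, 0.05)
})

test_that("IVW reduces to the homogeneous and equal-weight cases", {
  homog <- make_set(beta_exp = c(0.1, 0.2, 0.4),
                    beta_out = c(0.05, 0.10, 0.20), se_out = 0.01)
  fe <- mr_ivw(homog, random_effects = FALSE)
  mre <- mr_ivw(homog, random_effects = TRUE)
  expect_equal(fe$beta, 0.5)
  expect_equal(attr(fe, "Q"), 0)
  expect_equal(mre$se, fe$se) # Q = 0: inflation floors at 1

  two <- make_set(beta_exp = c(0.1, 0.1), beta_out = c(0.01, 0.03),
                  se_out = 0.01)
  expect_equal(mr_ivw(two)$beta, 0.2)
  expect_error(mr_ivw(two[1, ]), "at least 2")
})

test_that("IVW equals zero-intercept WLS on simulated instruments", {
  set.seed(402)
  set <- make_set(beta_exp = rnorm(20, 0, 0.1),
                  beta_out = rnorm(20, 0, 0.05),
                  se_out = runif(20, 0.005, 0.03))
  est <- mr_ivw(set, random_effects = FALSE)
  wls <- lm(beta_out ~ 0 + beta_exp, data = set, weights = 1 / set$se_out^2)
  expect_equal(est$beta, unname(coef(wls)[1]), tolerance = 1e-10)
  # FE se equals the model-based WLS slope se (dispersion fixed at 1)
  expect_equal(est$se,
               unname(sqrt(diag(vcov(wls)))[1]) / summary(wls)$sigma,
               tolerance = 1e-10)
})

test_that("IVW is invariant to ordering and harmonization flips", {
  set.seed(403)
  set <- make_set(beta_exp = rnorm(15, 0.05, 0.02),
                  beta_out = rnorm(15, 0.02, 0.02),
                  se_out = runif(15, 0.005, 0.02))
  base <- mr_ivw(set)
  perm <- set[sample(nrow(set)), ]
  expect_equal(mr_ivw(perm)$beta, base$beta)
  flipped <- set
  flip <- c(1, 4, 9)
  flipped$beta_exp[flip] <- -flipped$beta_exp[flip]
  flipped$beta_out[flip] <- -flipped$beta_out[flip]
  expect_equal(mr_ivw(flipped)$beta, base$beta)
  expect_gte(mr_ivw(set, TRUE)$se, mr_ivw(set, FALSE)$se)
})

test_that("Egger recovers an exact line and matches WLS with intercept", {
  bx <- seq(0.02, 0.2, length.out = 10)
  line <- make_set(beta_exp = bx, beta_out = 0.01 + 0.5 * bx, se_out = 0.01)
  est <- mr_egger(line)
  expect_equal(est$beta, 0.5, tolerance = 1e-10)
  expect_equal(est$egger_intercept, 0.01, tolerance = 1e-10)

  set.seed(404)
  noisy <- make_set(beta_exp = runif(20, 0.02, 0.2),
                    beta_out = rnorm(20, 0.05, 0.02),
                    se_out = runif(20, 0.005, 0.03))
  est2 <- mr_egger(noisy)
  wls <- lm(beta_out ~ beta_exp, data = noisy, weights = 1 / noisy$se_out^2)
  expect_equal(est2$beta, unname(coef(wls)[2]), tolerance = 1e-10)
  expect_equal(est2$egger_intercept, unname(coef(wls)[1]), tolerance = 1e-10)
  # orientation step makes the fit invariant to allele re-coding
  reco <- noisy
  reco$beta_exp[1:7] <- -reco$beta_exp[1:7]
  reco$beta_out[1:7] <- -reco$beta_out[1:7]
  est3 <- mr_egger(reco)
  expect_equal(est3$beta, est2$beta)
  expect_equal(est3$egger_intercept, est2$egger_intercept)
  expect_error(mr_egger(noisy[1:2, ]), "at least 3")
})

test_that("Egger intercept is calibrated under balanced pleiotropy and
           detects a directional mean", {
  runs <- function(mode, mu, seeds) {
    vapply(seeds, function(i) {
      sim <- simulate_triple(sim_config(
        n_snps = 120, n_instruments = 40, pleio_mode = mode,
        pleio_mean = mu, pleio_sd = 0.02, ld_block_size = 1, seed = i))
      iv <- select_instruments(sim$exposure, NULL, ld_r2_matrix(sim$truth))
      mr_egger(harmonize(iv, sim$outcome))$egger_intercept
    }, numeric(1))
  }
  bal <- runs("balanced", 0, 1:30)
  expect_lt(abs(mean(bal)), 3 * sd(bal) / sqrt(30))
  dir <- runs("directional", 0.02, 31:60)
  expect_lt(abs(mean(dir) - 0.02), 3 * sd(dir) / sqrt(30))
})

test_that("weighted median handles ties, dominance, and interpolation", {
  eq <- make_set(beta_exp = rep(0.1, 3),
                 beta_out = c(0.01, 0.02, 0.09), se_out = 0.01)
  expect_equal(mr_weighted_median(eq, n_boot = 50, seed = 1)$beta, 0.2)

  # one SNP holding > 50% of total weight returns its own ratio
  dom <- make_set(beta_exp = c(0.5, 0.1, 0.1),
                  beta_out = c(0.5 * 0.7, 0.1 * 0.1, 0.1 * 0.9),
                  se_out = 0.01)
  w <- dom$beta_exp^2 / dom$se_out^2
  expect_gt(w[1] / sum(w), 0.5)
  expect_equal(mr_weighted_median(dom, n_boot = 50, seed = 1)$beta, 0.7)
  expect_error(mr_weighted_median(eq[1:2, ], n_boot = 10, seed = 1),
               "at least 3")
})

test_that("weighted median resists 40% pleiotropic outliers where IVW fails", {
  set.seed(405)
  wm_ok <- ivw_off <- logical(40)
  for (i in seq_len(40)) {
    bx <- rnorm(20, 0.08, 0.02)
    ratio <- c(rep(0.3, 12), rep(1.2, 8)) # 60% valid, 40% outliers
    by <- ratio * bx + rnorm(20, 0, 0.004)
    set <- make_set(beta_exp = bx, beta_out = by, se_out = 0.004)
    wm <- mr_weighted_median(set, n_boot = 50, seed = i)
    ivw <- mr_ivw(set)
    wm_ok[i] <- abs(wm$beta - 0.3) <= 3 * wm$se
    ivw_off[i] <- abs(ivw$beta - 0.3) > 3 * ivw$se
  }
  expect_gte(mean(wm_ok), 0.9)  # median stays on the valid majority
  expect_gte(mean(ivw_off), 0.9) # IVW dragged > 3 SE toward the outliers
})

test_that("weighted mode finds the majority cluster and matches a dense grid", {
  const <- make_set(beta_exp = rep(0.1, 4), beta_out = rep(0.03, 4))
  expect_equal(mr_weighted_mode(const, n_boot = 20, seed = 1)$beta, 0.3)

  clus <- make_set(beta_exp = rep(0.1, 4),
                   beta_out = 0.1 * c(0.30, 0.31, 0.29, 1.5), se_out = 0.01)
  est <- mr_weighted_mode(clus, n_boot = 20, seed = 1)
  expect_lt(abs(est$beta - 0.30), 0.05)

  # grid-search argmax oracle with the documented bandwidth rule
  set.seed(406)
  set <- make_set(beta_exp = rnorm(15, 0.1, 0.03),
                  beta_out = rnorm(15, 0.03, 0.01),
                  se_out = runif(15, 0.005, 0.02))
  got <- mr_weighted_mode(set, n_boot = 20, seed = 2)$beta
  ratio <- set$beta_out / set$beta_exp
  w <- set$beta_exp^2 / set$se_out^2
  s <- 1.4826 * oracle_wmedian(abs(ratio - oracle_wmedian(ratio, w)), w)
  h <- 0.9 * s * 15^(-1 / 5)
  grid <- seq(min(ratio) - h, max(ratio) + h, length.out = 2e5)
  dens <- sapply(ratio, function(r) w[match(r, ratio)] *
                   dnorm((grid - r) / h))
  oracle <- grid[which.max(rowSums(dens))]
  expect_equal(got, oracle, tolerance = 1e-3)
})

test_that("all estimators converge on a single dominant instrument", {
  dom <- make_set(beta_exp = c(1.0, 0.02, 0.02, 0.02),
                  beta_out = c(0.25, 0.02 * 0.9, 0.02 * 0.1, 0.02 * 0.5),
                  se_out = c(0.001, 0.02, 0.02, 0.02))
  target <- 0.25
  expect_equal(mr_ivw(dom, random_effects = FALSE)$beta, target,
               tolerance = 0.01)
  expect_equal(mr_weighted_median(dom, n_boot = 20, seed = 1)$beta, target,
               tolerance = 0.01)
  expect_equal(mr_weighted_mode(dom, n_boot = 20, seed = 1)$beta, target,
               tolerance = 0.05)
})

test_that("odds-ratio scale is exp() of the log-odds scale and monotone", {
  est <- mr_ivw(make_set(beta_exp = c(0.1, 0.1),
                         beta_out = c(0.0068, 0.0068), se_out = 0.01))
  est$beta <- 0.068
  est$ci_low <- 0.032; est$ci_high <- 0.103
  est <- to_odds_scale(est)
  expect_equal(round(est$or_, 2), 1.07)
  expect_equal(est$or_ci_low, exp(0.032))

  est$beta <- 0; est$ci_low <- 0; est$ci_high <- 0
  expect_equal(to_odds_scale(est)$or_, 1.0)

  grid <- c(-1, -0.5, -0.1, 0, 0.143, 0.5, 1)
  ors <- vapply(grid, function(b) {
    est$beta <- b
    to_odds_scale(est)$or_
  }, numeric(1))
  expect_identical(order(ors), seq_along(ors))
  expect_equal(ors, exp(grid))
})

test_that("estimates_table flattens a full method run", {
  set.seed(407)
  set <- make_set(beta_exp = rnorm(10, 0.08, 0.02),
                  beta_out = rnorm(10, 0.02, 0.01),
                  se_out = runif(10, 0.005, 0.02))
  ests <- mr_all(set, n_boot = 30, seed = 5)
  tab <- estimates_table(ests, "expA", "outB")
  expect_equal(nrow(tab), 4L)
  expect_setequal(tab$method, c("ivw_mre", "egger", "weighted_median",
                                "weighted_mode"))
  expect_equal(tab$or, exp(tab$beta))
  expect_false(is.na(tab$egger_intercept[tab$method == "egger"]))
})
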