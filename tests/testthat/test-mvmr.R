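# multivariable MR and the two-step mediation decomposition

test_that("MVMR recovers an exact linear model and degenerates gracefully", {
  set.seed(901)
  bx <- rnorm(12, 0.1, 0.04)
  bm <- rnorm(12, 0.05, 0.05)
  exact <- data.frame(beta_exp = bx, beta_med = bm,
                      beta_out = 0.2 * bx + 0.4 * bm, se_out = 0.01)
  fit <- mvmr_ivw(exact)
  expect_equal(fit$beta_exposure, 0.2, tolerance = 1e-10)
  expect_equal(fit$beta_mediator, 0.4, tolerance = 1e-10)

  # all-zero mediator column: exposure coefficient equals univariable IVW
  degen <- data.frame(beta_exp = bx, beta_med = 0,
                      beta_out = 0.2 * bx + rnorm(12, 0, 0.01),
                      se_out = 0.01)
  fit2 <- mvmr_ivw(degen)
  uni <- mr_ivw(make_set(beta_exp = bx, beta_out = degen$beta_out))
  expect_equal(fit2$beta_exposure, uni$beta, tolerance = 1e-10)
  expect_true(is.na(fit2$beta_mediator))

  # collinear columns are a named error
  colin <- data.frame(beta_exp = bx, beta_med = 2 * bx,
                      beta_out = 0.2 * bx, se_out = 0.01)
  expect_error(mvmr_ivw(colin), "collinear")
  expect_error(mvmr_ivw(exact[1:2, ]), "at least 3")
})

test_that("MVMR equals a generic weighted-least-squares fit", {
  set.seed(902)
  k <- 25
  input <- data.frame(beta_exp = rnorm(k, 0.08, 0.04),
                      beta_med = rnorm(k, 0, 0.06),
                      beta_out = rnorm(k, 0.02, 0.03),
                      se_out = runif(k, 0.005, 0.03))
  fit <- mvmr_ivw(input)
  wls <- lm(beta_out ~ 0 + beta_exp + beta_med, data = input,
            weights = 1 / input$se_out^2)
  expect_equal(fit$beta_exposure, unname(coef(wls)[1]), tolerance = 1e-10)
  expect_equal(fit$beta_mediator, unname(coef(wls)[2]), tolerance = 1e-10)
  # SE = model-based WLS se times the floored dispersion inflation
  raw_se <- sqrt(diag(vcov(wls))) / summary(wls)$sigma
  q <- sum(residuals(wls)^2 / input$se_out^2)
  infl <- sqrt(max(1, q / (k - 2)))
  expect_equal(fit$se_mediator, unname(raw_se[2]) * infl, tolerance = 1e-10)
})

test_that("mediate() implements the product decomposition and its identities", {
  # arithmetic of the published decomposition: a log OR of 1.022 on the
  # mediator and 0.84 of the mediator on the outcome
  res <- mediate(beta_a = log(1.022), se_a = 0.007,
                 beta_b = log(0.84), se_b = 0.05,
                 total = 0.070, se_total = 0.02)
  expect_equal(round(res$mediation_effect, 3), -0.004)
  expect_identical(res$direct_effect,
                   res$total_effect - res$mediation_effect)
  expect_equal(round(res$direct_effect, 3), 0.074)

  # null mediator path
  null_a <- mediate(0, 0.01, -0.2, 0.05, total = 0.1, se_total = 0.02)
  expect_equal(null_a$mediation_effect, 0)
  expect_equal(null_a$direct_effect, 0.1)
  expect_equal(null_a$proportion_mediated, 0)

  # symmetry in (a, b)
  ab <- mediate(0.2, 0.03, -0.4, 0.05, 0.1, 0.02)
  ba <- mediate(-0.4, 0.05, 0.2, 0.03, 0.1, 0.02)
  expect_equal(ab$mediation_effect, ba$mediation_effect)
  expect_equal(ab$mediation_se, ba$mediation_se)

  # zero total: proportion undefined
  zt <- mediate(0.2, 0.03, -0.4, 0.05, total = 0, se_total = 0.02)
  expect_true(is.na(zt$proportion_mediated))

  # CI spanning zero suppresses the proportion CI
  wide <- mediate(0.02, 0.05, -0.17, 0.5, total = 0.07, se_total = 0.02)
  expect_true(wide$mediation_ci_low < 0 && wide$mediation_ci_high > 0)
  expect_true(is.na(wide$proportion_ci_low))
  tight <- mediate(0.2, 0.001, -0.4, 0.001, total = 0.07, se_total = 0.02)
  expect_false(is.na(tight$proportion_ci_low))

  # identity holds to machine precision on random inputs
  set.seed(903)
  for (i in 1:20) {
    r <- mediate(rnorm(1), 0.01, rnorm(1), 0.01, rnorm(1), 0.01)
    expect_identical(r$direct_effect, r$total_effect - r$mediation_effect)
  }
})

test_that("the Sobel SE matches a Monte-Carlo product of normals", {
  res <- mediate(0.02, 0.005, -0.17, 0.03, total = 0.07, se_total = 0.02)
  set.seed(904)
  prod <- rnorm(1e6, 0.02, 0.005) * rnorm(1e6, -0.17, 0.03)
  expect_lt(abs(res$mediation_se - sd(prod)) / sd(prod), 0.05)
})

test_that("the mediation pipeline recovers simulated truth", {
  sim <- sim_fixture(seed = 31, n_snps = 250, n_instruments = 50,
                     n_med_instruments = 50, beta_a = 0.3, beta_b = 0.4,
                     delta = 0.2)
  res <- run_mediation_pipeline(sim$exposure, sim$mediator, sim$outcome,
                                sim$r2)
  expect_lt(abs(res$beta_a - 0.3), 3 * res$se_a)
  expect_lt(abs(res$beta_b - 0.4), 3 * res$se_b)
  expect_lt(abs(res$total_effect - 0.32), 3 * res$se_total)
  expect_lt(abs(res$mediation_effect - 0.12), 3 * res$mediation_se)
  expect_identical(res$direct_effect,
                   res$total_effect - res$mediation_effect)
  steps <- attr(res, "steps")
  expect_s3_class(steps$beta_a, "mr_estimate")
  expect_s3_class(steps$sensitivity_step1, "sensitivity_report")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_mediation_results(res, path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(tab$mediation_effect, res$mediation_effect)
})

test_that("full mediation: with no direct effect the proportion approaches 100%", {
  sim <- sim_fixture(seed = 32, n_snps = 250, n_instruments = 50,
                     n_med_instruments = 50, n_exp = 2e5, n_med = 2e5,
                     n_case = 3e4, n_control = 3e5,
                     beta_a = 0.3, beta_b = 0.4, delta = 0)
  res <- run_mediation_pipeline(sim$exposure, sim$mediator, sim$outcome,
                                sim$r2)
  expect_lt(abs(res$proportion_mediated - 100), 3 * res$proportion_se)
})

test_that("a null mediator path yields a mediation CI covering zero", {
  covered <- vapply(1:20, function(i) {
    sim <- simulate_triple(sim_config(
      n_snps = 200, n_instruments = 40, n_med_instruments = 40,
      beta_a = 0.3, beta_b = 0, delta = 0.2, ld_block_size = 1,
      seed = 910 + i))
    res <- run_mediation_pipeline(sim$exposure, sim$mediator, sim$outcome,
                                  ld_r2_matrix(sim$truth))
    res$mediation_ci_low <= 0 && res$mediation_ci_high >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("each pipeline step reports its own failure", {
  sim <- sim_fixture(seed = 31, n_snps = 250, n_instruments = 50,
                     n_med_instruments = 50, beta_a = 0.3, beta_b = 0.4,
                     delta = 0.2)
  hopeless <- sim$exposure
  hopeless$pval <- rep(0.5, nrow(hopeless))
  expect_error(
    run_mediation_pipeline(hopeless, sim$mediator, sim$outcome, sim$r2),
    "step 1")
})
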