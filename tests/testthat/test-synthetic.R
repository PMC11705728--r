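test_that("identical configs give bit-identical bundles", {
  cfg <- sim_config("discovery", n_per_center = 5, n_probes = 10, seed = 1)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$beta, b2$beta)
  expect_identical(b1$detection_p, b2$detection_p)
  expect_identical(b1$cohort, b2$cohort)
  expect_identical(b1$expression, b2$expression)
})

test_that("symmetric Beta probes stay in (0,1) around 0.5", {
  cfg <- sim_config("discovery", n_per_center = 50, n_probes = 10, seed = 2)
  bp <- cbind(a = rep(50, 10), b = rep(50, 10))
  meth <- simulate_methylation(cfg, beta_params = bp)
  expect_true(all(meth$beta > 0 & meth$beta < 1))
  expect_true(all(abs(colMeans(meth$beta) - 0.5) < 0.1))
  bad <- bp; bad[3, 1] <- NA
  expect_error(simulate_methylation(cfg, beta_params = bad), "cgX")
})

test_that("detection noise fails the configured fraction of entries", {
  cfg <- sim_config("discovery", n_per_center = 5, n_probes = 10,
                    detection_noise = 0.10, seed = 3)
  meth <- simulate_methylation(cfg)   # 10 x 20 matrix
  n_fail <- sum(meth$detection_p > 0.05)
  # ~ Binomial(200, 0.1): 20 +/- 3 sd
  expect_true(abs(n_fail - 20) <= 3 * sqrt(200 * 0.1 * 0.9) + 1)
})

test_that("planted probes are dispersed enough to survive the CV rule", {
  cfg <- sim_config("discovery", n_per_center = 30, n_probes = 10, seed = 4)
  meth <- simulate_methylation(cfg)
  for (p in cfg$planted_probe_ids) {
    cv <- sd(meth$beta[p, ]) / mean(meth$beta[p, ])
    expect_gte(cv, 0.05)
  }
})

test_that("null hazard model produces unit-exponential times", {
  cfg <- sim_config("discovery", n_per_center = 2500, n_probes = 4,
                    covariate_coefficients = c(age = 0),
                    baseline_hazards = c(LUAD = 1, LUSC = 1),
                    censoring = list(target = NULL, horizon = Inf),
                    seed = 5)
  cov <- simulate_covariates(cfg)
  meth <- simulate_methylation(cfg)
  sv <- simulate_survival(cfg, cov, meth$beta)
  expect_true(all(sv$event == 1))
  expect_lt(abs(mean(sv$time) - 1), 3 / sqrt(10000))
})

test_that("negative planted four-way effect lengthens survival with the product", {
  cfg <- sim_config("discovery", n_per_center = 1250, n_probes = 4,
                    censoring = list(target = NULL, horizon = Inf),
                    seed = 6)
  cfg$planted_coefficients <- planted_interaction(-8e-7, cfg)
  cov <- simulate_covariates(cfg)
  meth <- simulate_methylation(cfg)
  sv <- simulate_survival(cfg, cov, meth$beta)
  d <- cfg$covariate_distributions
  mu_e <- (1 - d$p_smoking[["never"]]) * d$packyear_mean
  prod4 <- (cov$pack_years - mu_e) *
    (meth$beta["cgG1", ] * 100 - 50) *
    (meth$beta["cgG2", ] * 100 - 50) *
    (meth$beta["cgX", ] * 100 - 50)
  expect_gt(cor(prod4, sv$time, method = "spearman"), 0)
})

test_that("realized censoring tracks the configured target", {
  cfg <- sim_config("validation", seed = 7)   # n = 468, target 0.7607
  bu <- simulate_bundle(cfg, expression = FALSE)
  cens <- 1 - mean(bu$cohort$event)
  expect_true(cens >= 0.71 && cens <= 0.81)
  cfg2 <- sim_config("discovery", seed = 8)   # n = 524, target 0.479
  bu2 <- simulate_bundle(cfg2, expression = FALSE)
  cens2 <- 1 - mean(bu2$cohort$event)
  expect_true(cens2 >= 0.429 && cens2 <= 0.529)
})

test_that("never-smokers carry zero pack-years; smokers match the gamma", {
  cfg <- sim_config("discovery", n_per_center = 500, n_probes = 4, seed = 9)
  cov <- simulate_covariates(cfg)
  expect_true(all(cov$pack_years[cov$smoking_status == "never"] == 0))
  py <- cov$pack_years[cov$smoking_status != "never"]
  expect_lt(abs(mean(py) - 43.36), 3 * 31.1 / sqrt(length(py)))
})

test_that("cis expression is standardized and carries the planted correlation", {
  cfg <- sim_config("validation", n_per_center = 456, n_probes = 4,
                    cis_r = 0.455, seed = 10)
  cov <- simulate_covariates(cfg)
  meth <- simulate_methylation(cfg, center = cov$center)
  ex <- simulate_expression(cfg, meth$beta)
  expect_true(all(abs(rowMeans(ex$expression)) < 1e-9))
  expect_true(all(abs(apply(ex$expression, 1, sd) - 1) < 1e-9))
  r_hat <- cor(ex$expression["GENE_G1", ], meth$beta["cgG1", ])
  expect_lt(abs(r_hat - 0.455), 0.1)
  # r = 0: independence
  cfg0 <- sim_config("validation", n_per_center = 400, n_probes = 4,
                     cis_r = 0, seed = 11)
  cov0 <- simulate_covariates(cfg0)
  m0 <- simulate_methylation(cfg0, center = cov0$center)
  e0 <- simulate_expression(cfg0, m0$beta)
  expect_lt(abs(cor(e0$expression["GENE_G1", ], m0$beta["cgG1", ])), 0.1)
  expect_error(
    simulate_expression(cfg0, m0$beta,
                        cis_map = data.frame(probe = "cgG1", gene = "g",
                                             r = 1.2)),
    "\\|r\\| > 1")
})

test_that("overflowing planted effects are rejected with rescaling advice", {
  cfg <- sim_config("discovery", n_per_center = 250, n_probes = 4, seed = 12)
  cfg$planted_coefficients <- c("pack_years:cgG1:cgG2:cgX" = -1e-4)
  cov <- simulate_covariates(cfg)
  meth <- simulate_methylation(cfg)
  expect_error(simulate_survival(cfg, cov, meth$beta), "rescale")
})

test_that("fitting the planted model recovers the four-way coefficient", {
  b4 <- planted_four_way_default()
  pivot <- cover <- rep(NA_real_, 36)
  for (r in seq_along(cover)) {
    cfg <- sim_config("discovery", n_per_center = 250, n_probes = 6,
                      seed = 800 + r)
    cfg$planted_coefficients <- planted_interaction(b4, cfg)
    bu <- simulate_bundle(cfg, expression = FALSE)
    fit <- suppressWarnings(
      cox_interaction(bu$cohort, bu$beta, probes = cfg$planted_probe_ids))
    w <- wald_interaction_test(fit)
    pivot[r] <- (w$estimate - b4) / w$se
    cover[r] <- b4 >= w$estimate - 1.96 * w$se &&
      b4 <= w$estimate + 1.96 * w$se
  }
  # the estimator is unbiased on the pivot scale ...
  expect_lt(abs(mean(pivot)) / (sd(pivot) / sqrt(length(pivot))), 3.5)
  # ... and the Wald CI roughly calibrated; heavy-tailed interaction
  # regressors make the pivot t-like at this scale (coverage ~0.85-0.9,
  # see the methods vignette), so assert a conservative floor
  expect_gte(mean(cover), 0.7)
})
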