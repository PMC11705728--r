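test_that("the integrated score is exactly the fitted linear predictor", {
  cfg <- sim_config("discovery", n_per_center = 60, n_probes = 8, seed = 41)
  bu <- simulate_bundle(cfg, expression = FALSE)
  fit <- cox_interaction(bu$cohort, bu$beta, probes = c("cgG1", "cgG2", "cgX"))
  rs <- compute_triune(fit)
  expect_equal(rs$triune, unname(fit$linear_predictor), tolerance = 1e-12)
  expect_equal(rs$triune,
               unname(drop(fit$design %*% coef(fit))), tolerance = 1e-12)
  clin <- fit_clinical(bu$cohort)
  rs2 <- compute_triune(fit, clinical_fit = clin)
  expect_equal(rs2$clinical_score, unname(clin$linear_predictor),
               tolerance = 1e-12)
})

test_that("score arithmetic: weighted sum of components", {
  X <- cbind(age = c(50, 0), pack_years = c(30, 10))
  fit <- mock_interaction_fit(c(age = 0.02, pack_years = 0.01), X,
                              spec = list(k = 2))
  rs <- suppressWarnings(compute_triune(fit))
  expect_equal(rs$triune, c(0.02 * 50 + 0.01 * 30, 0.1))
  # all-zero coefficients give zero scores; quartiles are then undefined
  fit0 <- mock_interaction_fit(c(age = 0, pack_years = 0), X,
                               spec = list(k = 2))
  expect_warning(rs0 <- compute_triune(fit0), "quartile")
  expect_identical(rs0$triune, c(0, 0))
  expect_true(all(is.na(rs0$group)))
})

test_that("quartile groups split as specified, ties to the lower group", {
  expect_identical(as.vector(table(quartile_groups(1:8))), rep(2L, 4))
  g <- quartile_groups(c(1, 1, 1, 2))
  expect_identical(g, quartile_groups(c(1, 1, 1, 2)))   # deterministic
  expect_identical(g[1:3], rep(1L, 3))                   # ties go low
  set.seed(1)
  s <- rnorm(992)
  expect_identical(as.vector(table(quartile_groups(s))), rep(248L, 4))
  expect_error(quartile_groups(c(1, 1)), "at least 4")
  expect_error(quartile_groups(rep(2, 10)), "identical")
})

test_that("Kaplan-Meier estimator matches the hand product-limit", {
  km <- km_curve(c(1, 2, 3, 4), c(0, 1, 1, 1))
  at <- function(t) km$surv[km$time == t]
  expect_equal(at(2), 2 / 3, tolerance = 1e-12)
  expect_equal(at(3), 1 / 3, tolerance = 1e-12)
  expect_equal(at(4), 0, tolerance = 1e-12)
  expect_equal(km$median, 3)
  # no censoring: equals the empirical survival function
  set.seed(2)
  tt <- rexp(60)
  km2 <- km_curve(tt, rep(1, 60))
  expect_equal(km2$surv, 1 - ecdf(tt)(km2$time), tolerance = 1e-12)
  # all censored: S identically 1, median undefined
  km3 <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km3$surv == 1))
  expect_null(km3$median)
  expect_error(km_curve(c(0, 1), c(1, 1)), "> 0")
})

test_that("group hazard ratios match the brute-force oracle on a toy", {
  set.seed(3)
  n <- 20
  coh <- data.frame(time = sample(n) + runif(n, 0, 0.3),
                    event = rbinom(n, 1, 0.8),
                    stringsAsFactors = FALSE)
  groups <- rep(1:4, each = 5)
  tab <- group_hazard_ratios(coh, groups)
  X <- sapply(2:4, function(g) as.numeric(groups == g))
  b_oracle <- pl_fit(coh$time, coh$event, X)
  expect_equal(unname(log(tab$hr)), b_oracle, tolerance = 1e-4)
  expect_identical(tab$reference, rep("1", 3))
})

test_that("a planted monotone risk gradient yields ordered group HRs", {
  cfg <- sim_config("discovery", n_per_center = 250, n_probes = 6, seed = 44)
  cfg$planted_coefficients <- planted_interaction(-1.5e-6, cfg)
  bu <- simulate_bundle(cfg, expression = FALSE)
  fit <- suppressWarnings(
    cox_interaction(bu$cohort, bu$beta, probes = c("cgG1", "cgG2", "cgX")))
  rs <- compute_triune(fit)
  coh <- bu$cohort[match(rs$sample_id, bu$cohort$sample_id), ]
  tab <- group_hazard_ratios(coh, rs$group)
  expect_true(all(diff(tab$hr) > 0))   # HR2 < HR3 < HR4
  expect_gt(tab$hr[1], 1)
})

test_that("TRIUNE separates risk groups better than the clinical score", {
  wins <- 0
  for (r in 1:5) {
    cfg <- sim_config("discovery", n_per_center = 150, n_probes = 6,
                      seed = 400 + r)
    cfg$planted_coefficients <- planted_interaction(-1.5e-6, cfg)
    bu <- simulate_bundle(cfg, expression = FALSE)
    fit <- suppressWarnings(
      cox_interaction(bu$cohort, bu$beta,
                      probes = c("cgG1", "cgG2", "cgX")))
    clin <- fit_clinical(bu$cohort)
    rs <- compute_triune(fit, clinical_fit = clin)
    coh <- bu$cohort[match(rs$sample_id, bu$cohort$sample_id), ]
    lr_stat <- function(groups) {
      idx <- groups %in% c(1, 4)
      survival::survdiff(survival::Surv(coh$time[idx], coh$event[idx]) ~
                           groups[idx])$chisq
    }
    wins <- wins + (lr_stat(rs$group) >
                      lr_stat(quartile_groups(rs$clinical_score)))
  }
  expect_gte(wins, 4)
})

test_that("stratified forest: single-level factor equals the plain fit", {
  cfg <- sim_config("validation", n_per_center = 150, n_probes = 4,
                    seed = 45)
  bu <- simulate_bundle(cfg, expression = FALSE)
  scores <- rnorm(nrow(bu$cohort))
  tab <- stratified_forest(bu$cohort, scores, strata_factors = "center")
  expect_identical(nrow(tab), 1L)
  ref <- fit_cox(bu$cohort$time, bu$cohort$event,
                 cbind(score_sd = scores / sd(scores)))
  expect_equal(tab$hr, unname(ref$hr), tolerance = 1e-10)
  # tiny strata are skipped with a warning
  coh <- bu$cohort
  coh$flag <- c(rep("big", nrow(coh) - 4), rep("tiny", 4))
  expect_warning(stratified_forest(coh, scores, strata_factors = "flag"),
                 "skipped")
})

test_that("conditional effect surface equals the closed form", {
  vars <- c("pack_years", "g1", "g2", "x")
  labs <- expand_terms("pack_years", c("g1", "g2", "x"))
  cf <- setNames(rep(0, 15), labs)
  cf["x"] <- 0.02
  cf["pack_years:x"] <- 1e-3
  cf["g2:x"] <- -2e-4
  cf["pack_years:g1:g2:x"] <- -5e-6
  set.seed(6)
  X <- sapply(labs, function(l) runif(30, 10, 60))
  colnames(X) <- labs
  fit <- mock_interaction_fit(cf, X,
                              spec = list(k = 4, exposure = "pack_years",
                                          probes = c("g1", "g2", "x")))
  surf <- conditional_effect_surface(fit, exposure_grid = c(20, 35, 50),
                                     g1_grid = c(15, 30, 45))
  for (i in sample(nrow(surf), 9)) {
    row <- surf[i, ]
    expected <- cf[["x"]] + cf[["pack_years:x"]] * row$exposure +
      cf[["g2:x"]] * row$g2_ref +
      cf[["pack_years:g1:g2:x"]] * row$exposure * row$g1 * row$g2_ref
    expect_equal(row$log_hr, unname(expected), tolerance = 1e-12)
  }
  # no interaction terms: constant surface exp(beta_x)
  cf0 <- setNames(rep(0, 15), labs)
  cf0["x"] <- 0.01
  fit0 <- mock_interaction_fit(cf0, X,
                               spec = list(k = 4, exposure = "pack_years",
                                           probes = c("g1", "g2", "x")))
  s0 <- conditional_effect_surface(fit0, exposure_grid = c(20, 40),
                                   g1_grid = c(20, 40))
  expect_true(all(abs(s0$hr - exp(0.01)) < 1e-12))
  # opposite tilt of the two subgroup surfaces under a pure four-way term
  cf4 <- setNames(rep(0, 15), labs)
  cf4["pack_years:g1:g2:x"] <- -5e-6
  X2 <- X
  X2[, "g2"] <- c(rep(-20, 15), rep(20, 15))   # subgroup medians straddle 0
  fit4 <- mock_interaction_fit(cf4, X2,
                               spec = list(k = 4, exposure = "pack_years",
                                           probes = c("g1", "g2", "x")))
  s4 <- conditional_effect_surface(fit4, exposure_grid = c(20, 40),
                                   g1_grid = c(20, 40))
  lo <- s4[s4$subgroup == "low", ]
  hi <- s4[s4$subgroup == "high", ]
  slope <- function(d) d$log_hr[d$exposure == 40 & d$g1 == 40] -
    d$log_hr[d$exposure == 20 & d$g1 == 20]
  expect_gt(slope(lo), 0)   # negative beta4, negative g2 ref
  expect_lt(slope(hi), 0)
})
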