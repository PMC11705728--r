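test_that("with no censoring the timed AUC is the binary Mann-Whitney AUC", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(15:40, 1)
    tt <- runif(n, 0.5, 10)
    sc <- rnorm(n)
    h <- stats::median(tt)
    ta <- timed_auc(sc, tt, rep(1, n), h)
    expect_equal(ta$auc, auc_binary(sc, as.integer(tt <= h)),
                 tolerance = 1e-12)
  }
})

test_that("uninformative scores give AUC one half", {
  tt <- c(1, 2, 3, 4, 5, 6)
  ta <- timed_auc(rep(1, 6), tt, rep(1, 6), 3.5)
  expect_equal(ta$auc, 0.5, tolerance = 1e-12)
})

test_that("six-sample censored fixture matches the hand-computed weights", {
  # subjects: (time, event, score); horizon 3
  tt <- c(1, 2, 2.5, 4, 5, 6)
  ev <- c(1, 0, 1, 1, 0, 1)
  sc <- c(5, 4, 2.5, 3, 2, 1)
  h <- 3
  # censoring KM G: censoring events at t=2 (Y=5) and t=5 (Y=2)
  # G(t) = 1 for t < 2; 4/5 for 2 <= t < 5; 2/5 for t >= 5
  # cases: t=1 (G(1-)=1), t=2.5 (G(2.5-)=4/5); controls: t=4,5,6 (G(3)=4/5)
  w1 <- 1; w3 <- 1 / (4 / 5); wc <- 1 / (4 / 5)
  num <- w1 * wc * 3 + w3 * wc * 2   # score 5 beats 3,2,1; score 2.5 beats 2,1
  den <- (w1 + w3) * (3 * wc)
  ta <- timed_auc(sc, tt, ev, h)
  expect_equal(ta$auc, num / den, tolerance = 1e-10)
  expect_true(ta$ci[1] <= ta$auc && ta$auc <= ta$ci[2])
})

test_that("timed AUC is invariant to strictly monotone score transforms", {
  set.seed(12)
  tt <- rexp(50, 0.2)
  ev <- rbinom(50, 1, 0.6)
  sc <- rnorm(50)
  h <- stats::median(tt)
  a1 <- timed_auc(sc, tt, ev, h)
  a2 <- timed_auc(exp(2 * sc) + 7, tt, ev, h)
  expect_equal(a1$auc, a2$auc, tolerance = 1e-12)
  expect_equal(a1$se, a2$se, tolerance = 1e-12)
  expect_error(timed_auc(sc, tt, ev, 1e6), "one case and one control")
})

test_that("influence-function variance agrees with DeLong when uncensored", {
  set.seed(13)
  n <- 120
  tt <- runif(n, 1, 9)
  sc <- tt * -0.5 + rnorm(n)
  h <- 5
  ta <- timed_auc(sc, tt, rep(1, n), h)
  dc <- delong_components(sc, as.integer(tt <= h))
  m <- sum(tt <= h); k <- n - m
  se_delong <- sqrt(var(dc$v10) / m + var(dc$v01) / k)
  expect_lt(abs(ta$se - se_delong) / se_delong, 0.15)
})

test_that("DeLong test matches the independent pROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  for (rep in 1:5) {
    n <- 80
    lab <- rbinom(n, 1, 0.4)
    s1 <- lab + rnorm(n)
    s2 <- 0.5 * lab + rnorm(n)
    ours <- delong_test(s1, s2, lab)
    ref <- pROC::roc.test(pROC::roc(lab, s1, quiet = TRUE),
                          pROC::roc(lab, s2, quiet = TRUE),
                          method = "delong", paired = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
    expect_equal(ours$auc_a, as.numeric(pROC::auc(pROC::roc(lab, s1,
                                                            quiet = TRUE))),
                 tolerance = 1e-12)
  }
})

test_that("AUC comparison: identical scores, method switching, arithmetic", {
  set.seed(15)
  tt <- runif(40, 1, 9)
  ev <- rep(1, 40)
  sc <- rnorm(40)
  cmp <- compare_auc(sc, sc, tt, ev, 5)
  expect_equal(cmp$delta_auc, 0)
  expect_equal(cmp$p, 1)
  expect_match(cmp$method, "DeLong")
  # censored: falls back to the iid contrast
  ev2 <- ev; ev2[tt <= 5][1:3] <- 0
  cmp2 <- compare_auc(sc, rnorm(40), tt, ev2, 5)
  expect_match(cmp2$method, "iid")
  expect_equal(cmp2$relative_increase_pct,
               100 * cmp2$delta_auc / cmp2$auc_small, tolerance = 1e-12)
})

test_that("C-index: hand examples, oracle equivalence, negation symmetry", {
  expect_equal(c_index(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1.0)
  expect_equal(c_index(c(2, 3, 1), c(1, 2, 3), c(1, 1, 1)), 2 / 3)
  set.seed(16)
  for (rep in 1:50) {
    n <- sample(5:12, 1)
    tt <- sample(n) + runif(n, 0, 0.4)
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) ev[1] <- 1
    sc <- sample(1:4, n, TRUE)   # include score ties
    expect_equal(c_index(sc, tt, ev), cindex_brute(sc, tt, ev),
                 tolerance = 1e-15)
  }
  # untied scores: c(score) + c(-score) = 1
  sc <- rnorm(10); tt <- sample(10) + runif(10, 0, .2); ev <- rep(1, 10)
  expect_equal(c_index(sc, tt, ev) + c_index(-sc, tt, ev), 1,
               tolerance = 1e-12)
  expect_equal(c_index(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1),
                       symmetric = TRUE), 1.0)
  expect_error(c_index(c(1, 2), c(2, 2), c(1, 1)), "usable")
})

test_that("nested models on planted data order as expected; null is flat", {
  cfg <- sim_config("discovery", n_per_center = 250, n_probes = 6, seed = 47)
  cfg$planted_coefficients <- planted_interaction(-1.5e-6, cfg)
  bu <- simulate_bundle(cfg, expression = FALSE)
  nm <- suppressWarnings(
    nested_models(bu$cohort, bu$beta, c("cgG1", "cgG2", "cgX")))
  a3 <- nm$auc$auc[nm$auc$horizon == 3]
  names(a3) <- nm$auc$model[nm$auc$horizon == 3]
  expect_gte(a3[["c_fourway"]], a3[["b_threeway"]] - 0.02)
  expect_gte(a3[["b_threeway"]], a3[["a_covariates"]] - 0.02)
  expect_gt(a3[["c_fourway"]], a3[["a_covariates"]])
  expect_identical(nrow(nm$contrasts), 6L)
  expect_true(all(nm$c_index$c_index > 0.5))

  # null bundle: all three AUCs near 0.5
  cfg0 <- sim_config("discovery", n_per_center = 150, n_probes = 6,
                     covariate_coefficients = c(age = 0), seed = 48)
  bu0 <- simulate_bundle(cfg0, expression = FALSE)
  nm0 <- suppressWarnings(
    nested_models(bu0$cohort, bu0$beta, c("cgG1", "cgG2", "cgX")))
  expect_true(all(nm0$auc$ci_low <= 0.55 & nm0$auc$ci_high >= 0.45))
})

test_that("ROC points are monotone and bracket the AUC construction", {
  set.seed(18)
  tt <- rexp(60, 0.2); ev <- rbinom(60, 1, 0.7); sc <- rnorm(60)
  roc <- timed_roc(sc, tt, ev, stats::median(tt))
  expect_true(all(diff(roc$tpr) >= -1e-12))
  expect_true(all(diff(roc$fpr) >= -1e-12))
  expect_true(all(roc$tpr >= 0 & roc$tpr <= 1))
})
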