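test_that("BH adjustment matches hand and brute-force computations", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.1, 1.2)), "outside")
  # missing values are skipped, not counted in m
  q <- bh_adjust(c(0.02, NA, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_adjust(c(0.02, 0.04)))
  set.seed(42)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-15)
  }
})

test_that("two-phase rule enforces both thresholds and direction", {
  disc <- data.frame(probe = c("a", "b", "c", "d"),
                     beta = c(-1, -1, 1, -1), p = c(1e-6, 1e-4, 1e-3, 0.04),
                     q = c(0.027, 0.04, 0.045, 0.2))
  attr(disc, "fixed_probes") <- character()
  attr(disc, "exposure") <- "pack_years"
  valid <- data.frame(probe = c("a", "b", "c"),
                      beta = c(-0.8, 0.9, 1.2), p = c(0.014, 0.03, 0.2))
  dec <- two_phase_decide(disc, valid)
  expect_identical(dec$probe, c("a", "b", "c"))   # q <= 0.05 only
  expect_identical(dec$pass, c(TRUE, FALSE, FALSE))
  expect_false(dec$direction_consistent[2])        # sign flip fails rule (b)
  # probe absent from validation: untestable, never passed
  valid2 <- valid[valid$probe != "a", ]
  dec2 <- two_phase_decide(disc, valid2)
  expect_true(dec2$untestable[dec2$probe == "a"])
  expect_false(dec2$pass[dec2$probe == "a"])
  # pass set is always a subset of the discovery q <= 0.05 set
  expect_true(all(dec$probe[dec$pass] %in% disc$probe[disc$q <= 0.05]))
})

test_that("null scan rejects at about the nominal rate", {
  cfg <- sim_config("discovery", n_per_center = 75, n_probes = 300,
                    seed = 61)
  bu <- simulate_bundle(cfg, expression = FALSE)
  sc <- scan_order_k(bu$cohort, bu$beta, fixed_probes = c("cgG1", "cgG2"))
  expect_identical(nrow(sc), 298L)
  rate <- mean(sc$p <= 0.05, na.rm = TRUE)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 298) + 0.02)
  # q-values respect the step-up ordering
  o <- order(sc$p)
  expect_true(all(diff(sc$q[o][!is.na(sc$q[o])]) >= -1e-12))
})

test_that("scan results are invariant to candidate ordering", {
  cfg <- sim_config("discovery", n_per_center = 40, n_probes = 20, seed = 62)
  bu <- simulate_bundle(cfg, expression = FALSE)
  cand <- setdiff(rownames(bu$beta), c("cgG1", "cgG2"))
  s1 <- scan_order_k(bu$cohort, bu$beta, fixed_probes = c("cgG1", "cgG2"),
                     candidates = cand)
  s2 <- scan_order_k(bu$cohort, bu$beta, fixed_probes = c("cgG1", "cgG2"),
                     candidates = rev(cand))
  m <- match(s1$probe, s2$probe)
  expect_equal(s1$beta, s2$beta[m], tolerance = 1e-10)
  expect_equal(s1$p, s2$p[m], tolerance = 1e-10)
})

test_that("a strongly planted four-way signal tops the scan and validates", {
  b4 <- -8e-7    # strong setting: near-certain end-to-end detection
  cfg0 <- sim_config("discovery", seed = 1)
  pc <- planted_interaction(b4, cfg0)
  cfgd <- sim_config("discovery", n_per_center = 250, n_probes = 100,
                     planted_coefficients = pc, seed = 63)
  cfgv <- sim_config("validation", n_per_center = 400, n_probes = 100,
                     planted_coefficients = pc, seed = 64)
  bd <- simulate_bundle(cfgd, expression = FALSE)
  bv <- simulate_bundle(cfgv, expression = FALSE)
  sd_ <- scan_order_k(bd$cohort, bd$beta, fixed_probes = c("cgG1", "cgG2"))
  expect_identical(sd_$probe[which(sd_$rank == 1)], "cgX")
  sv <- scan_order_k(bv$cohort, bv$beta, fixed_probes = c("cgG1", "cgG2"),
                     candidates = sd_$probe[!is.na(sd_$q) & sd_$q <= 0.05])
  dec <- two_phase_decide(sd_, sv)
  expect_true("cgX" %in% dec$probe[dec$pass])
  expect_true(all(sign(dec$beta_disc[dec$pass]) ==
                    sign(dec$beta_valid[dec$pass])))
})

test_that("hill climbing recovers a planted winner sequence and stops on null", {
  # plant nested centered-product interactions so each order has its own
  # signal: b * prod_{v in S} (v - mu_v) expanded onto raw factorial terms
  cfg0 <- sim_config("discovery", seed = 1)
  d <- cfg0$covariate_distributions
  mu_e <- (1 - d$p_smoking[["never"]]) * d$packyear_mean
  centered_plant <- function(b, vars, mu) {
    out <- numeric(0)
    k <- length(vars)
    for (size in seq_len(k)) {
      for (s in utils::combn(k, size, simplify = FALSE)) {
        lab <- paste(vars[s], collapse = ":")
        out[lab] <- b * prod(-mu[setdiff(seq_len(k), s)])
      }
    }
    out
  }
  p2 <- centered_plant(-8e-4, c("pack_years", "cgG1"), c(mu_e, 50))
  p3 <- centered_plant(-2.5e-5, c("pack_years", "cgG1", "cgG2"),
                       c(mu_e, 50, 50))
  p4 <- planted_interaction(-1e-6, cfg0)
  pc <- p4
  for (nm in names(p2)) pc[nm] <- pc[nm] + p2[nm]
  for (nm in names(p3)) pc[nm] <- pc[nm] + p3[nm]
  cfgd <- sim_config("discovery", n_per_center = 250, n_probes = 30,
                     planted_coefficients = pc, seed = 65)
  cfgv <- sim_config("validation", n_per_center = 400, n_probes = 30,
                     planted_coefficients = pc, seed = 66)
  bd <- simulate_bundle(cfgd, expression = FALSE)
  bv <- simulate_bundle(cfgv, expression = FALSE)
  hc <- hill_climb(bd$cohort, bd$beta, bv$cohort, bv$beta, max_order = 4)
  expect_identical(hc$winners, c("cgG1", "cgG2", "cgX"))

  # all-null bundles: empty winner list, stops at order 2
  cfgn <- sim_config("discovery", n_per_center = 60, n_probes = 15,
                     seed = 67)
  cfgm <- sim_config("validation", n_per_center = 120, n_probes = 15,
                     seed = 68)
  bn <- simulate_bundle(cfgn, expression = FALSE)
  bm <- simulate_bundle(cfgm, expression = FALSE)
  hn <- hill_climb(bn$cohort, bn$beta, bm$cohort, bm$beta, max_order = 4)
  expect_length(hn$winners, 0)
  expect_identical(names(hn$scans), "order2")
})

test_that("pre-specified winners reproduce the fourth-slot-only design", {
  cfg0 <- sim_config("discovery", seed = 1)
  pc <- planted_interaction(-8e-7, cfg0)
  cfgd <- sim_config("discovery", n_per_center = 250, n_probes = 30,
                     planted_coefficients = pc, seed = 69)
  cfgv <- sim_config("validation", n_per_center = 400, n_probes = 30,
                     planted_coefficients = pc, seed = 70)
  bd <- simulate_bundle(cfgd, expression = FALSE)
  bv <- simulate_bundle(cfgv, expression = FALSE)
  hc <- hill_climb(bd$cohort, bd$beta, bv$cohort, bv$beta,
                   fixed_probes = c("cgG1", "cgG2"), max_order = 4)
  expect_identical(names(hc$scans), "order4")
  expect_identical(hc$winners, "cgX")
  expect_identical(attr(hc$scans$order4, "k"), 4L)
})

test_that("scan validates its inputs", {
  cfg <- sim_config("discovery", n_per_center = 10, n_probes = 5, seed = 71)
  bu <- simulate_bundle(cfg, expression = FALSE)
  expect_error(scan_order_k(bu$cohort, bu$beta, candidates = character()),
               "empty candidate")
  coh <- bu$cohort
  coh$pack_years <- 1
  expect_error(scan_order_k(coh, bu$beta), "constant")
  expect_error(scan_order_k(bu$cohort, bu$beta, fixed_probes = "nope"),
               "absent")
})
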