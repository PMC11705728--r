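# Synthetic multi-center NSCLC methylation-survival cohorts with planted
# high-order gene-smoking interactions.  The generator emulates the structure
# of a two-phase early-stage NSCLC study: a LUAD-dominant multi-center
# discovery super-cohort (~524 samples, censoring ~0.48) and a single-center
# validation cohort (~468 samples, censoring ~0.76), beta-valued probes, and
# pack-years with mean ~43 / SD ~31 among smokers.

# deterministic sub-stream seeds derived from one global integer seed
sub_seed <- function(seed, k) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 8L)[k]
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

#' Configuration for a synthetic cohort
#'
#' Presets reproduce the two study phases: `"discovery"` is a four-center,
#' LUAD-dominant cohort (524 samples, target censoring 0.479) and
#' `"validation"` a single-center cohort (468 samples, LUAD/LUSC balanced,
#' target censoring 0.7607). Pack-years among smokers follow a gamma
#' distribution matched to mean 43.36 / SD 31.10; never-smokers have
#' pack-years 0.
#'
#' `planted_coefficients` is a named map from factorial term labels (as
#' produced by [expand_terms()] with the exposure `"pack_years"` and the
#' planted probe ids) to log-hazard coefficients; unspecified terms are 0.
#' All-zero (the default) gives a global-null cohort.
#'
#' @param phase preset: `"discovery"` or `"validation"`.
#' @param n_per_center samples per center (recycled over `centers`).
#' @param centers center labels.
#' @param n_probes number of methylation probes (>= 4).
#' @param planted_probe_ids ids of the three interaction-partner probes
#'   (G1, G2, X); always the first three probes of the matrix.
#' @param planted_coefficients named numeric map term -> log-hazard
#'   coefficient (see Details).
#' @param covariate_coefficients named log-hazard effects of the clinical
#'   covariates used when simulating survival.
#' @param covariate_distributions list of covariate sampling parameters
#'   (age mean/sd, sex male proportion, smoking-status proportions, stage II
#'   proportion, LUAD proportion, pack-year mean/sd among smokers).
#' @param baseline_hazards per-histology exponential baseline rates (1/year).
#' @param censoring list with `target` (censoring fraction aimed at) and
#'   `horizon` (administrative follow-up limit, years); `target = NULL`
#'   disables random censoring.
#' @param detection_noise fraction of detection p-value entries made to fail
#'   (p > 0.05).
#' @param center_shift_sd SD of the per-center location shift added to beta
#'   values (batch effect stand-in).
#' @param n_null_genes extra noise genes in the expression matrix.
#' @param cis_r correlation planted between each planted probe and its cis
#'   gene in the expression matrix.
#' @param seed integer seed fixing the whole bundle bit-for-bit.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(phase = c("discovery", "validation"),
                       n_per_center = NULL, centers = NULL,
                       n_probes = 500,
                       planted_probe_ids = c("cgG1", "cgG2", "cgX"),
                       planted_coefficients = numeric(0),
                       covariate_coefficients = c(
                         age = 0.02, sexM = 0.2, smoking_statusever = 0.1,
                         smoking_statuscurrent = 0.3, stageII = 0.5),
                       covariate_distributions = NULL,
                       baseline_hazards = c(LUAD = 0.12, LUSC = 0.18),
                       censoring = NULL,
                       detection_noise = 0,
                       center_shift_sd = 0.01,
                       n_null_genes = 20,
                       cis_r = 0.455,
                       seed = 1L) {
  phase <- match.arg(phase)
  if (phase == "discovery") {
    if (is.null(centers)) centers <- c("Harvard", "Spain", "Norway", "Sweden")
    if (is.null(n_per_center)) n_per_center <- 131L
    dist_default <- list(age_mean = 66.7, age_sd = 10.04, p_male = 0.5095,
                         p_smoking = c(never = 0.1527, ever = 0.5324,
                                       current = 0.3149),
                         p_stage2 = 0.2462, p_luad = 0.8111,
                         packyear_mean = 43.36, packyear_sd = 31.10)
    if (is.null(censoring)) censoring <- list(target = 0.479, horizon = 12)
  } else {
    if (is.null(centers)) centers <- "TCGA"
    if (is.null(n_per_center)) n_per_center <- 468L
    dist_default <- list(age_mean = 66.52, age_sd = 9.3, p_male = 0.6047,
                         p_smoking = c(never = 0, ever = 0.6902,
                                       current = 0.3098),
                         p_stage2 = 0.3568, p_luad = 0.485,
                         packyear_mean = 43.36, packyear_sd = 31.10)
    if (is.null(censoring)) censoring <- list(target = 0.7607, horizon = 12)
  }
  dist <- utils::modifyList(dist_default,
                            as.list(covariate_distributions %||% list()))
  if (n_probes < 4) stop("n_probes must be >= 4")
  if (length(planted_probe_ids) != 3)
    stop("planted_probe_ids must name three probes (G1, G2, X)")
  props <- c(dist$p_male, dist$p_smoking, dist$p_stage2, dist$p_luad)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0,1]")
  if (length(planted_coefficients) && any(!is.finite(planted_coefficients)))
    stop("planted coefficients must be finite")
  if (detection_noise < 0 || detection_noise > 1)
    stop("detection_noise must lie in [0,1]")
  cfg <- list(phase = phase,
              n_per_center = rep_len(as.integer(n_per_center),
                                     length(centers)),
              centers = centers, n_probes = as.integer(n_probes),
              planted_probe_ids = planted_probe_ids,
              planted_coefficients = planted_coefficients,
              covariate_coefficients = covariate_coefficients,
              covariate_distributions = dist,
              baseline_hazards = baseline_hazards,
              censoring = censoring, detection_noise = detection_noise,
              center_shift_sd = center_shift_sd,
              n_null_genes = as.integer(n_null_genes), cis_r = cis_r,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration (", x$phase, " preset)\n", sep = "")
  cat("centers:", paste(sprintf("%s(n=%d)", x$centers, x$n_per_center),
                        collapse = ", "), "\n")
  cat("probes:", x$n_probes, "; planted:",
      paste(x$planted_probe_ids, collapse = ", "), "\n")
  np <- sum(x$planted_coefficients != 0)
  cat("non-zero planted coefficients:", np,
      if (np == 0) "(global null)", "\n")
  cat("censoring target:", x$censoring$target %||% "none",
      "; horizon:", x$censoring$horizon, "years; seed:", x$seed, "\n")
  invisible(x)
}

#' All factorial term labels of the planted four-way model
#'
#' Convenience for building `planted_coefficients` maps: the 15 full-factorial
#' labels for pack-years and the three planted probes, initialized to 0.
#'
#' @param config a `sim_config`.
#' @return named numeric vector of zeros.
#' @export
planted_terms <- function(config) {
  labs <- expand_terms("pack_years", config$planted_probe_ids)
  stats::setNames(numeric(length(labs)), labs)
}

#' Centered-product interaction coefficient map
#'
#' Expands a pure four-way interaction planted on the centered product
#' `effect * (E - mu_E)(g1 - mu_1)(g2 - mu_2)(x - mu_x)` into the implied
#' coefficients of all 15 raw-scale factorial terms (the constant is
#' absorbed by the baseline hazard). The highest-order coefficient equals
#' `effect`, and because the centered product is nearly orthogonal to the
#' lower-order terms the planted signal is concentrated on the four-way
#' test rather than being absorbed by main effects -- planting on the raw
#' product instead distorts the hazard heavily while adding almost no
#' testable four-way information. Centering constants are the theoretical
#' generator means (expected pack-years including never-smokers; planted
#' probes at 50%).
#'
#' @param effect log-hazard coefficient of the four-way term (per pack-year
#'   x 1% x 1% x 1%).
#' @param config a `sim_config` (supplies the centering means).
#' @return named 15-element coefficient map for `planted_coefficients`.
#' @export
planted_interaction <- function(effect, config) {
  d <- config$covariate_distributions
  p_never <- d$p_smoking[["never"]] / sum(d$p_smoking)
  mu <- c((1 - p_never) * d$packyear_mean, 50, 50, 50)
  vars <- c("pack_years", config$planted_probe_ids)
  subsets <- term_subsets(4L, "full_factorial")
  out <- vapply(subsets, function(s)
    effect * prod(-mu[setdiff(1:4, s)]), numeric(1))
  names(out) <- vapply(subsets, function(s)
    paste(vars[s], collapse = ":"), character(1))
  out
}

#' Planted four-way log-hazard coefficient at the calibrated power setting
#'
#' The default four-way effect size used in planted-signal experiments,
#' intended to be expanded through [planted_interaction()]: calibrated by
#' simulation so that the end-to-end two-phase detection -- discovery
#' FDR-q <= 0.05 among 2000 scanned probes at n = 1000 (~48% censoring),
#' then validation p <= 0.05 at n = 500 (~76% censoring) -- succeeds in
#' roughly 80% of replicates. See the methods vignette for the calibration
#' procedure.
#'
#' @return the calibrated four-way log-hazard coefficient (per pack-year x
#'   1% x 1% x 1%).
#' @export
planted_four_way_default <- function() {
  -9.5e-07
}

probe_ids <- function(config) {
  ids <- sprintf("cg%06d", seq_len(config$n_probes))
  ids[1:3] <- config$planted_probe_ids
  ids
}

#' Simulate clinical covariates for a multi-center cohort
#'
#' @param config a `sim_config`.
#' @return data frame with sample_id, center, age, sex, smoking_status,
#'   pack_years, stage and histology. Never-smokers have pack-years 0.
#' @export
simulate_covariates <- function(config) {
  set.seed(sub_seed(config$seed, 1L))
  d <- config$covariate_distributions
  center <- rep(config$centers, times = config$n_per_center)
  n <- length(center)
  smoking_p <- d$p_smoking / sum(d$p_smoking)
  smoking <- sample(names(smoking_p), n, replace = TRUE, prob = smoking_p)
  shape <- (d$packyear_mean / d$packyear_sd)^2
  rate <- shape / d$packyear_mean
  pack <- ifelse(smoking == "never", 0,
                 stats::rgamma(n, shape = shape, rate = rate))
  data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    center = center,
    age = round(stats::rnorm(n, d$age_mean, d$age_sd), 1),
    sex = ifelse(stats::runif(n) < d$p_male, "M", "F"),
    smoking_status = smoking,
    pack_years = round(pack, 2),
    stage = ifelse(stats::runif(n) < d$p_stage2, "II", "I"),
    histology = ifelse(stats::runif(n) < d$p_luad, "LUAD", "LUSC"),
    stringsAsFactors = FALSE)
}

#' Simulate a beta-value methylation matrix with detection p-values
#'
#' Each probe is drawn from a probe-specific Beta(a, b) whose mean spans
#' hypo-, hemi- and hyper-methylated regimes; the three planted probes use a
#' mid-range, dispersed Beta so their coefficient of variation is at least 5%
#' and they survive QC. Detection p-values are Uniform(0, 0.01) except for a
#' configured fraction forced above 0.05. A per-center location shift (the
#' batch-effect stand-in) is added and values clipped to [0, 1].
#'
#' @param config a `sim_config`.
#' @param center optional vector of center labels per sample (defaults to the
#'   configured center layout).
#' @param beta_params optional 2-column matrix (a, b) of per-probe Beta
#'   parameters, rows named by probe id, overriding the sampled regimes.
#' @return list with `beta` (probe x sample matrix), `detection_p` (same
#'   shape) and `params` (the Beta parameters used).
#' @export
simulate_methylation <- function(config, center = NULL, beta_params = NULL) {
  set.seed(sub_seed(config$seed, 2L))
  ids <- probe_ids(config)
  m <- config$n_probes
  if (is.null(center)) center <- rep(config$centers,
                                     times = config$n_per_center)
  n <- length(center)

  if (is.null(beta_params)) {
    regime <- sample(c("hypo", "hemi", "hyper"), m, replace = TRUE,
                     prob = c(0.3, 0.4, 0.3))
    mu <- ifelse(regime == "hypo", stats::runif(m, 0.15, 0.30),
          ifelse(regime == "hemi", stats::runif(m, 0.35, 0.65),
                 stats::runif(m, 0.70, 0.85)))
    phi <- stats::runif(m, 15, 60)
    # planted probes: mid-range, variably methylated (Beta(2,2), sd ~ 0.22)
    # -- only dispersed CpGs can carry a detectable interaction signal
    mu[1:3] <- 0.5
    phi[1:3] <- 4
    beta_params <- cbind(a = mu * phi, b = (1 - mu) * phi)
    rownames(beta_params) <- ids
  } else {
    beta_params <- as.matrix(beta_params)
    if (nrow(beta_params) != m) stop("beta_params must have one row per probe")
    if (is.null(rownames(beta_params))) rownames(beta_params) <- ids
    bad <- !is.finite(beta_params[, 1]) | !is.finite(beta_params[, 2]) |
      beta_params[, 1] <= 0 | beta_params[, 2] <= 0
    if (any(bad))
      stop("non-finite or non-positive Beta parameters for probe(s): ",
           paste(rownames(beta_params)[bad], collapse = ", "))
  }

  beta <- matrix(stats::rbeta(m * n, beta_params[, 1], beta_params[, 2]),
                 nrow = m, ncol = n)
  # guarantee the planted probes pass the CV >= 5% QC rule
  for (j in 1:3) {
    tries <- 0
    while (stats::sd(beta[j, ]) / mean(beta[j, ]) < 0.05 && tries < 100) {
      beta[j, ] <- stats::rbeta(n, beta_params[j, 1], beta_params[j, 2])
      tries <- tries + 1
    }
  }
  if (config$center_shift_sd > 0) {
    shift <- stats::rnorm(length(config$centers), 0, config$center_shift_sd)
    names(shift) <- config$centers
    beta <- beta + rep(shift[center], each = m)
    beta <- pmin(pmax(beta, 0), 1)
  }
  dimnames(beta) <- list(ids, sprintf("S%04d", seq_len(n)))

  det <- matrix(stats::runif(m * n, 0, 0.01), m, n, dimnames = dimnames(beta))
  if (config$detection_noise > 0) {
    fail <- stats::runif(m * n) < config$detection_noise
    det[fail] <- stats::runif(sum(fail), 0.06, 0.5)
  }
  list(beta = beta, detection_p = det, params = beta_params)
}

#' Simulate survival times from a planted interaction hazard model
#'
#' Event times are generated by inverse transform from a per-histology
#' exponential baseline hazard multiplied by `exp(lp)`, where the linear
#' predictor combines the configured covariate effects with the planted
#' factorial interaction coefficients (methylation on the 0-100 percent
#' scale, so planted coefficients are per 1 percentage point). The linear
#' predictor is mean-centred before exponentiation -- a constant shift is
#' absorbed by the baseline hazard, so the implied Cox model is unchanged.
#' Censoring is the minimum of the administrative horizon and an independent
#' exponential whose rate is calibrated so the expected censoring fraction
#' matches the configured target.
#'
#' @param config a `sim_config`.
#' @param covariates cohort data frame from [simulate_covariates()].
#' @param beta probe x sample beta matrix containing the planted probes.
#' @return data frame with `time` (> 0) and `event` (0/1) per sample.
#' @export
simulate_survival <- function(config, covariates, beta) {
  set.seed(sub_seed(config$seed, 3L))
  n <- nrow(covariates)
  planted <- config$planted_probe_ids
  if (!all(planted %in% rownames(beta)))
    stop("planted probes missing from beta matrix")

  covs <- intersect(c("age", "sex", "smoking_status", "stage", "center"),
                    names(covariates))
  X <- build_design(covariates, beta, exposure = "pack_years",
                    probes = planted, covariates = covs,
                    scheme = "full_factorial", value_scale = 100)
  coefs <- stats::setNames(numeric(ncol(X)), colnames(X))
  cc <- config$covariate_coefficients
  coefs[intersect(names(cc), names(coefs))] <-
    cc[intersect(names(cc), names(coefs))]
  pc <- config$planted_coefficients
  unknown <- setdiff(names(pc), names(coefs))
  if (length(unknown))
    stop("planted coefficient term(s) not in the factorial design: ",
         paste(unknown, collapse = ", "))
  coefs[names(pc)] <- pc

  lp <- drop(X %*% coefs)
  lp <- lp - mean(lp)
  if (any(abs(lp) > 50))
    stop("linear predictor overflow (|lp| > 50); rescale the planted ",
         "coefficients (methylation terms are per 1% on a 0-100 scale)")

  lambda0 <- config$baseline_hazards[covariates$histology]
  t_event <- stats::rexp(n) / (lambda0 * exp(lp))

  cens <- config$censoring
  horizon <- cens$horizon %||% Inf
  if (is.null(cens$target)) {
    c_time <- rep(horizon, n)
  } else {
    frac <- function(rho) mean(ifelse(t_event >= horizon, 1,
                                      1 - exp(-rho * t_event)))
    if (frac(0) >= cens$target) {
      rho <- 0
    } else {
      hi <- 1
      while (frac(hi) < cens$target && hi < 1e6) hi <- hi * 2
      rho <- stats::uniroot(function(r) frac(r) - cens$target,
                            c(0, hi))$root
    }
    c_time <- pmin(horizon,
                   if (rho > 0) stats::rexp(n, rho) else rep(Inf, n))
  }
  time <- pmin(t_event, c_time)
  data.frame(time = pmax(time, 1e-8), event = as.integer(t_event <= c_time))
}

#' Simulate an expression matrix cis-linked to planted probes
#'
#' Each planted probe gets one cis gene built as
#' `r * standardized(beta) + sqrt(1 - r^2) * noise`, plus independent noise
#' genes; every gene is standardized to mean 0, SD 1 (emulating log2-scale
#' standardized expression).
#'
#' @param config a `sim_config`.
#' @param beta probe x sample beta matrix.
#' @param cis_map optional data frame (probe, gene, r) overriding the default
#'   map of planted probes to genes `GENE_G1`, `GENE_G2`, `GENE_X` at
#'   correlation `config$cis_r`.
#' @return list with `expression` (gene x sample, standardized) and
#'   `cis_map`.
#' @export
simulate_expression <- function(config, beta, cis_map = NULL) {
  set.seed(sub_seed(config$seed, 4L))
  if (is.null(cis_map)) {
    cis_map <- data.frame(probe = config$planted_probe_ids,
                          gene = c("GENE_G1", "GENE_G2", "GENE_X"),
                          r = config$cis_r, stringsAsFactors = FALSE)
  }
  if (any(abs(cis_map$r) > 1)) stop("cis correlation |r| > 1 rejected")
  n <- ncol(beta)
  genes <- list()
  for (i in seq_len(nrow(cis_map))) {
    z <- as.numeric(scale(beta[cis_map$probe[i], ]))
    r <- cis_map$r[i]
    genes[[cis_map$gene[i]]] <- r * z + sqrt(1 - r^2) * stats::rnorm(n)
  }
  for (j in seq_len(config$n_null_genes)) {
    genes[[sprintf("gene_null%03d", j)]] <- stats::rnorm(n)
  }
  expr <- do.call(rbind, genes)
  expr <- t(scale(t(expr)))   # per-gene mean 0, sd 1
  attr(expr, "scaled:center") <- attr(expr, "scaled:scale") <- NULL
  colnames(expr) <- colnames(beta)
  list(expression = expr, cis_map = cis_map)
}

# Probe and gene annotation for the bundle: planted probes sit within 1 kb of
# their cis genes; all QC flags are clean by default.
simulate_annotation <- function(config, cis_map) {
  set.seed(sub_seed(config$seed, 5L))
  ids <- probe_ids(config)
  m <- length(ids)
  chrom <- paste0("chr", sample(1:22, m, replace = TRUE))
  pos <- sample.int(1e8, m)
  gene <- rep("", m)
  gene[1:3] <- cis_map$gene[match(ids[1:3], cis_map$probe)]
  annot <- data.frame(probe = ids, chrom = chrom, pos = pos, gene = gene,
                      snp_flag = FALSE, cross_reactive = FALSE,
                      stringsAsFactors = FALSE)
  cis_genes <- data.frame(chrom = chrom[1:3], start = pos[1:3] + 200,
                          end = pos[1:3] + 5200, gene = gene[1:3],
                          stringsAsFactors = FALSE)
  null_genes <- data.frame(
    chrom = paste0("chr", sample(1:22, config$n_null_genes, replace = TRUE)),
    start = sample.int(1e8, config$n_null_genes),
    gene = sprintf("gene_null%03d", seq_len(config$n_null_genes)),
    stringsAsFactors = FALSE)
  null_genes$end <- null_genes$start + 5000
  gene_annot <- rbind(cis_genes, null_genes[, c("chrom", "start", "end",
                                                "gene")])
  list(annotation = annot, gene_annotation = gene_annot)
}

#' Simulate a complete synthetic study bundle
#'
#' Orchestrates covariate, methylation, survival, expression and annotation
#' simulation into one aligned bundle. The seed fixes the whole output
#' bit-for-bit; every component uses its own sub-stream derived from the
#' global seed.
#'
#' @param config a `sim_config`.
#' @param expression logical: also simulate a cis-linked expression matrix.
#' @return object of class `synthetic_bundle`: `cohort` (covariates plus
#'   `time`/`event`), `beta`, `detection_p`, `expression` (or NULL),
#'   `annotation`, `gene_annotation`, `cis_map` and `truth` (the planted
#'   coefficient maps and the config).
#' @export
simulate_bundle <- function(config, expression = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  cov <- simulate_covariates(config)
  meth <- simulate_methylation(config)
  surv <- simulate_survival(config, cov, meth$beta)
  cohort <- cbind(cov, surv)
  expr <- NULL
  cis_map <- data.frame(probe = config$planted_probe_ids,
                        gene = c("GENE_G1", "GENE_G2", "GENE_X"),
                        r = config$cis_r, stringsAsFactors = FALSE)
  if (expression) {
    ex <- simulate_expression(config, meth$beta)
    expr <- ex$expression
    cis_map <- ex$cis_map
  }
  ann <- simulate_annotation(config, cis_map)
  out <- list(cohort = cohort, beta = meth$beta,
              detection_p = meth$detection_p, expression = expr,
              annotation = ann$annotation,
              gene_annotation = ann$gene_annotation,
              cis_map = cis_map,
              truth = list(planted_coefficients = config$planted_coefficients,
                           covariate_coefficients =
                             config$covariate_coefficients,
                           config = config))
  class(out) <- "synthetic_bundle"
  out
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("Synthetic study bundle:", ncol(x$beta), "samples,",
      nrow(x$beta), "probes\n")
  cat("events:", sum(x$cohort$event), "/", nrow(x$cohort),
      sprintf("(censoring %.3f)\n", 1 - mean(x$cohort$event)))
  if (!is.null(x$expression))
    cat("expression:", nrow(x$expression), "genes\n")
  np <- sum(x$truth$planted_coefficients != 0)
  cat("planted non-zero interaction coefficients:", np, "\n")
  invisible(x)
}
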