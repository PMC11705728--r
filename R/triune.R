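# TRIUNE: the integrated covariate + four-way interaction score (the fitted
# Cox model's linear predictor), its quartile subgroups, Kaplan-Meier and
# hazard-ratio comparisons, stratified forest analysis, and the conditional
# hazard-ratio surface of the highest-order interaction.

#' Compute the TRIUNE integrated risk score
#'
#' TRIUNE is the weighted linear combination of all clinical covariates and
#' all configured factorial interaction components, with weights from the
#' fitted interaction Cox model -- exactly the model's uncentered linear
#' predictor (no intercept, no baseline term). A covariate-only clinical
#' comparator score can be attached for benchmarking.
#'
#' Note that when scored on the same cohort the model was fitted to, weights
#' and groups are in-sample (circular); pass `newdata`/`values` for honest
#' out-of-sample scoring.
#'
#' @param fit a `cox_interaction` fit (the four-way model).
#' @param newdata,values optional cohort and feature matrix to score instead
#'   of the training data.
#' @param clinical_fit optional covariate-only `cox_interaction`/`cox_fit`
#'   used to add the `clinical_score` column.
#' @return data frame of class `risk_score`: `sample_id`, `triune`,
#'   optionally `clinical_score`, and `group` (quartile 1-4, 1 = lowest).
#' @export
compute_triune <- function(fit, newdata = NULL, values = NULL,
                           clinical_fit = NULL) {
  stopifnot(inherits(fit, "cox_interaction"))
  score <- predict(fit, newdata = newdata, values = values, type = "lp")
  ids <- if (is.null(newdata)) fit$sample_id else
    newdata$sample_id %||% rownames(newdata)
  out <- data.frame(sample_id = ids, triune = score,
                    stringsAsFactors = FALSE)
  if (!is.null(clinical_fit)) {
    out$clinical_score <- predict(clinical_fit, newdata = newdata,
                                  values = values, type = "lp")
  }
  out$group <- tryCatch(quartile_groups(out$triune), error = function(e) {
    warning("quartile groups unavailable: ", conditionMessage(e))
    rep(NA_integer_, nrow(out))
  })
  class(out) <- c("risk_score", "data.frame")
  out
}

#' Quartile group assignment
#'
#' Cutoffs at the empirical 25/50/75 percentiles; values equal to a cutoff go
#' to the lower group, so with `n` divisible by 4 and no ties the groups are
#' equal-sized. Group 1 is the lowest-risk quartile.
#'
#' @param scores numeric vector (>= 4 values, not all identical).
#' @return integer group labels 1-4.
#' @export
quartile_groups <- function(scores) {
  if (length(scores) < 4) stop("need at least 4 scores")
  if (length(unique(scores)) == 1L) stop("all scores identical")
  qs <- stats::quantile(scores, c(0.25, 0.5, 0.75), names = FALSE)
  1L + (scores > qs[1]) + (scores > qs[2]) + (scores > qs[3])
}

#' Kaplan-Meier curve with median survival
#'
#' Product-limit estimator; the median is the smallest time with
#' `S(t) <= 0.5` (absent if never reached), with its confidence interval from
#' the log-log-transformed curve bounds.
#'
#' @param times follow-up times (> 0).
#' @param events event indicators (0/1).
#' @param conf_level confidence level for the curve and median CI.
#' @return object of class `km_curve`: `time`, `surv`, `n_risk`, `lower`,
#'   `upper`, `median`, `median_ci`.
#' @export
km_curve <- function(times, events, conf_level = 0.95) {
  if (any(times <= 0)) stop("times must be > 0")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          conf.type = "log-log", conf.int = conf_level)
  med <- unname(stats::quantile(sf, probs = 0.5)$quantile)
  med_ci <- c(unname(stats::quantile(sf, probs = 0.5)$lower),
              unname(stats::quantile(sf, probs = 0.5)$upper))
  out <- list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
              n_event = sf$n.event, lower = sf$lower, upper = sf$upper,
              median = if (is.na(med)) NULL else med,
              median_ci = med_ci, n = length(times), nevent = sum(events))
  class(out) <- "km_curve"
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, ", events =", x$nevent, "\n")
  if (is.null(x$median)) {
    cat("median survival not reached\n")
  } else {
    cat(sprintf("median survival %.2f (95%% CI %.2f-%.2f)\n",
                x$median, x$median_ci[1], x$median_ci[2]))
  }
  invisible(x)
}

#' @export
plot.km_curve <- function(x, col = "black", add = FALSE,
                          xlab = "Years", ylab = "Survival probability",
                          ...) {
  t0 <- c(0, x$time)
  s0 <- c(1, x$surv)
  if (!add) {
    graphics::plot(t0, s0, type = "s", ylim = c(0, 1), col = col,
                   xlab = xlab, ylab = ylab, ...)
  } else {
    graphics::lines(t0, s0, type = "s", col = col, ...)
  }
  invisible(x)
}

#' Hazard ratios of risk-score groups versus Group 1
#'
#' Cox model with group indicators (reference Group 1); marginal
#' (covariate-free) by default, covariate-adjusted by flag.
#'
#' @param cohort cohort data frame with `time` and `event`.
#' @param groups integer group labels (1 = reference).
#' @param adjust logical: adjust for the clinical covariates.
#' @param covariates adjustment set used when `adjust = TRUE`.
#' @param strata_var optional stratification (used when `adjust = TRUE`).
#' @return data frame: group, n, events, hr, ci_low, ci_high, p; groups with
#'   zero events are flagged unstable.
#' @export
group_hazard_ratios <- function(cohort, groups, adjust = FALSE,
                                covariates = c("age", "sex",
                                               "smoking_status", "stage",
                                               "center"),
                                strata_var = "histology") {
  gf <- factor(groups)
  if (sum(cohort$event[gf == levels(gf)[1]]) < 1)
    stop("reference group must contain at least one event")
  cols <- list()
  for (lv in levels(gf)[-1]) cols[[paste0("group", lv)]] <-
      as.numeric(gf == lv)
  if (adjust) cols <- c(cols, covariate_columns(cohort, covariates))
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  fit <- fit_cox(cohort$time, cohort$event, X,
                 strata = if (adjust) cohort[[strata_var]] else NULL)
  idx <- paste0("group", levels(gf)[-1])
  ev <- tapply(cohort$event, gf, sum)
  out <- data.frame(
    group = levels(gf)[-1], reference = levels(gf)[1],
    n = as.vector(table(gf))[-1], events = as.vector(ev)[-1],
    hr = fit$hr[idx], ci_low = fit$ci_low[idx], ci_high = fit$ci_high[idx],
    p = fit$p[idx], row.names = NULL, stringsAsFactors = FALSE)
  out$unstable <- out$events == 0
  out
}

#' Stratified forest analysis of a risk score
#'
#' Within each level of each clinical factor, fits a Cox model of the score
#' on survival and reports the hazard ratio per 1 SD of the score (SD
#' computed once on the full sample, so strata are on a common scale).
#' Strata with fewer than `min_n` samples or `min_events` events are skipped
#' with a warning.
#'
#' @param cohort cohort data frame with `time` and `event`.
#' @param scores risk-score vector aligned with `cohort`.
#' @param strata_factors clinical factors to stratify on.
#' @param min_n,min_events minimum stratum size / event count.
#' @return data frame: factor, level, n, events, hr (per 1 SD), ci, p.
#' @export
stratified_forest <- function(cohort, scores,
                              strata_factors = c("sex", "smoking_status",
                                                 "stage", "histology",
                                                 "center"),
                              min_n = 10, min_events = 3) {
  z <- scores / stats::sd(scores)
  rows <- list()
  for (f in strata_factors) {
    if (!f %in% names(cohort)) next
    for (lv in unique(as.character(cohort[[f]]))) {
      idx <- cohort[[f]] == lv
      if (sum(idx) < min_n || sum(cohort$event[idx]) < min_events) {
        warning("stratum skipped (too small): ", f, " = ", lv)
        next
      }
      fit <- tryCatch(
        fit_cox(cohort$time[idx], cohort$event[idx],
                cbind(score_sd = z[idx])),
        error = function(e) NULL)
      if (is.null(fit)) next
      rows[[paste(f, lv)]] <- data.frame(
        factor = f, level = lv, n = sum(idx),
        events = sum(cohort$event[idx]),
        hr = fit$hr[["score_sd"]], ci_low = fit$ci_low[["score_sd"]],
        ci_high = fit$ci_high[["score_sd"]], p = fit$p[["score_sd"]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Conditional hazard-ratio surface of the highest-order probe
#'
#' The model-implied log hazard ratio of probe X per 1% methylation as a
#' function of the exposure E and the first probe G1, with the second probe
#' G2 fixed at the median of each of its two median-split subgroups:
#' `beta_4 + beta_14 E + beta_24 g1 + beta_34 g2 + beta_124 E g1
#'  + beta_134 E g2 + beta_234 g1 g2 + beta_1234 E g1 g2`
#' (the `beta_134` term only if present in the fitted scheme). Evaluating on
#' the two G2 subgroups reproduces the paired 3-D surface display.
#'
#' @param fit a four-way `cox_interaction` fit.
#' @param exposure_grid,g1_grid numeric grids (exposure units; percent scale
#'   for g1). Defaults span the observed data range.
#' @param g2_values the probe-2 values (percent scale) whose median split
#'   defines the two subgroups; defaults to the fitted design column.
#' @return data frame of class `effect_surface`: subgroup, g2_ref, exposure,
#'   g1, log_hr, hr.
#' @export
conditional_effect_surface <- function(fit, exposure_grid = NULL,
                                       g1_grid = NULL, g2_values = NULL) {
  stopifnot(inherits(fit, "cox_interaction"))
  sp <- fit$spec
  if (sp$k != 4) stop("surface requires a four-way fit (k = 4)")
  e_name <- sp$exposure
  g1 <- sp$probes[1]; g2 <- sp$probes[2]; x <- sp$probes[3]
  b <- function(lab) if (lab %in% fit$terms) fit$coefficients[[lab]] else 0
  lab <- function(...) paste(c(...), collapse = ":")

  if (is.null(exposure_grid))
    exposure_grid <- seq(min(fit$design[, e_name]),
                         max(fit$design[, e_name]), length.out = 25)
  if (is.null(g1_grid))
    g1_grid <- seq(min(fit$design[, g1]), max(fit$design[, g1]),
                   length.out = 25)
  if (is.null(g2_values)) g2_values <- fit$design[, g2]
  med <- stats::median(g2_values)
  sub_lo <- g2_values <= med
  g2_ref <- c(low = stats::median(g2_values[sub_lo]),
              high = stats::median(g2_values[!sub_lo]))

  rng_e <- range(fit$design[, e_name]); rng_g1 <- range(fit$design[, g1])
  if (any(exposure_grid < rng_e[1] | exposure_grid > rng_e[2]) ||
      any(g1_grid < rng_g1[1] | g1_grid > rng_g1[2]))
    warning("grid extends beyond the observed data range (extrapolation)")

  grid <- expand.grid(exposure = exposure_grid, g1 = g1_grid)
  out <- do.call(rbind, lapply(names(g2_ref), function(sg) {
    gv <- g2_ref[[sg]]
    log_hr <- b(x) +
      b(lab(e_name, x)) * grid$exposure +
      b(lab(g1, x)) * grid$g1 +
      b(lab(g2, x)) * gv +
      b(lab(e_name, g1, x)) * grid$exposure * grid$g1 +
      b(lab(e_name, g2, x)) * grid$exposure * gv +
      b(lab(g1, g2, x)) * grid$g1 * gv +
      b(lab(e_name, g1, g2, x)) * grid$exposure * grid$g1 * gv
    data.frame(subgroup = sg, g2_ref = gv, exposure = grid$exposure,
               g1 = grid$g1, log_hr = log_hr, hr = exp(log_hr),
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("effect_surface", "data.frame")
  out
}

#' @export
plot.effect_surface <- function(x, ...) {
  sgs <- unique(x$subgroup)
  op <- graphics::par(mfrow = c(1, length(sgs)))
  on.exit(graphics::par(op))
  for (sg in sgs) {
    d <- x[x$subgroup == sg, ]
    e <- sort(unique(d$exposure)); g <- sort(unique(d$g1))
    z <- matrix(d$hr[order(d$g1, d$exposure)], length(e), length(g))
    graphics::image(e, g, z, col = grDevices::hcl.colors(64, "RdBu",
                                                         rev = TRUE),
                    xlab = "Exposure (pack-years)",
                    ylab = "G1 methylation (%)",
                    main = paste0("HR of X per 1% (G2 ", sg, ")"), ...)
  }
  invisible(x)
}

#' Clinical covariate-only Cox model
#'
#' The comparator model behind the clinical score: the same stratified Cox
#' model with clinical covariates only (no exposure, no probes).
#'
#' @inheritParams cox_interaction
#' @return a `cox_interaction` fit with no interaction block.
#' @export
fit_clinical <- function(cohort,
                         covariates = c("age", "sex", "smoking_status",
                                        "stage", "center"),
                         strata_var = "histology",
                         time_var = "time", event_var = "event",
                         ties = c("efron", "breslow")) {
  cox_interaction(cohort, values = NULL, exposure = NULL,
                  probes = character(), covariates = covariates,
                  strata_var = strata_var, time_var = time_var,
                  event_var = event_var, ties = match.arg(ties))
}
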