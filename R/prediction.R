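# Discrimination evaluation for prognostic models: IPCW cumulative/dynamic
# time-dependent ROC/AUC with influence-function confidence intervals,
# paired AUC contrasts (exact DeLong when the horizon is uncensored, an
# iid-representation Wald contrast otherwise), Harrell's C-index, and the
# nested-model comparison (covariates / + three-way elements / + four-way
# elements).

# Kaplan-Meier of the censoring distribution; returns evaluators for
# G(t-) (left limit), G(t), plus the at-risk count Y(t) and the cumulative
# H(t) = sum_{censor times u <= t} d_u / Y(u)^2 used by the influence terms.
censoring_km <- function(times, events) {
  ut <- sort(unique(times))
  Y <- vapply(ut, function(u) sum(times >= u), numeric(1))
  dc <- vapply(ut, function(u) sum(times == u & events == 0), numeric(1))
  surv <- cumprod(1 - dc / Y)
  Hstep <- cumsum(dc / Y^2)
  G_at <- function(t) {
    i <- findInterval(t, ut)
    ifelse(i == 0, 1, surv[pmax(i, 1)])
  }
  G_minus <- function(t) {
    # product over u < t: use a shifted lookup
    i <- findInterval(t, ut, left.open = TRUE)   # u < t
    ifelse(i == 0, 1, surv[pmax(i, 1)])
  }
  H_at <- function(t) {
    i <- findInterval(t, ut)
    ifelse(i == 0, 0, Hstep[pmax(i, 1)])
  }
  H_minus <- function(t) {
    i <- findInterval(t, ut, left.open = TRUE)
    ifelse(i == 0, 0, Hstep[pmax(i, 1)])
  }
  Y_at <- function(t) {
    vapply(t, function(u) sum(times >= u), numeric(1))
  }
  list(G_at = G_at, G_minus = G_minus, H_at = H_at, H_minus = H_minus,
       Y_at = Y_at)
}

# concordance indicator matrix helper: for each case score, the count of
# controls scored strictly lower plus half the ties.
concordance_vs_controls <- function(case_scores, control_scores,
                                    control_w = NULL) {
  if (is.null(control_w)) control_w <- rep(1, length(control_scores))
  vapply(case_scores, function(s) {
    sum(control_w * ((s > control_scores) + 0.5 * (s == control_scores)))
  }, numeric(1))
}

#' IPCW time-dependent AUC
#'
#' Cumulative/dynamic time-dependent AUC at a horizon: cases are subjects
#' with an observed event by the horizon, controls those still at risk
#' beyond it; subjects censored before the horizon are weighted out by
#' inverse probability of censoring (Kaplan-Meier of the censoring
#' distribution on the pooled sample). The confidence interval comes from
#' the estimator's influence-function (iid) representation, including the
#' term for estimating the censoring distribution; with no censoring the
#' estimator reduces exactly to the Mann-Whitney AUC of the binary
#' event-by-horizon label.
#'
#' @param scores risk scores (higher = higher risk).
#' @param times follow-up times.
#' @param events event indicators (0/1).
#' @param horizon evaluation time (within follow-up range).
#' @param conf_level confidence level.
#' @return object of class `timed_auc`: `auc`, `se`, `ci`, `horizon`,
#'   `n_case`, `n_control`, `n`, and the per-subject influence values.
#' @export
timed_auc <- function(scores, times, events, horizon, conf_level = 0.95) {
  n <- length(scores)
  stopifnot(length(times) == n, length(events) == n)
  case <- times <= horizon & events == 1
  control <- times > horizon
  if (!any(case) || !any(control))
    stop("need at least one case and one control at the horizon")

  km <- censoring_km(times, events)
  Wd <- ifelse(case, 1 / km$G_minus(times), 0)
  Wn <- ifelse(control, 1 / km$G_at(horizon), 0)

  a <- numeric(n)     # a_i = (1/n) sum_j Wn_j c(s_i, s_j), cases only
  a[case] <- concordance_vs_controls(scores[case], scores[control],
                                     Wn[control]) / n
  b <- numeric(n)     # b_j = (1/n) sum_i Wd_i c(s_i, s_j), controls only
  b[control] <- vapply(scores[control], function(s) {
    sum(Wd[case] * ((scores[case] > s) + 0.5 * (scores[case] == s)))
  }, numeric(1)) / n

  theta <- sum(Wd * a) / n
  Fhat <- mean(Wd)
  Shat <- mean(Wn)
  auc <- theta / (Fhat * Shat)

  # --- influence-function variance ---------------------------------------
  # U-statistic part with the censoring distribution treated as known
  if0 <- Wd * a + Wn * b - 2 * theta
  # correction for estimating G: L_i(t) is the influence of -log G(t);
  # sums over cases' left limits are reduced to cumulative step lookups
  Yi <- km$Y_at(times)
  cens_i <- events == 0
  q_sum <- function(q) {
    # returns Sigma_i = sum_k q_k L_i(T_k-) / n for all i (cases k only)
    ct <- times[case]
    o <- order(ct)
    ct_s <- ct[o]
    q_s <- q[case][o]
    Hm <- km$H_minus(ct_s)
    tot <- sum(q_s)
    cq <- cumsum(q_s)
    cqH <- cumsum(q_s * Hm)
    idx <- findInterval(times, ct_s)                    # T_k <= T_i
    Qle <- ifelse(idx == 0, 0, cq[pmax(idx, 1)])
    QHle <- ifelse(idx == 0, 0, cqH[pmax(idx, 1)])
    Qgt <- tot - Qle
    (cens_i / Yi) * Qgt - (QHle + km$H_at(times) * Qgt)
  }
  L_tau <- n * ((times <= horizon & cens_i) / Yi -
                  km$H_at(pmin(horizon, times)))
  if_theta <- if0 + q_sum(Wd * a) + theta * L_tau
  if_F <- Wd - Fhat + q_sum(Wd)
  if_S <- Wn - Shat + Shat * L_tau
  iid <- (if_theta - auc * (Shat * if_F + Fhat * if_S)) / (Fhat * Shat)
  se <- sqrt(sum(iid^2)) / n

  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- list(auc = auc, se = se,
              ci = c(max(0, auc - zq * se), min(1, auc + zq * se)),
              horizon = horizon, n_case = sum(case),
              n_control = sum(control), n = n,
              estimator = "IPCW cumulative/dynamic (pooled KM weights)",
              iid = iid)
  class(out) <- "timed_auc"
  out
}

#' @export
print.timed_auc <- function(x, ...) {
  cat(sprintf(
    "%.0f-unit horizon AUC = %.3f (95%% CI %.3f-%.3f); %d cases / %d controls of %d\n",
    x$horizon, x$auc, x$ci[1], x$ci[2], x$n_case, x$n_control, x$n))
  invisible(x)
}

# DeLong structural components for one score vector on binary labels
delong_components <- function(scores, labels) {
  xs <- scores[labels == 1]
  ys <- scores[labels == 0]
  v10 <- vapply(xs, function(x)
    mean((x > ys) + 0.5 * (x == ys)), numeric(1))
  v01 <- vapply(ys, function(y)
    mean((xs > y) + 0.5 * (xs == y)), numeric(1))
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' DeLong test for two correlated ROC curves
#'
#' Paired contrast of two AUCs on the same binary labels using DeLong's
#' structural-component variance.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels binary outcome labels (0/1).
#' @return list with `auc_a`, `auc_b`, `delta`, `se`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  m <- sum(labels == 1)
  nn <- sum(labels == 0)
  var_d <- stats::var(ca$v10 - cb$v10) / m + stats::var(ca$v01 - cb$v01) / nn
  delta <- ca$auc - cb$auc
  z <- if (var_d == 0) 0 else delta / sqrt(var_d)
  list(auc_a = ca$auc, auc_b = cb$auc, delta = delta,
       se = sqrt(var_d), z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare the time-dependent AUCs of two nested models
#'
#' Paired contrast of two models' horizon AUCs on the same samples. When no
#' subject is censored at or before the horizon the problem reduces exactly
#' to correlated binary-label ROC curves and DeLong's test is applied;
#' otherwise a Wald test on the AUC difference uses the joint
#' influence-function variance of the two IPCW estimators (the method used
#' is labeled in the output). The relative increase is
#' `100 * (AUC_big - AUC_small) / AUC_small`.
#'
#' @param scores_small,scores_big score vectors of the nested models.
#' @param times,events survival outcome shared by both models.
#' @param horizon evaluation time.
#' @return list with both AUCs, `delta_auc`, `relative_increase_pct`, `p`,
#'   and `method`.
#' @export
compare_auc <- function(scores_small, scores_big, times, events, horizon) {
  stopifnot(length(scores_small) == length(scores_big))
  uncensored_horizon <- !any(times <= horizon & events == 0)
  auc_s <- timed_auc(scores_small, times, events, horizon)
  auc_b <- timed_auc(scores_big, times, events, horizon)
  if (uncensored_horizon) {
    labels <- as.integer(times <= horizon)
    dl <- delong_test(scores_big, scores_small, labels)
    p <- dl$p
    method <- "DeLong (horizon fully observed)"
  } else {
    dif <- auc_b$iid - auc_s$iid
    se <- sqrt(sum(dif^2)) / length(times)
    z <- if (se == 0) 0 else (auc_b$auc - auc_s$auc) / se
    p <- 2 * stats::pnorm(-abs(z))
    method <- "iid-representation Wald contrast (IPCW)"
  }
  list(auc_small = auc_s$auc, auc_big = auc_b$auc,
       delta_auc = auc_b$auc - auc_s$auc,
       relative_increase_pct =
         100 * (auc_b$auc - auc_s$auc) / auc_s$auc,
       p = p, method = method, horizon = horizon)
}

#' Harrell's concordance index
#'
#' Probability that of two orderable subjects the one with the shorter
#' survival carries the higher risk score: concordant pairs plus half-credit
#' score ties over usable pairs (pairs with tied observed times are not
#' usable). Computed via the concordance machinery of the survival package.
#'
#' @param scores risk scores (higher = higher risk).
#' @param times,events survival outcome.
#' @param symmetric if TRUE report `max(c, 1 - c)` (the 0.5-1 convention);
#'   default is the raw c.
#' @return concordance value.
#' @export
c_index <- function(scores, times, events, symmetric = FALSE) {
  fit <- survival::concordance(survival::Surv(times, events) ~ scores,
                               reverse = TRUE)
  ct <- fit$count
  usable <- ct[["concordant"]] + ct[["discordant"]] + ct[["tied.x"]]
  if (usable == 0) stop("no usable pairs")
  c_raw <- (ct[["concordant"]] + 0.5 * ct[["tied.x"]]) / usable
  if (symmetric) max(c_raw, 1 - c_raw) else c_raw
}

#' Nested prognostic-model comparison
#'
#' Fits the three nested histology-stratified Cox models -- (a) clinical
#' covariates only; (b) covariates plus all elements of the three-way
#' interaction (exposure and the first two probes, full factorial); (c)
#' covariates plus all elements of the four-way interaction -- scores each
#' sample with each linear predictor, and evaluates horizon AUCs, pairwise
#' AUC contrasts and the C-index per model.
#'
#' @inheritParams cox_interaction
#' @param probes the three winner probes (G1, G2, X).
#' @param horizons evaluation horizons in years (default 3 and 5).
#' @return object of class `model_comparison`: `auc` (model x horizon table
#'   with CIs), `contrasts` (pairwise DeLong/Wald results), `c_index`, and
#'   the three fits.
#' @export
nested_models <- function(cohort, values, probes, exposure = "pack_years",
                          covariates = c("age", "sex", "smoking_status",
                                         "stage", "center"),
                          strata_var = "histology", horizons = c(3, 5),
                          ...) {
  stopifnot(length(probes) == 3)
  fits <- list(
    a_covariates = fit_clinical(cohort, covariates = covariates,
                                strata_var = strata_var),
    b_threeway = cox_interaction(cohort, values, exposure = exposure,
                                 probes = probes[1:2],
                                 covariates = covariates,
                                 strata_var = strata_var, ...),
    c_fourway = cox_interaction(cohort, values, exposure = exposure,
                                probes = probes, covariates = covariates,
                                strata_var = strata_var, ...))
  scores <- lapply(fits, function(f) f$linear_predictor)
  tm <- cohort$time
  ev <- cohort$event

  auc_rows <- list()
  for (mod in names(fits)) {
    for (h in horizons) {
      ta <- timed_auc(scores[[mod]], tm, ev, h)
      auc_rows[[paste(mod, h)]] <- data.frame(
        model = mod, horizon = h, auc = ta$auc, se = ta$se,
        ci_low = ta$ci[1], ci_high = ta$ci[2],
        stringsAsFactors = FALSE)
    }
  }
  auc_tab <- do.call(rbind, c(auc_rows, list(make.row.names = FALSE)))

  pairs <- list(c("a_covariates", "b_threeway"),
                c("b_threeway", "c_fourway"),
                c("a_covariates", "c_fourway"))
  ct_rows <- list()
  for (pr in pairs) {
    for (h in horizons) {
      cmp <- compare_auc(scores[[pr[1]]], scores[[pr[2]]], tm, ev, h)
      ct_rows[[paste(pr[1], pr[2], h)]] <- data.frame(
        smaller = pr[1], larger = pr[2], horizon = h,
        auc_small = cmp$auc_small, auc_big = cmp$auc_big,
        delta_auc = cmp$delta_auc,
        relative_increase_pct = cmp$relative_increase_pct,
        p = cmp$p, method = cmp$method, stringsAsFactors = FALSE)
    }
  }
  contrasts <- do.call(rbind, c(ct_rows, list(make.row.names = FALSE)))

  cidx <- vapply(scores, function(s) c_index(s, tm, ev), numeric(1))
  out <- list(auc = auc_tab, contrasts = contrasts,
              c_index = data.frame(model = names(cidx), c_index = cidx,
                                   row.names = NULL),
              fits = fits, horizons = horizons)
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Nested prognostic model comparison\n")
  cat("\nTime-dependent AUC:\n")
  print(x$auc, digits = 3)
  cat("\nAUC contrasts:\n")
  print(x$contrasts[, c("smaller", "larger", "horizon", "delta_auc",
                        "relative_increase_pct", "p")], digits = 3)
  cat("\nC-index:\n")
  print(x$c_index, digits = 3)
  invisible(x)
}

#' Time-dependent ROC curve points
#'
#' IPCW-weighted TPR/FPR over the score thresholds at one horizon (one row
#' per observed threshold), for plotting or export.
#'
#' @inheritParams timed_auc
#' @return data frame: threshold, tpr, fpr, horizon.
#' @export
timed_roc <- function(scores, times, events, horizon) {
  case <- times <= horizon & events == 1
  control <- times > horizon
  if (!any(case) || !any(control))
    stop("need at least one case and one control at the horizon")
  km <- censoring_km(times, events)
  wd <- ifelse(case, 1 / km$G_minus(times), 0)
  wn <- ifelse(control, 1, 0)   # common weight cancels
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(wd[scores >= t]) / sum(wd), numeric(1))
  fpr <- vapply(th, function(t) sum(wn[scores >= t]) / sum(wn), numeric(1))
  data.frame(threshold = th, tpr = tpr, fpr = fpr, horizon = horizon)
}
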