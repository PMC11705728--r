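# Hill-climbing epigenome-wide interaction scan with Benjamini-Hochberg FDR
# and the discovery/validation two-phase decision rule.

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR q-values: `q_(i) = min_{j >= i} p_(j) * m / j`, clipped at 1,
#' ties sharing the adjusted value, original order restored. Missing p-values
#' are skipped (they do not count towards `m`) and stay missing, matching the
#' scan's treatment of non-converged fits.
#'
#' @param p numeric vector of p-values in `[0,1]`, `NA` allowed.
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Epigenome-wide order-k interaction scan
#'
#' For each candidate probe X, fits the order-k interaction Cox model on
#' `{exposure} u fixed_probes u {X}` (full factorial expansion, clinical
#' covariates, histology-stratified) and records the Wald statistics of the
#' highest-order term. Non-converged or singular candidate fits are recorded
#' with missing p and excluded from the FDR adjustment (count logged in the
#' attributes). One base design is assembled per scan; only the columns
#' involving the candidate slot are refilled per probe, so an
#' epigenome-sized candidate set is feasible.
#'
#' @inheritParams cox_interaction
#' @param beta probe x sample beta matrix (QC-passed).
#' @param fixed_probes probes occupying the fixed interaction slots (the
#'   validated order-(k-1) winners); may be empty for a two-way G x E scan.
#' @param candidates candidate probe ids; default all rows of `beta` minus
#'   the fixed probes.
#' @return a `scan_table` data frame: probe, beta, se, hr, ci_low, ci_high,
#'   p, q, rank; attributes `k`, `fixed_probes`, `exposure`, `n_tested`,
#'   `n_failed`.
#' @export
scan_order_k <- function(cohort, beta, exposure = "pack_years",
                         fixed_probes = character(), candidates = NULL,
                         covariates = c("age", "sex", "smoking_status",
                                        "stage", "center"),
                         strata_var = "histology",
                         time_var = "time", event_var = "event",
                         scheme = c("full_factorial", "as_printed"),
                         value_scale = 100,
                         ties = c("efron", "breslow")) {
  scheme <- match.arg(scheme)
  ties <- match.arg(ties)
  if (is.null(candidates))
    candidates <- setdiff(rownames(beta), fixed_probes)
  if (!length(candidates)) stop("empty candidate set")
  miss <- setdiff(c(fixed_probes, candidates), rownames(beta))
  if (length(miss))
    stop("probe(s) absent from beta matrix: ", paste(miss, collapse = ", "))
  ex <- cohort[[exposure]]
  if (is.null(ex)) stop("exposure '", exposure, "' not found in cohort")
  if (stats::sd(ex, na.rm = TRUE) == 0) stop("exposure is constant")

  k <- length(fixed_probes) + 2L
  vars <- c(exposure, fixed_probes, "..X..")

  # complete cases over covariates, survival, exposure and fixed probes
  need <- intersect(c(time_var, event_var, strata_var, exposure, covariates),
                    names(cohort))
  cc <- stats::complete.cases(cohort[, need, drop = FALSE])
  if (length(fixed_probes))
    cc <- cc & stats::complete.cases(t(beta[fixed_probes, , drop = FALSE]))
  cohort <- cohort[cc, , drop = FALSE]
  beta_cc <- beta[, cc, drop = FALSE]

  cov_cols <- covariate_columns(cohort, covariates)
  fixed_vals <- cbind(as.numeric(cohort[[exposure]]),
                      if (length(fixed_probes))
                        t(beta_cc[fixed_probes, , drop = FALSE]) * value_scale)
  subsets <- term_subsets(k, scheme)
  labs <- vapply(subsets, function(s) paste(vars[s], collapse = ":"),
                 character(1))
  has_x <- vapply(subsets, function(s) k %in% s, logical(1))

  n <- nrow(cohort)
  X <- matrix(0, n, length(cov_cols) + length(subsets))
  colnames(X) <- c(names(cov_cols), labs)
  for (j in seq_along(cov_cols)) X[, j] <- cov_cols[[j]]
  off <- length(cov_cols)
  # fixed (candidate-free) terms, and the candidate-free part of X-terms
  prefix <- vector("list", length(subsets))
  for (t in seq_along(subsets)) {
    s <- subsets[[t]]
    s_fixed <- setdiff(s, k)
    col <- rep(1, n)
    for (j in s_fixed) col <- col * fixed_vals[, j]
    if (has_x[t]) prefix[[t]] <- col else X[, off + t] <- col
  }
  x_cols <- off + which(has_x)
  top <- length(cov_cols) + length(subsets)   # highest-order term column

  strat <- as.integer(factor(cohort[[strata_var]]))
  y <- survival::Surv(cohort[[time_var]], cohort[[event_var]])
  ctl <- survival::coxph.control(iter.max = 100, eps = 1e-9)

  nc <- length(candidates)
  est <- se <- p <- rep(NA_real_, nc)
  conv <- rep(FALSE, nc)
  cand_mat <- beta_cc[candidates, , drop = FALSE] * value_scale
  for (i in seq_len(nc)) {
    xv <- cand_mat[i, ]
    if (anyNA(xv)) next
    for (t in which(has_x)) X[, off + t] <- prefix[[t]] * xv
    scl <- apply(X, 2, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    fit <- tryCatch(
      survival::coxph.fit(sweep(X, 2, scl, "/"), y, strata = strat,
                          offset = NULL, init = NULL, control = ctl,
                          weights = NULL, method = ties, rownames = NULL),
      error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) next
    b <- fit$coefficients[top] / scl[top]
    s <- sqrt(fit$var[top, top]) / scl[top]
    if (!is.finite(b) || !is.finite(s) || s == 0) next
    if (fit$iter >= ctl$iter.max || abs(fit$coefficients[top]) > 20) next
    est[i] <- b; se[i] <- s
    p[i] <- 2 * stats::pnorm(-abs(b / s))
    conv[i] <- TRUE
  }

  q <- bh_adjust(p)
  out <- data.frame(probe = candidates, beta = est, se = se,
                    hr = exp(est), ci_low = exp(est - 1.96 * se),
                    ci_high = exp(est + 1.96 * se),
                    p = p, q = q, converged = conv,
                    stringsAsFactors = FALSE)
  out$rank <- rank(out$p, ties.method = "first", na.last = "keep")
  attr(out, "k") <- k
  attr(out, "fixed_probes") <- fixed_probes
  attr(out, "exposure") <- exposure
  attr(out, "scheme") <- scheme
  attr(out, "n_tested") <- sum(conv)
  attr(out, "n_failed") <- sum(!conv)
  class(out) <- c("scan_table", "data.frame")
  out
}

#' @export
print.scan_table <- function(x, n = 10, ...) {
  cat("Order-", attr(x, "k"), " interaction scan: ", nrow(x),
      " candidates, ", attr(x, "n_tested"), " tested (",
      attr(x, "n_failed"), " failed fits)\n", sep = "")
  cat("fixed:", attr(x, "exposure"),
      if (length(attr(x, "fixed_probes")))
        paste("+", paste(attr(x, "fixed_probes"), collapse = ", ")), "\n")
  top <- x[order(x$p), ][seq_len(min(n, nrow(x))), ]
  print.data.frame(top, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Two-phase discovery/validation decision
#'
#' A candidate passes when its discovery FDR q is at most `alpha_q`, its
#' validation p is at most `alpha_p`, and the interaction coefficients have
#' the same sign in both phases. Probes absent from the validation scan are
#' recorded as untestable (never passed). Passers are optionally re-fit on a
#' pooled cohort.
#'
#' @param discovery,validation `scan_table`s from [scan_order_k()] on the
#'   two disjoint cohorts (same exposure, fixed probes and term scheme).
#' @param alpha_q discovery FDR threshold (default 0.05).
#' @param alpha_p validation p threshold (default 0.05).
#' @param combined optional list with `cohort` and `beta` of the pooled
#'   cohort (distinct `center` labels per phase; the validation cohort
#'   enters as its own center) for the combined re-fit of passers.
#' @param ... passed to [cox_interaction()] for combined re-fits.
#' @return data frame of decisions: per probe the discovery (beta, p, q) and
#'   validation (beta, p) statistics, direction consistency, pass flag, and
#'   combined (beta, hr, ci, p) for passers.
#' @export
two_phase_decide <- function(discovery, validation, alpha_q = 0.05,
                             alpha_p = 0.05, combined = NULL, ...) {
  hits <- discovery[!is.na(discovery$q) & discovery$q <= alpha_q, ]
  if (!nrow(hits)) {
    out <- data.frame(probe = character(0))
    class(out) <- c("two_phase_decision", "data.frame")
    return(out)
  }
  vi <- match(hits$probe, validation$probe)
  out <- data.frame(
    probe = hits$probe,
    beta_disc = hits$beta, p_disc = hits$p, q_disc = hits$q,
    beta_valid = validation$beta[vi], p_valid = validation$p[vi],
    stringsAsFactors = FALSE)
  out$untestable <- is.na(vi) | is.na(out$p_valid)
  out$direction_consistent <- !out$untestable &
    sign(out$beta_disc) == sign(out$beta_valid)
  out$pass <- !out$untestable & out$p_valid <= alpha_p &
    out$direction_consistent

  out$beta_comb <- out$hr_comb <- out$ci_low_comb <- out$ci_high_comb <-
    out$p_comb <- NA_real_
  if (!is.null(combined) && any(out$pass)) {
    fixed <- attr(discovery, "fixed_probes")
    exposure <- attr(discovery, "exposure")
    scheme <- attr(discovery, "scheme") %||% "full_factorial"
    for (i in which(out$pass)) {
      fit <- tryCatch(
        cox_interaction(combined$cohort, combined$beta, exposure = exposure,
                        probes = c(fixed, out$probe[i]), scheme = scheme,
                        ...),
        error = function(e) NULL)
      if (is.null(fit)) next
      w <- wald_interaction_test(fit)
      out$beta_comb[i] <- w$estimate
      out$hr_comb[i] <- w$hr
      out$ci_low_comb[i] <- w$ci_low
      out$ci_high_comb[i] <- w$ci_high
      out$p_comb[i] <- w$p
    }
  }
  class(out) <- c("two_phase_decision", "data.frame")
  out
}

#' @export
print.two_phase_decision <- function(x, ...) {
  cat("Two-phase decisions:", nrow(x), "discovery hits,",
      if (nrow(x)) sum(x$pass) else 0, "validated\n")
  if (nrow(x)) print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Hill-climbing escalation from low- to high-order interactions
#'
#' Greedy search: starting from the fixed winner set (possibly empty),
#' iterate k = 2..`max_order`; at each order, scan all candidate probes for
#' the added slot in the discovery cohort, re-test the discovery FDR hits in
#' the validation cohort, and append the two-phase passer with the smallest
#' discovery p to the winner set. The search stops early at the first order
#' with no passer.
#'
#' @param cohort_disc,beta_disc discovery cohort and beta matrix.
#' @param cohort_valid,beta_valid validation cohort and beta matrix.
#' @param exposure environmental exposure variable name.
#' @param max_order largest interaction order to attempt (>= 2).
#' @param fixed_probes pre-specified winners occupying the first slots
#'   (scanning then starts at order `length(fixed_probes) + 2`).
#' @param alpha_q,alpha_p two-phase thresholds.
#' @param ... passed to [scan_order_k()].
#' @return list with `winners` (ordered probe ids), `scans` (per-order
#'   discovery `scan_table`s), `decisions` (per-order two-phase tables).
#' @export
hill_climb <- function(cohort_disc, beta_disc, cohort_valid, beta_valid,
                       exposure = "pack_years", max_order = 4,
                       fixed_probes = character(),
                       alpha_q = 0.05, alpha_p = 0.05, ...) {
  if (max_order < 2) stop("max_order must be >= 2")
  winners <- fixed_probes
  scans <- list()
  decisions <- list()
  shared <- intersect(rownames(beta_disc), rownames(beta_valid))
  for (k in seq(length(fixed_probes) + 2L, max_order)) {
    cand <- setdiff(shared, winners)
    disc <- scan_order_k(cohort_disc, beta_disc, exposure = exposure,
                         fixed_probes = winners, candidates = cand, ...)
    key <- paste0("order", k)
    scans[[key]] <- disc
    hits <- disc$probe[!is.na(disc$q) & disc$q <= alpha_q]
    if (!length(hits)) {
      decisions[[key]] <- two_phase_decide(disc, disc[0, ], alpha_q, alpha_p)
      break
    }
    valid <- scan_order_k(cohort_valid, beta_valid, exposure = exposure,
                          fixed_probes = winners, candidates = hits, ...)
    dec <- two_phase_decide(disc, valid, alpha_q = alpha_q,
                            alpha_p = alpha_p)
    decisions[[key]] <- dec
    passers <- dec[dec$pass, ]
    if (!nrow(passers)) break
    winners <- c(winners, passers$probe[which.min(passers$p_disc)])
  }
  list(winners = setdiff(winners, fixed_probes), fixed_probes = fixed_probes,
       scans = scans, decisions = decisions)
}
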