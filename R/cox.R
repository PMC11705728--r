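#' Enumerate the factorial interaction terms of a model specification
#'
#' Builds the ordered list of design terms for an order-`k` gene-environment
#' interaction model with `k = length(probes) + 1` interacting variables (the
#' smoking exposure plus the methylation probes, in that fixed order).
#'
#' Two term schemes are supported. `"full_factorial"` expands all `2^k - 1`
#' products of non-empty subsets of the interacting variables, which respects
#' the interaction hierarchy and is the default used by the scan.
#' `"as_printed"` (defined for `k = 4` only) reproduces the 14-term integrated
#' score formula in which the exposure x probe2 x probe3 triple is absent.
#'
#' Terms are ordered deterministically: main effects first, then interactions
#' of ascending order, lexicographically by variable position within an order.
#'
#' @param exposure name of the environmental exposure variable (pack-years).
#' @param probes character vector of probe (or gene) identifiers entering the
#'   interaction, in scan order; must not contain `exposure`.
#' @param scheme `"full_factorial"` or `"as_printed"`.
#' @return character vector of term labels, components joined by `":"`.
#' @examples
#' expand_terms("pack_years", c("cgA", "cgB", "cgC"))          # 15 terms
#' expand_terms("pack_years", c("cgA", "cgB", "cgC"), "as_printed")
#' @export
expand_terms <- function(exposure, probes,
                         scheme = c("full_factorial", "as_printed")) {
  scheme <- match.arg(scheme)
  vars <- c(exposure, probes)
  if (anyDuplicated(vars))
    stop("duplicate variable names among exposure and probes")
  k <- length(vars)
  if (k < 2) stop("need at least two interacting variables (k >= 2)")
  subsets <- term_subsets(k, scheme)
  vapply(subsets, function(s) paste(vars[s], collapse = ":"), character(1))
}

# Subsets of 1..k defining the factorial terms, ordered by size then
# lexicographically by position.  as_printed (k = 4) drops {1,3,4}: the
# exposure x probe2 x probe3 triple is missing from the printed score formula.
term_subsets <- function(k, scheme = "full_factorial") {
  out <- list()
  for (size in seq_len(k)) {
    cmb <- utils::combn(k, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  if (scheme == "as_printed") {
    if (k != 4)
      stop("scheme 'as_printed' is defined only for four-way models (k = 4)")
    out <- Filter(function(s) !identical(s, c(1L, 3L, 4L)), out)
  }
  out
}

# Reference level orders for the standard clinical covariates.
cov_factor_levels <- function(name, x) {
  preset <- switch(name,
    sex            = c("F", "M"),
    smoking_status = c("never", "ever", "current"),
    stage          = c("I", "II"),
    NULL)
  if (!is.null(preset) && all(unique(as.character(x)) %in% preset)) {
    preset
  } else if (is.factor(x)) {
    levels(x)
  } else {
    sort(unique(as.character(x)))
  }
}

# Expand the clinical covariates into numeric design columns
# (reference-coded indicators for factors; numeric columns as-is).
# Factors with a single observed level contribute no columns.
covariate_columns <- function(cohort, covariates) {
  cols <- list()
  for (v in covariates) {
    x <- cohort[[v]]
    if (is.null(x)) stop("covariate '", v, "' not found in cohort")
    if (is.numeric(x)) {
      cols[[v]] <- as.numeric(x)
    } else {
      f <- droplevels(factor(x, levels = cov_factor_levels(v, x)))
      if (nlevels(f) >= 2L) {
        for (lv in levels(f)[-1L]) {
          cols[[paste0(v, lv)]] <- as.numeric(f == lv)
        }
      }
    }
  }
  cols
}

#' Build the design matrix for an interaction Cox model
#'
#' Assembles reference-coded covariate columns followed by the factorial
#' interaction terms of [expand_terms()]. Methylation probe values (given as
#' proportions in `[0,1]`) enter on the 0-100 percent scale, so hazard ratios
#' of methylation terms are per 1 percentage point; expression or other
#' pre-scaled features can be passed with `value_scale = 1`.
#'
#' @param cohort data frame with the clinical covariates and the exposure.
#' @param values numeric feature-by-sample matrix (rows named by feature id)
#'   supplying the probe columns, aligned with `cohort` rows.
#' @param exposure name of the exposure column in `cohort`.
#' @param probes feature ids (rows of `values`) entering the interaction.
#' @param covariates clinical adjustment variables.
#' @param scheme term scheme, see [expand_terms()].
#' @param value_scale multiplier applied to `values` rows before products
#'   (100 for beta values, 1 for standardized expression).
#' @return numeric design matrix; attributes `interaction_terms` (labels of
#'   the factorial block) and `highest_term` (the order-k product term).
#' @export
build_design <- function(cohort, values = NULL, exposure, probes = character(),
                         covariates = c("age", "sex", "smoking_status",
                                        "stage", "center"),
                         scheme = c("full_factorial", "as_printed"),
                         value_scale = 100) {
  scheme <- match.arg(scheme)
  n <- nrow(cohort)
  cols <- covariate_columns(cohort, covariates)

  int_terms <- character(0)
  if (length(probes)) {
    if (is.null(values)) stop("probes given but no values matrix supplied")
    missing_p <- setdiff(probes, rownames(values))
    if (length(missing_p))
      stop("probes not found in values matrix: ",
           paste(missing_p, collapse = ", "))
    vars <- c(exposure, probes)
    vmat <- cbind(as.numeric(cohort[[exposure]]),
                  t(values[probes, , drop = FALSE]) * value_scale)
    subsets <- term_subsets(length(vars), scheme)
    for (s in subsets) {
      lab <- paste(vars[s], collapse = ":")
      col <- vmat[, s[1]]
      for (j in s[-1]) col <- col * vmat[, j]
      cols[[lab]] <- col
      int_terms <- c(int_terms, lab)
    }
  } else if (!is.null(exposure) && exposure %in% names(cohort) &&
             !exposure %in% covariates) {
    # exposure-only model (no probes): include the exposure main effect
    cols[[exposure]] <- as.numeric(cohort[[exposure]])
  }

  X <- do.call(cbind, cols)
  if (is.null(X)) stop("empty design: no usable covariates or terms")
  colnames(X) <- names(cols)
  rownames(X) <- NULL
  stopifnot(nrow(X) == n)
  attr(X, "interaction_terms") <- int_terms
  attr(X, "highest_term") <- if (length(int_terms))
    int_terms[length(int_terms)] else NA_character_
  X
}

#' Fit a stratified Cox proportional-hazards model
#'
#' Maximizes the stratified partial likelihood (sum of per-stratum log partial
#' likelihoods) for a prepared numeric design matrix, with Efron tie handling
#' by default. The covariance is the inverse observed information. Design
#' columns are standardized to unit standard deviation internally for
#' numerical stability and the coefficients and covariance rescaled back, so
#' reported effects are on the original column scale (exactly: scaling a
#' column by `c` divides its coefficient by `c`).
#'
#' @param time follow-up times (> 0).
#' @param event event indicators (0/1).
#' @param design numeric design matrix with named columns.
#' @param strata optional stratification factor (e.g. histology).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param iter_max maximum Newton iterations.
#' @return an object of class `cox_fit`: coefficients, standard errors,
#'   covariance, per-term Wald z and p, hazard ratios with 95% CIs
#'   (`exp(beta +/- 1.96 se)`), log partial likelihood, convergence flags,
#'   and the (uncentered) linear predictor `design %*% beta`.
#' @examples
#' d <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0), x = c(1, 0, 1))
#' f <- fit_cox(d$time, d$event, cbind(x = d$x))
#' coef(f)  # -log(2)/2
#' @export
fit_cox <- function(time, event, design, strata = NULL,
                    ties = c("efron", "breslow"), iter_max = 100L) {
  ties <- match.arg(ties)
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  n <- length(time)
  if (nrow(design) != n || length(event) != n)
    stop("time, event and design dimensions disagree")
  if (any(!is.finite(time)) || any(time <= 0)) stop("times must be finite and > 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (any(!is.finite(design)))
    stop("non-finite values in design column(s): ",
         paste(colnames(design)[colSums(!is.finite(design)) > 0],
               collapse = ", "))
  if (is.null(strata)) strata <- rep(1L, n)
  sfac <- factor(strata)
  ev_by_stratum <- tapply(event, sfac, sum)
  if (any(ev_by_stratum == 0))
    warning("stratum with no events: ",
            paste(names(ev_by_stratum)[ev_by_stratum == 0], collapse = ", "))

  # internal column standardization (see Details)
  scl <- apply(design, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- sweep(design, 2, scl, "/")

  ctl <- survival::coxph.control(iter.max = iter_max, eps = 1e-9)
  fit <- survival::coxph.fit(Xs, survival::Surv(time, event),
                             strata = as.integer(sfac), offset = NULL,
                             init = NULL, control = ctl, weights = NULL,
                             method = ties, rownames = NULL)
  beta_s <- fit$coefficients
  if (anyNA(beta_s))
    stop("singular design; collinear or constant term(s): ",
         paste(colnames(design)[is.na(beta_s)], collapse = ", "))
  beta <- beta_s / scl
  V <- fit$var / tcrossprod(scl)
  dimnames(V) <- list(colnames(design), colnames(design))
  se <- sqrt(pmax(diag(V), 0))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  names(beta) <- names(se) <- names(z) <- names(p) <- colnames(design)

  monotone <- any(abs(beta_s) > 20)
  converged <- fit$iter < iter_max && !monotone

  out <- list(
    terms = colnames(design),
    coefficients = beta,
    se = se,
    var = V,
    z = z,
    p = p,
    hr = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    loglik = fit$loglik[2],
    loglik_null = fit$loglik[1],
    n = n,
    nevent = sum(event),
    iter = fit$iter,
    converged = converged,
    monotone = monotone,
    ties = ties,
    strata_levels = levels(sfac),
    linear_predictor = drop(design %*% beta)
  )
  class(out) <- "cox_fit"
  if (!converged)
    warning("Cox fit flagged: ",
            if (monotone) "monotone likelihood (|beta| escaping)" else
              "iteration limit reached")
  out
}

#' Fit the high-order gene-smoking interaction Cox model
#'
#' The central model of the package: a histology-stratified Cox
#' proportional-hazards model adjusted for clinical covariates, with a full
#' factorial expansion of the exposure-by-probe interaction of order
#' `k = length(probes) + 1`. Methylation enters per 1 percentage point, so
#' interaction hazard ratios match the per-1% reporting convention.
#' Complete cases only; the number of dropped rows is recorded.
#'
#' @inheritParams build_design
#' @param time_var,event_var names of the follow-up time and event columns.
#' @param strata_var name of the stratification column (default histology).
#' @param ties tie handling, see [fit_cox()].
#' @return object of class `cox_interaction` (inherits `cox_fit`) with the
#'   model specification, design matrix and sample ids attached.
#' @seealso [compute_triune()], [wald_interaction_test()], [scan_order_k()]
#' @export
cox_interaction <- function(cohort, values = NULL, exposure = "pack_years",
                            probes = character(),
                            covariates = c("age", "sex", "smoking_status",
                                           "stage", "center"),
                            strata_var = "histology",
                            time_var = "time", event_var = "event",
                            scheme = c("full_factorial", "as_printed"),
                            value_scale = 100,
                            ties = c("efron", "breslow")) {
  scheme <- match.arg(scheme)
  ties <- match.arg(ties)
  if (length(probes) && exposure %in% probes)
    stop("exposure must not be among the probes")

  need <- c(time_var, event_var, strata_var, exposure,
            intersect(covariates, names(cohort)))
  cc <- stats::complete.cases(cohort[, intersect(need, names(cohort)),
                                     drop = FALSE])
  if (!is.null(values) && length(probes))
    cc <- cc & stats::complete.cases(t(values[probes, , drop = FALSE]))
  n_dropped <- sum(!cc)
  cohort_cc <- cohort[cc, , drop = FALSE]
  values_cc <- if (is.null(values)) NULL else values[, cc, drop = FALSE]

  X <- build_design(cohort_cc, values_cc, exposure = exposure, probes = probes,
                    covariates = covariates, scheme = scheme,
                    value_scale = value_scale)
  fit <- fit_cox(cohort_cc[[time_var]], cohort_cc[[event_var]], X,
                 strata = cohort_cc[[strata_var]], ties = ties)
  fit$spec <- list(exposure = exposure, probes = probes, k = length(probes) + 1,
                   covariates = covariates, strata_var = strata_var,
                   time_var = time_var, event_var = event_var,
                   scheme = scheme, value_scale = value_scale, ties = ties)
  fit$interaction_terms <- attr(X, "interaction_terms")
  fit$highest_term <- attr(X, "highest_term")
  fit$design <- X
  fit$sample_id <- if ("sample_id" %in% names(cohort_cc))
    cohort_cc$sample_id else rownames(cohort_cc)
  fit$n_dropped <- n_dropped
  class(fit) <- c("cox_interaction", "cox_fit")
  fit
}

#' Wald test for a single model term
#'
#' Two-sided normal-based test of `H0: beta_term = 0` with
#' `CI = exp(beta +/- 1.96 se)`; used to report the highest-order
#' interaction effect.
#'
#' @param fit a `cox_fit`.
#' @param term term label; defaults to the highest-order interaction term
#'   for `cox_interaction` fits.
#' @return list with `term`, `estimate`, `se`, `hr`, `ci_low`, `ci_high`,
#'   `z`, `p`.
#' @export
wald_interaction_test <- function(fit, term = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  if (is.null(term)) {
    term <- fit$highest_term
    if (is.null(term) || is.na(term))
      stop("no interaction term in fit; supply 'term'")
  }
  if (!term %in% fit$terms) stop("term not in fit: ", term)
  b <- fit$coefficients[[term]]
  s <- fit$se[[term]]
  list(term = term, estimate = b, se = s,
       hr = exp(b), ci_low = exp(b - 1.96 * s), ci_high = exp(b + 1.96 * s),
       z = b / s, p = 2 * stats::pnorm(-abs(b / s)))
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
vcov.cox_fit <- function(object, ...) object$var

#' @export
logLik.cox_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
confint.cox_fit <- function(object, parm, level = 0.95, ...) {
  zq <- if (level == 0.95) 1.96 else stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - zq * object$se,
              object$coefficients + zq * object$se)
  dimnames(ci) <- list(object$terms,
                       paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                              " %"))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Linear predictor of a fitted interaction Cox model
#'
#' `type = "lp"` returns the uncentered linear predictor `X beta` (no
#' intercept, no baseline term) -- the quantity the TRIUNE score is built
#' from. `type = "risk"` returns `exp(lp)`.
#'
#' @param object a `cox_interaction` fit.
#' @param newdata optional cohort data frame for out-of-sample scoring.
#' @param values feature matrix aligned with `newdata` (required with
#'   `newdata` when the model has probe terms).
#' @param type `"lp"` or `"risk"`.
#' @param ... unused.
#' @export
predict.cox_interaction <- function(object, newdata = NULL, values = NULL,
                                    type = c("lp", "risk"), ...) {
  type <- match.arg(type)
  lp <- if (is.null(newdata)) {
    object$linear_predictor
  } else {
    sp <- object$spec
    X <- build_design(newdata, values, exposure = sp$exposure,
                      probes = sp$probes, covariates = sp$covariates,
                      scheme = sp$scheme, value_scale = sp$value_scale)
    miss <- setdiff(object$terms, colnames(X))
    if (length(miss))
      stop("newdata design lacks fitted term(s): ",
           paste(miss, collapse = ", "))
    drop(X[, object$terms, drop = FALSE] %*% object$coefficients)
  }
  if (type == "risk") exp(lp) else lp
}

#' @export
print.cox_fit <- function(x, digits = 4, ...) {
  cat("Stratified Cox proportional-hazards fit (", x$ties, " ties)\n",
      sep = "")
  cat("n =", x$n, ", events =", x$nevent,
      ", strata:", paste(x$strata_levels, collapse = "/"), "\n")
  tab <- data.frame(coef = x$coefficients, se = x$se, HR = x$hr,
                    lower95 = x$ci_low, upper95 = x$ci_high, p = x$p)
  print(round(tab, digits))
  if (!x$converged) cat("** fit flagged: check convergence diagnostics **\n")
  invisible(x)
}

#' @export
print.cox_interaction <- function(x, digits = 4, ...) {
  sp <- x$spec
  cat("High-order interaction Cox model (order k = ", sp$k, ", ",
      sp$scheme, ")\n", sep = "")
  cat("exposure:", sp$exposure,
      if (length(sp$probes)) paste("; probes:",
                                   paste(sp$probes, collapse = ", ")), "\n")
  NextMethod()
  if (!is.na(x$highest_term)) {
    w <- wald_interaction_test(x)
    cat(sprintf(
      "Highest-order term %s: HR = %.4f (95%% CI %.4f-%.4f), p = %.3g\n",
      w$term, w$hr, w$ci_low, w$ci_high, w$p))
  }
  invisible(x)
}

#' @export
summary.cox_fit <- function(object, ...) {
  tab <- data.frame(
    term = object$terms, coef = object$coefficients, se = object$se,
    z = object$z, p = object$p, HR = object$hr,
    ci_low = object$ci_low, ci_high = object$ci_high,
    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(table = tab, n = object$n, nevent = object$nevent,
              loglik = object$loglik, converged = object$converged)
  class(out) <- "summary.cox_fit"
  out
}

#' @export
print.summary.cox_fit <- function(x, ...) {
  cat("n =", x$n, ", events =", x$nevent,
      ", log partial likelihood =", format(x$loglik), "\n")
  print(x$table, digits = 4)
  invisible(x)
}

# Serialize a fit to a JSON-ready list (terms, beta, se, covariance, p).
#' Serialize a Cox fit to JSON
#'
#' @param fit a `cox_fit`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @export
cox_fit_json <- function(fit, path = NULL) {
  obj <- list(terms = fit$terms,
              coefficients = as.list(fit$coefficients),
              se = as.list(fit$se),
              covariance = unname(apply(fit$var, 1, as.list)),
              p = as.list(fit$p),
              loglik = fit$loglik, n = fit$n, nevent = fit$nevent,
              ties = fit$ties, converged = fit$converged)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    invisible(path)
  } else js
}
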