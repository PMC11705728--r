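# Methylation-expression correlation, cis-regulation candidate definition,
# and the four-way interaction re-test at the gene-expression level.

#' Covariate-adjusted methylation-expression correlation
#'
#' For each (probe, gene) pair fits the linear model
#' `expression ~ methylation + covariates` and reports the methylation
#' coefficient, its t-test p-value, and the Benjamini-Hochberg q over all
#' tested pairs. By design the probe set defaults to the probes involved in
#' the integrated score rather than the whole array, tested against all
#' genes. One QR decomposition per probe is shared across genes.
#'
#' @param beta probe x sample beta matrix.
#' @param expr gene x sample expression matrix (standardized), samples
#'   aligned with `beta` columns.
#' @param cohort cohort data frame for the adjustment covariates.
#' @param covariates adjustment variables (reference-coded internally).
#' @param probes probes to test (default: all rows of `beta`).
#' @param genes genes to test (default: all rows of `expr`).
#' @return data frame: probe, gene, estimate, se, t, p, q.
#' @export
meth_expr_correlation <- function(beta, expr, cohort,
                                  covariates = c("age", "sex",
                                                 "smoking_status", "stage",
                                                 "center"),
                                  probes = NULL, genes = NULL) {
  if (is.null(probes)) probes <- rownames(beta)
  if (is.null(genes)) genes <- rownames(expr)
  shared <- intersect(colnames(beta), colnames(expr))
  cov_cols <- if (length(covariates))
    covariate_columns(cohort[match(shared, cohort$sample_id), , drop = FALSE],
                      covariates) else list()
  n <- length(shared)
  p_cov <- length(cov_cols)
  if (n < p_cov + 3) stop("too few shared samples for the adjusted model")
  Y <- t(expr[genes, shared, drop = FALSE])

  rows <- list()
  for (pb in probes) {
    X <- cbind(intercept = 1, meth = beta[pb, shared],
               do.call(cbind, cov_cols))
    ok <- stats::complete.cases(X) & stats::complete.cases(Y)
    qr_x <- qr(X[ok, , drop = FALSE])
    df_res <- sum(ok) - qr_x$rank
    if (df_res < 1) stop("zero residual degrees of freedom")
    cf <- qr.coef(qr_x, Y[ok, , drop = FALSE])
    res <- qr.resid(qr_x, Y[ok, , drop = FALSE])
    sigma2 <- colSums(res^2) / df_res
    XtXinv <- chol2inv(qr.R(qr_x))
    se <- sqrt(sigma2 * XtXinv[2, 2])
    tval <- cf["meth", ] / se
    rows[[pb]] <- data.frame(
      probe = pb, gene = colnames(Y), estimate = unname(cf["meth", ]),
      se = unname(se), t = unname(tval),
      p = unname(2 * stats::pt(-abs(tval), df_res)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q <- bh_adjust(out$p)
  out
}

#' Define cis-regulation candidates
#'
#' A (probe, gene) pair is a cis candidate when the probe lies within 1 kb of
#' the gene interval and the correlation is significant (p <= 0.05); both
#' boundaries are inclusive. Distance is 0 for a probe inside the gene body,
#' otherwise the base-pair gap to the nearest interval end (1-based inclusive
#' coordinates, strand ignored). A probe may map to several genes.
#'
#' @param correlations data frame from [meth_expr_correlation()].
#' @param probe_annotation data frame with `probe`, `chrom`, `pos`.
#' @param gene_annotation BED-like data frame with `chrom`, `start`, `end`,
#'   `gene`.
#' @param max_distance cis window in bp (default 1000).
#' @param alpha correlation significance threshold (default 0.05).
#' @return data frame: probe, gene, distance, estimate, p, q, cis (flag).
#'   Pairs whose probe chromosome is absent from the gene annotation are
#'   skipped with a warning.
#' @export
cis_candidates <- function(correlations, probe_annotation, gene_annotation,
                           max_distance = 1000, alpha = 0.05) {
  pi <- match(correlations$probe, probe_annotation$probe)
  gi <- match(correlations$gene, gene_annotation$gene)
  keep <- !is.na(pi) & !is.na(gi)
  out <- correlations[keep, , drop = FALSE]
  pa <- probe_annotation[pi[keep], ]
  ga <- gene_annotation[gi[keep], ]

  bad_chr <- !pa$chrom %in% gene_annotation$chrom
  if (any(bad_chr))
    warning("probe chromosome absent from gene annotation; skipped: ",
            paste(unique(pa$probe[bad_chr]), collapse = ", "))
  same <- pa$chrom == ga$chrom
  dist <- ifelse(!same, Inf,
          ifelse(pa$pos >= ga$start & pa$pos <= ga$end, 0,
          ifelse(pa$pos < ga$start, ga$start - pa$pos, pa$pos - ga$end)))
  out$distance <- dist
  out$cis <- dist <= max_distance & out$p <= alpha
  out[!bad_chr, , drop = FALSE]
}

#' Four-way interaction test at the gene-expression level
#'
#' Re-tests the gene-smoking interaction with standardized expression values
#' of the three cis genes in place of the methylation probes: an order-4
#' factorial Cox model adjusted for the clinical covariates, with the
#' highest-order Wald p reported against the 0.05 threshold.
#'
#' @inheritParams cox_interaction
#' @param expr gene x sample standardized expression matrix.
#' @param gene_triple the three gene names entering the interaction.
#' @param alpha significance threshold for the report (default 0.05).
#' @return list with `fit` (the `cox_interaction`) and `interaction` (the
#'   highest-order Wald report plus a `significant` flag).
#' @export
expression_interaction <- function(cohort, expr, gene_triple,
                                   exposure = "pack_years",
                                   covariates = c("age", "sex",
                                                  "smoking_status", "stage",
                                                  "center"),
                                   strata_var = "histology",
                                   scheme = "full_factorial",
                                   alpha = 0.05, ...) {
  stopifnot(length(gene_triple) == 3)
  fit <- cox_interaction(cohort, expr, exposure = exposure,
                         probes = gene_triple, covariates = covariates,
                         strata_var = strata_var, scheme = scheme,
                         value_scale = 1, ...)
  w <- wald_interaction_test(fit)
  w$significant <- w$p <= alpha
  list(fit = fit, interaction = w)
}
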