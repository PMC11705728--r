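# Probe- and sample-level quality control for beta-value methylation
# matrices, and expression-matrix QC.  Probe rules, applied in a fixed order
# (first failing rule attributed):
#   a  detection   : detection p > 0.05 in more than 5% of samples (strict)
#   b  low_cv      : coefficient of variation sd/mean < 5% on the [0,1] scale
#   c  constant_state: all betas >= hi (methylated) or all <= lo
#                    (unmethylated); probes with mean 0 fall in here
#   d  snp_flag    : SNP in probe sequence or 10-bp flank (annotation flag)
#   e  cross_reactive: cross-reactive/cross-hybridizing (annotation flag)
#   f  not_in_all_centers: data-driven rules a-c re-evaluated per center must
#                    pass in every center (annotation rules are
#                    center-invariant)

qc_rules <- c("detection", "low_cv", "constant_state", "snp_flag",
              "cross_reactive", "not_in_all_centers")

# first failing data-driven rule (a-c) for one probe block, or NA
probe_data_rule <- function(b, dp, detection_frac, cv_min, lo, hi) {
  if (!is.null(dp)) {
    fail_frac <- mean(dp > 0.05, na.rm = TRUE)
    if (is.finite(fail_frac) && fail_frac > detection_frac)
      return("detection")
  }
  x <- b[!is.na(b)]
  if (!length(x)) return("constant_state")   # entirely missing: no signal
  m <- mean(x)
  if (m == 0) return("constant_state")       # mean-zero: constant by design
  if (stats::sd(x) / m < cv_min) return("low_cv")
  if (all(x >= hi) || all(x <= lo)) return("constant_state")
  NA_character_
}

#' Probe-level quality control
#'
#' Applies the six probe-exclusion rules (see the package QC rule table) and
#' removes a probe if any rule fires. Missing betas are ignored in the CV and
#' constant-state checks; a probe entirely missing in any center fails the
#' per-center rule.
#'
#' @param beta probe x sample matrix of beta values in `[0,1]`.
#' @param detection_p optional matrix of detection p-values, same shape.
#' @param annotation optional data frame with columns `probe`, `snp_flag`,
#'   `cross_reactive` (logical).
#' @param center_labels optional per-sample center labels; enables the
#'   pass-in-all-centers rule.
#' @param detection_frac maximum tolerated fraction of detection failures
#'   (strictly greater removes; default 0.05).
#' @param cv_min minimum coefficient of variation (default 0.05).
#' @param lo,hi constant-state thresholds: removed if all betas `<= lo` or
#'   all `>= hi` (defaults 0.1 / 0.9).
#' @return list with `beta` (retained probes), `report` (per-probe pass/fail
#'   with the first failing rule) and `counts` (removals per rule).
#' @export
filter_probes <- function(beta, detection_p = NULL, annotation = NULL,
                          center_labels = NULL,
                          detection_frac = 0.05, cv_min = 0.05,
                          lo = 0.1, hi = 0.9) {
  check_matrix_ids(beta)
  if (!is.null(detection_p) && !identical(dim(detection_p), dim(beta)))
    stop("beta and detection_p shapes disagree")
  if (!is.null(annotation)) {
    need <- c("probe", "snp_flag", "cross_reactive")
    miss <- setdiff(need, names(annotation))
    if (length(miss))
      stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  }
  m <- nrow(beta)
  rule <- rep(NA_character_, m)

  for (i in seq_len(m)) {
    r <- probe_data_rule(beta[i, ],
                         if (is.null(detection_p)) NULL else detection_p[i, ],
                         detection_frac, cv_min, lo, hi)
    if (!is.na(r)) { rule[i] <- r; next }
    if (!is.null(annotation)) {
      j <- match(rownames(beta)[i], annotation$probe)
      if (!is.na(j)) {
        if (isTRUE(annotation$snp_flag[j])) { rule[i] <- "snp_flag"; next }
        if (isTRUE(annotation$cross_reactive[j])) {
          rule[i] <- "cross_reactive"; next
        }
      }
    }
    if (!is.null(center_labels)) {
      for (ctr in unique(center_labels)) {
        idx <- center_labels == ctr
        rc <- probe_data_rule(
          beta[i, idx],
          if (is.null(detection_p)) NULL else detection_p[i, idx],
          detection_frac, cv_min, lo, hi)
        if (!is.na(rc)) { rule[i] <- "not_in_all_centers"; break }
      }
    }
  }

  pass <- is.na(rule)
  report <- data.frame(probe = rownames(beta), pass = pass, rule = rule,
                       stringsAsFactors = FALSE)
  counts <- table(factor(rule, levels = qc_rules))
  structure(list(beta = beta[pass, , drop = FALSE], report = report,
                 counts = counts, retained = sum(pass),
                 removed = sum(!pass)),
            class = "qc_result")
}

#' Sample-level quality control
#'
#' Removes a sample if its fraction of undetectable probes (detection
#' p > 0.05) strictly exceeds 5%, or if its pack-years of smoking is
#' missing. Retained samples keep their input order.
#'
#' @param beta probe x sample matrix (used for sample ids and alignment).
#' @param detection_p optional detection p-value matrix, same shape.
#' @param phenotypes data frame with `sample_id` and `pack_years` columns.
#' @param max_fail_frac removal threshold on the undetectable fraction
#'   (strict; default 0.05).
#' @return list with `samples` (retained ids, input order), `report` and
#'   `counts`.
#' @export
filter_samples <- function(beta, detection_p = NULL, phenotypes,
                           max_fail_frac = 0.05) {
  ids <- colnames(beta)
  if (!all(ids %in% phenotypes$sample_id))
    stop("sample id mismatch between beta and phenotypes")
  ph <- phenotypes[match(ids, phenotypes$sample_id), ]
  reason <- rep(NA_character_, length(ids))
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(beta)))
      stop("beta and detection_p shapes disagree")
    fail_frac <- colMeans(detection_p > 0.05, na.rm = TRUE)
    reason[fail_frac > max_fail_frac] <- "sample_detection"
  }
  reason[is.na(reason) & is.na(ph$pack_years)] <- "missing_packyear"
  pass <- is.na(reason)
  report <- data.frame(sample_id = ids, pass = pass, rule = reason,
                       stringsAsFactors = FALSE)
  counts <- table(factor(reason,
                         levels = c("sample_detection", "missing_packyear")))
  structure(list(samples = ids[pass], report = report, counts = counts,
                 retained = sum(pass), removed = sum(!pass)),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("QC:", x$retained, "retained,", x$removed, "removed\n")
  ct <- x$counts[x$counts > 0]
  if (length(ct)) print(ct)
  invisible(x)
}

#' Location-scale batch alignment of beta values
#'
#' A simple per-probe, per-batch location/scale alignment to the pooled
#' reference (per-probe pooled mean and SD), clipped to `[0,1]`. This is a
#' deliberately lightweight batch-adjustment step for desk-scale matrices,
#' not a reimplementation of array-normalization pipelines; with a single
#' batch the input is returned unchanged.
#'
#' @param beta probe x sample matrix.
#' @param batch_labels per-sample batch labels (>= 2 samples per batch).
#' @return adjusted matrix, same shape and dimnames.
#' @export
normalize_batches <- function(beta, batch_labels) {
  stopifnot(length(batch_labels) == ncol(beta))
  tab <- table(batch_labels)
  if (any(tab < 2))
    stop("batch with fewer than 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  if (length(tab) == 1L) return(beta)
  pooled_m <- rowMeans(beta, na.rm = TRUE)
  pooled_s <- apply(beta, 1, stats::sd, na.rm = TRUE)
  out <- beta
  for (b in names(tab)) {
    idx <- which(batch_labels == b)
    bm <- rowMeans(beta[, idx, drop = FALSE], na.rm = TRUE)
    bs <- apply(beta[, idx, drop = FALSE], 1, stats::sd, na.rm = TRUE)
    scale <- ifelse(bs > 0, pooled_s / bs, 1)
    out[, idx] <- (beta[, idx, drop = FALSE] - bm) * scale + pooled_m
  }
  pmin(pmax(out, 0), 1)
}

#' Expression matrix quality control
#'
#' Removes genes whose missing fraction strictly exceeds `missing_threshold`,
#' optionally applies `log2(x + 1)`, and standardizes each gene to mean 0,
#' SD 1 (computed over non-missing entries). Genes constant after filtering
#' cannot be standardized and are dropped with a warning.
#'
#' @param expr gene x sample matrix, possibly with missing entries.
#' @param missing_threshold maximum tolerated missing fraction (default 0.8).
#' @param log2_transform logical; raw non-negative values expected if TRUE.
#' @return gene x sample matrix of standardized retained genes.
#' @export
filter_expression <- function(expr, missing_threshold = 0.8,
                              log2_transform = FALSE) {
  miss <- rowMeans(is.na(expr))
  keep <- miss <= missing_threshold
  expr <- expr[keep, , drop = FALSE]
  if (log2_transform) {
    if (any(expr < 0, na.rm = TRUE))
      stop("negative raw values with log2 transform enabled")
    expr <- log2(expr + 1)
  }
  sds <- apply(expr, 1, stats::sd, na.rm = TRUE)
  const <- !is.finite(sds) | sds == 0
  if (any(const)) {
    warning("constant gene(s) dropped (cannot standardize): ",
            paste(rownames(expr)[const], collapse = ", "))
    expr <- expr[!const, , drop = FALSE]
  }
  out <- t(scale(t(expr)))
  attr(out, "scaled:center") <- attr(out, "scaled:scale") <- NULL
  out
}

check_matrix_ids <- function(x) {
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("matrix must carry feature rownames and sample colnames")
  if (anyDuplicated(rownames(x))) stop("duplicated feature ids")
  if (anyDuplicated(colnames(x))) stop("duplicated sample ids")
  invisible(TRUE)
}
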