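# Readers/writers for the tabular interchange formats and the orchestrating
# end-to-end pipeline.  All matrices travel as delimited text with a header
# row of sample ids and a first column of feature ids; "NA" and empty tokens
# are missing.

#' Read a feature-by-sample matrix from delimited text
#'
#' @param path file path (tab- or comma-delimited inferred from extension,
#'   override with `sep`).
#' @param kind value validation: `"beta"` and `"detection"` require values in
#'   `[0,1]`; `"expression"` is unconstrained.
#' @param sep field separator; default by extension (.csv comma, else tab).
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix <- function(path, kind = c("beta", "detection", "expression"),
                        sep = NULL) {
  kind <- match.arg(kind)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicated feature ids in ", path)
  if (anyDuplicated(colnames(df)[-1]))
    stop("duplicated sample ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  rownames(m) <- ids
  if (kind %in% c("beta", "detection")) {
    bad <- which(m < 0 | m > 1, arr.ind = TRUE)
    if (nrow(bad))
      stop(kind, " value out of [0,1] at feature ", ids[bad[1, 1]],
           ", sample ", colnames(m)[bad[1, 2]])
  }
  m
}

#' Write a feature-by-sample matrix as delimited text
#'
#' @param m numeric matrix with dimnames.
#' @param path output path (.csv writes comma-separated, else tab).
#' @param id_col name of the feature-id column in the header.
#' @export
write_matrix <- function(m, path, id_col = "feature_id") {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' @param path CSV/TSV with a `sample_id` column plus the clinical fields
#'   (age, sex, smoking_status, pack_years, stage, histology, center, time,
#'   event).
#' @export
read_phenotypes <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("phenotype table lacks sample_id")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample ids in ", path)
  df
}

#' Write a synthetic bundle to a directory of text files
#'
#' Writes beta matrix TSV, detection-p TSV, phenotype CSV, probe annotation
#' TSV, gene annotation TSV, expression TSV (if present) and the planted
#' truth as JSON.
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(bundle$beta, file.path(dir, "beta.tsv"), "probe")
  write_matrix(bundle$detection_p, file.path(dir, "detection_p.tsv"),
               "probe")
  utils::write.csv(bundle$cohort, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  utils::write.table(bundle$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$gene_annotation,
                     file.path(dir, "gene_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$expression))
    write_matrix(bundle$expression, file.path(dir, "expression.tsv"),
                 "gene")
  truth <- bundle$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Validate a pipeline configuration
#'
#' Checks thresholds, horizons and file references before any computation.
#'
#' @param config named list (or path to a YAML file): per-phase file paths
#'   (`discovery`, `validation`, each with `beta`, `pheno`, optional
#'   `detection`), `annotation`, optional `expression` +
#'   `gene_annotation`, `exposure`, `fixed_probes`, `max_order`,
#'   `fdr_level`, `valid_p`, `scheme`, `horizons`, `seed`, `out_dir`.
#' @return the validated config list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(exposure = "pack_years", fixed_probes = character(),
                   max_order = 4, fdr_level = 0.05, valid_p = 0.05,
                   scheme = "full_factorial", horizons = c(3, 5),
                   seed = 1L)
  config <- utils::modifyList(defaults, config)
  for (thr in c("fdr_level", "valid_p")) {
    v <- config[[thr]]
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop("config: ", thr, " must lie in (0,1)")
  }
  if (any(config$horizons <= 0)) stop("config: horizons must be > 0")
  if (is.null(config$out_dir)) stop("config: out_dir required")
  for (phase in c("discovery", "validation")) {
    ph <- config[[phase]]
    if (is.null(ph$beta) || is.null(ph$pheno))
      stop("config: ", phase, " needs beta and pheno paths")
    for (f in unlist(ph)) {
      if (!file.exists(f)) stop("config: file not found: ", f)
    }
  }
  config
}

read_phase <- function(ph) {
  list(beta = read_matrix(ph$beta, "beta"),
       detection = if (!is.null(ph$detection))
         read_matrix(ph$detection, "detection"),
       pheno = read_phenotypes(ph$pheno))
}

read_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df
}

#' Run the two-phase interaction analysis end to end
#'
#' Orchestrates QC, the hill-climbing scan with two-phase validation, the
#' integrated-score subgroup analyses, the nested prognostic-model
#' evaluation, and (if expression data are configured) the cis-regulation
#' follow-up. Every stage writes its result table under `out_dir` plus a
#' JSON manifest with the seed, thresholds and stage counts; rerunning the
#' same configuration reproduces identical outputs. A stage failure aborts
#' with the stage name; tables of completed stages persist.
#'
#' @param config list or YAML path, see [validate_config()].
#' @return (invisibly) a list with the principal in-memory results.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list(seed = config$seed, fdr_level = config$fdr_level,
                   valid_p = config$valid_p, scheme = config$scheme,
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  disc <- stage("read", read_phase(config$discovery))
  valid <- stage("read", read_phase(config$validation))
  annot <- if (!is.null(config$annotation))
    stage("read", read_annotation(config$annotation))

  qc_phase <- function(d, label) {
    sq <- filter_samples(d$beta, d$detection, d$pheno)
    keep <- sq$samples
    beta <- d$beta[, keep, drop = FALSE]
    det <- if (!is.null(d$detection)) d$detection[, keep, drop = FALSE]
    pheno <- d$pheno[match(keep, d$pheno$sample_id), ]
    pq <- filter_probes(beta, det, annot, center_labels = pheno$center)
    utils::write.table(pq$report,
                       file.path(out, paste0("qc_probes_", label, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sq$report,
                       file.path(out, paste0("qc_samples_", label, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(beta = pq$beta, pheno = pheno,
         counts = list(samples_removed = sq$removed,
                       probes_removed = pq$removed))
  }
  dq <- stage("qc", qc_phase(disc, "discovery"))
  vq <- stage("qc", qc_phase(valid, "validation"))
  manifest$stages$qc <- c(dq$counts, vq$counts)

  # probes must survive QC in both phases to be scannable
  shared <- intersect(rownames(dq$beta), rownames(vq$beta))
  hc <- stage("scan", hill_climb(
    dq$pheno, dq$beta[shared, , drop = FALSE],
    vq$pheno, vq$beta[shared, , drop = FALSE],
    exposure = config$exposure, max_order = config$max_order,
    fixed_probes = config$fixed_probes,
    alpha_q = config$fdr_level, alpha_p = config$valid_p,
    scheme = config$scheme))
  for (k in names(hc$scans)) {
    utils::write.table(as.data.frame(hc$scans[[k]]),
                       file.path(out, paste0("scan_", k, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(hc$decisions[[k]]),
                       file.path(out, paste0("two_phase_", k, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest$stages$scan <- list(winners = hc$winners)

  results <- list(hill_climb = hc)
  winners <- c(config$fixed_probes, hc$winners)
  if (length(winners) >= 3) {
    winners <- winners[1:3]
    # phase-prefixed ids keep pooled samples unique across the two phases
    dp <- transform(dq$pheno, phase = "discovery",
                    sample_id = paste0("disc_", sample_id))
    vp <- transform(vq$pheno, phase = "validation",
                    sample_id = paste0("valid_", sample_id))
    pooled_pheno <- rbind(dp, vp)
    bd <- dq$beta[shared, , drop = FALSE]
    colnames(bd) <- paste0("disc_", colnames(bd))
    bv <- vq$beta[shared, , drop = FALSE]
    colnames(bv) <- paste0("valid_", colnames(bv))
    pooled_beta <- cbind(bd, bv)
    fit <- stage("triune", cox_interaction(
      pooled_pheno, pooled_beta, exposure = config$exposure,
      probes = winners, scheme = config$scheme))
    clin <- stage("triune", fit_clinical(pooled_pheno))
    rs <- stage("triune", compute_triune(fit, clinical_fit = clin))
    utils::write.csv(rs, file.path(out, "triune_scores.csv"),
                     row.names = FALSE)
    idx <- match(rs$sample_id, pooled_pheno$sample_id)
    ghr <- stage("triune", group_hazard_ratios(pooled_pheno[idx, ],
                                               rs$group))
    utils::write.csv(ghr, file.path(out, "group_hazard_ratios.csv"),
                     row.names = FALSE)
    forest <- stage("triune", stratified_forest(pooled_pheno[idx, ],
                                                rs$triune))
    utils::write.csv(forest, file.path(out, "stratified_forest.csv"),
                     row.names = FALSE)
    surf <- stage("triune", conditional_effect_surface(fit))
    utils::write.table(surf, file.path(out, "effect_surface.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    eval_res <- stage("evaluate", nested_models(
      pooled_pheno[idx, ], pooled_beta[, idx, drop = FALSE], winners,
      exposure = config$exposure, horizons = config$horizons))
    utils::write.csv(eval_res$auc, file.path(out, "model_auc.csv"),
                     row.names = FALSE)
    utils::write.csv(eval_res$contrasts,
                     file.path(out, "model_contrasts.csv"),
                     row.names = FALSE)
    utils::write.csv(eval_res$c_index, file.path(out, "model_cindex.csv"),
                     row.names = FALSE)
    results <- c(results, list(fit = fit, scores = rs, group_hr = ghr,
                               forest = forest, surface = surf,
                               evaluation = eval_res))
    manifest$stages$triune <- list(n_scored = nrow(rs))

    if (!is.null(config$expression)) {
      expr <- stage("cis", read_matrix(config$expression, "expression"))
      gene_annot <- stage("cis",
                          read_annotation(config$gene_annotation))
      # expression is profiled on the discovery samples; correlate there
      corr <- stage("cis", meth_expr_correlation(
        dq$beta[shared, , drop = FALSE], expr, dq$pheno,
        probes = winners))
      cis <- stage("cis", cis_candidates(corr, annot, gene_annot))
      utils::write.table(cis, file.path(out, "cis_candidates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$cis <- cis
      manifest$stages$cis <- list(n_pairs = nrow(corr),
                                  n_cis = sum(cis$cis))
    }
  }

  manifest$config_hash <- digest_config(config)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

# order-independent hash of the configuration list (base R)
digest_config <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997)) %% 2147483647
}
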