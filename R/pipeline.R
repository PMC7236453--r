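# End-to-end orchestration: ingest -> label -> filter -> split -> (optional
# wavelet selection) -> SWT -> CNN -> representative features -> gene scores
# -> top-n tuning -> univariate/multivariate Cox -> risk score -> ROC cutoff
# -> validation stratification -> KM/log-rank -> metrics.
#
# Everything learned (wavelet choice, best CNN run, top-n, signature, betas,
# cutoff) is derived from the training side only; validation samples are
# touched only by the final scoring/stratification.

#' Pipeline configuration
#'
#' @param endpoint `"survival3y"` or `"stage"`.
#' @param horizon_days Survival-endpoint horizon (default 1095).
#' @param wavelet A wavelet name, `"auto"` (inner-split selection over
#'   `wavelet_candidates`), or `"none"` (raw profiles).
#' @param wavelet_candidates Candidates searched when `wavelet = "auto"`.
#' @param levels Decomposition levels.
#' @param cnn A [cnn_config()].
#' @param cnn_runs Training repeats for best-model selection (paper protocol:
#'   100).
#' @param score_on `"expression"` (score matrix maps features back onto the
#'   original expression profiles, the default) or `"swt1"` (onto the level-1
#'   approximation coefficients).
#' @param top_n Integer, or `"auto"` to tune over `top_n_grid`.
#' @param top_n_grid Candidate top-n values.
#' @param train_fraction Training fraction of the single evaluation split.
#' @param log2_expression Use `log2(x + 1)` expression everywhere
#'   (default FALSE: raw values, matching the FPKM protocol).
#' @param seed Integer seed for every random choice in the run.
#' @param out_dir Directory for artifacts (score/risk tables, model, metrics,
#'   manifest); NULL writes nothing.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(endpoint = c("survival3y", "stage"),
                            horizon_days = 1095,
                            wavelet = "db3",
                            wavelet_candidates = wavelet_names(),
                            levels = 3L,
                            cnn = cnn_config(),
                            cnn_runs = 1L,
                            score_on = c("expression", "swt1"),
                            top_n = "auto",
                            top_n_grid = seq(100L, 1000L, by = 100L),
                            train_fraction = 0.7,
                            log2_expression = FALSE,
                            seed = 1L,
                            out_dir = NULL) {
  endpoint <- match.arg(endpoint)
  score_on <- match.arg(score_on)
  if (!identical(wavelet, "auto") && !identical(wavelet, "none")) {
    stopifnot(wavelet %in% wavelet_names())
  }
  structure(as.list(environment()), class = "pipeline_config")
}

.swt1_matrix <- function(tensor, cols) {
  t(tensor$coeffs[cols, , 1L, drop = TRUE])  # level-1 approximations, p x n
}

#' Run the full risk-stratification pipeline
#'
#' @param expr Expression matrix, genes x samples.
#' @param clinical Clinical data.frame (see [read_clinical()]).
#' @param config A [pipeline_config()].
#' @return A list of class `swtcnn_pipeline` holding the fitted `swt_cnn`
#'   model, the gene-score table, the Cox risk model with its cutoff, the
#'   validation risk table, KM/log-rank results, and a `metrics` list
#'   (SWT-CNN validation AUC, risk-score validation AUC, chosen wavelet and
#'   top-n, log-rank p).
#' @export
run_pipeline <- function(expr, clinical, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  expr <- as.matrix(expr)
  stage <- function(what, expr_) {
    tryCatch(expr_, error = function(e) {
      stop("pipeline stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  expr <- stage("filter", filter_low_expression(expr))
  if (config$log2_expression) expr <- log2(expr + 1)
  cohort <- stage("label", suppressMessages(
    if (config$endpoint == "survival3y") {
      derive_survival_labels(clinical, config$horizon_days)
    } else {
      derive_stage_labels(clinical)
    }))
  cohort <- cohort[cohort$sample_id %in% colnames(expr), , drop = FALSE]
  expr <- expr[, cohort$sample_id, drop = FALSE]

  set.seed(config$seed)
  idx <- stage("split", .split_indices(cohort$label, config$train_fraction))
  train_ids <- cohort$sample_id[idx$train]
  val_ids <- cohort$sample_id[idx$test]
  tr_expr <- expr[, train_ids, drop = FALSE]
  tr_coh <- cohort[idx$train, , drop = FALSE]

  wavelet <- config$wavelet
  wavelet_aucs <- NULL
  if (identical(wavelet, "auto")) {
    sel <- stage("wavelet selection",
                 select_wavelet(tr_expr, tr_coh$label,
                                candidates = config$wavelet_candidates,
                                levels = config$levels, config = config$cnn,
                                seed = config$seed))
    wavelet <- sel$wavelet
    wavelet_aucs <- sel$auc
  }

  fit <- stage("cnn training",
               swt_cnn(tr_expr, tr_coh$label, wavelet = wavelet,
                       levels = config$levels, config = config$cnn,
                       runs = config$cnn_runs, seed = config$seed))

  cnn_val_scores <- stage("cnn validation scoring",
                          predict(fit, expr[, val_ids, drop = FALSE]))
  cnn_val_auc <- auc(cohort$label[idx$test], cnn_val_scores)

  X <- stage("feature extraction",
             extract_representative_features(fit, tr_expr))
  Y <- if (config$score_on == "expression") {
    tr_expr
  } else {
    tens <- .tensor_for(fit, tr_expr)
    m <- .swt1_matrix(tens, seq_along(train_ids))
    rownames(m) <- rownames(tr_expr)
    m
  }
  B <- stage("gene scoring", score_matrix(Y, X))
  scores <- gene_scores(B)

  n_top <- if (identical(config$top_n, "auto")) {
    stage("top-n tuning",
          tune_top_n(tr_expr, tr_coh, scores, grid = config$top_n_grid,
                     seed = config$seed))$n
  } else {
    as.integer(config$top_n)
  }

  genes <- top_n_genes(scores, n_top)
  uni <- stage("univariate Cox",
               suppressWarnings(univariate_cox(tr_expr[genes, , drop = FALSE],
                                               tr_coh$os_days, tr_coh$event)))
  sel_genes <- uni$gene_id[uni$selected]
  if (length(sel_genes) == 0L) {
    stop("pipeline stage 'univariate Cox' failed: no gene at p < 0.05",
         call. = FALSE)
  }
  model <- stage("multivariate Cox", suppressMessages(
    multivariate_cox(tr_expr[sel_genes, , drop = FALSE],
                     tr_coh$os_days, tr_coh$event)))

  tr_scores <- risk_score(model, tr_expr)
  model$cutoff <- stage("cutoff", choose_cutoff_roc(tr_scores, tr_coh$label))

  val_expr <- expr[, val_ids, drop = FALSE]
  val_scores <- risk_score(model, val_expr)
  groups <- stratify(val_scores, model$cutoff)
  risk_val_auc <- auc(cohort$label[idx$test], val_scores)
  km <- if (nlevels(droplevels(groups)) == 2L) {
    suppressWarnings(km_logrank(groups, cohort$os_days[idx$test],
                                cohort$event[idx$test]))
  } else NULL

  metrics <- list(
    endpoint = config$endpoint,
    wavelet = wavelet,
    n_top = n_top,
    n_signature = length(model$gene_ids),
    fit_mode = model$fit_mode,
    cutoff = model$cutoff,
    cnn_validation_auc = cnn_val_auc,
    risk_validation_auc = risk_val_auc,
    logrank_chisq = if (!is.null(km)) km$chisq else NA_real_,
    logrank_p = if (!is.null(km)) km$p_value else NA_real_,
    median_survival = if (!is.null(km)) as.list(km$median) else NULL,
    n_train = length(train_ids), n_validation = length(val_ids),
    seed = config$seed
  )

  result <- structure(list(
    metrics = metrics, model = model, cnn = fit, scores = scores,
    univariate = uni, wavelet_aucs = wavelet_aucs,
    risk_table = data.frame(sample_id = val_ids, risk_score = val_scores,
                            group = groups, label = cohort$label[idx$test],
                            stringsAsFactors = FALSE),
    km = km, train_ids = train_ids, validation_ids = val_ids,
    config = config
  ), class = "swtcnn_pipeline")

  if (!is.null(config$out_dir)) .write_artifacts(result, config$out_dir)
  result
}

.write_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$scores, file.path(out_dir, "gene_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$risk_table, file.path(out_dir, "risk_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(gene_ids = result$model$gene_ids,
         betas = as.list(result$model$betas),
         cutoff = result$model$cutoff,
         fit_mode = result$model$fit_mode),
    file.path(out_dir, "risk_model.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg <- result$config
  cfg$cnn <- unclass(cfg$cnn)
  manifest <- list(config = unclass(cfg), seed = cfg$seed,
                   train_ids = result$train_ids,
                   validation_ids = result$validation_ids)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

#' @export
print.swtcnn_pipeline <- function(x, ...) {
  m <- x$metrics
  cat("SWT-CNN risk-stratification pipeline (endpoint ", m$endpoint, ")\n",
      "  wavelet ", m$wavelet, ", top-n ", m$n_top, " -> ", m$n_signature,
      " signature gene(s) [", m$fit_mode, "]\n",
      "  validation AUC: SWT-CNN ", round(m$cnn_validation_auc, 3),
      ", risk score ", round(m$risk_validation_auc, 3), "\n", sep = "")
  if (!is.na(m$logrank_p)) {
    cat("  log-rank chisq ", round(m$logrank_chisq, 2), " (p = ",
        signif(m$logrank_p, 3), ")\n", sep = "")
  }
  invisible(x)
}
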