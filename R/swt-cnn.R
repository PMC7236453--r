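# The user-facing fitting function: wavelet decomposition + CNN in one step.

#' Fit an SWT-CNN classifier to an expression matrix
#'
#' Decomposes every sample's profile with the stationary wavelet transform
#' (stacking the approximation bands of the requested levels as input
#' channels) and trains the one-convolutional-layer classifier on the
#' resulting tensor. With `wavelet = "none"` the raw profile is used as a
#' single input channel, which is the comparison the wavelet step is designed
#' to beat when informative genes are dwarfed by very highly expressed ones.
#'
#' @param expr Numeric matrix, genes x samples (non-negative expression).
#' @param labels Binary labels (1 = high risk), one per sample.
#' @param wavelet One of [wavelet_names()], or `"none"` for raw profiles.
#' @param levels Decomposition levels (default 3).
#' @param config A [cnn_config()].
#' @param runs Training runs; with `runs > 1` the best of `runs` models by
#'   inner-validation AUC is kept (see [repeat_train_select_best()]).
#' @param seed Integer seed.
#' @return An object of class `swt_cnn` with `predict`, `print` and
#'   `summary` methods.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_samples = 60, n_genes = 64, seed = 1))
#' coh <- derive_survival_labels(sim$clinical)
#' expr <- sim$expression[, coh$sample_id]
#' fit <- swt_cnn(expr, coh$label, wavelet = "db1",
#'                config = cnn_config(n_filters = 8, epochs = 3), seed = 1)
#' head(predict(fit, expr))
swt_cnn <- function(expr, labels, wavelet = "db3", levels = 3L,
                    config = cnn_config(), runs = 1L, seed = 1L) {
  expr <- as.matrix(expr)
  labels <- as.integer(labels)
  if (length(labels) != ncol(expr)) {
    stop("one label per sample (column) required", call. = FALSE)
  }
  tensor <- if (is.null(wavelet) || identical(wavelet, "none")) {
    .raw_tensor(expr)
  } else {
    decompose_cohort(expr, wavelet, levels)
  }
  cnn <- if (runs > 1L) {
    repeat_train_select_best(tensor, labels, config, runs = runs, seed = seed)
  } else {
    train_cnn(tensor, labels, config, seed = seed)
  }
  structure(list(cnn = cnn, wavelet = tensor$wavelet, levels = tensor$levels,
                 gene_ids = rownames(expr), config = config,
                 runs = as.integer(runs), seed = as.integer(seed),
                 n_train = ncol(expr), class_counts = table(labels)),
            class = "swt_cnn")
}

.tensor_for <- function(object, expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) != length(object$gene_ids)) {
    stop("expression matrix has ", nrow(expr), " genes; model was fitted on ",
         length(object$gene_ids), call. = FALSE)
  }
  if (!is.null(rownames(expr)) &&
      !identical(rownames(expr), object$gene_ids)) {
    stop("gene ids (and their order) must match the training matrix",
         call. = FALSE)
  }
  if (object$wavelet == "none") .raw_tensor(expr)
  else decompose_cohort(expr, object$wavelet, object$levels)
}

#' @export
predict.swt_cnn <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  pr <- predict_proba(object$cnn, .tensor_for(object, newdata))
  if (type == "prob") pr else as.integer(pr > 0.5)
}

#' @export
extract_representative_features.swt_cnn <- function(model, x, chunk = 64L) {
  extract_representative_features(model$cnn, .tensor_for(model, x), chunk)
}

#' @export
print.swt_cnn <- function(x, ...) {
  cat("SWT-CNN classifier\n",
      "  wavelet: ", x$wavelet,
      if (x$wavelet != "none") paste0(" (", x$levels, " levels)"), "\n",
      "  genes:   ", length(x$gene_ids), "\n",
      "  trained on ", x$n_train, " samples (",
      paste(names(x$class_counts), x$class_counts, sep = "=", collapse = ", "),
      "), ", x$runs, " run(s)\n", sep = "")
  invisible(x)
}

#' @export
summary.swt_cnn <- function(object, ...) {
  print(object)
  print(build_cnn(object$config, object$cnn$p, object$cnn$m))
  cat("training loss: first ", signif(object$cnn$history[1], 4), ", final ",
      signif(utils::tail(object$cnn$history, 1), 4), "\n", sep = "")
  if (!is.null(object$cnn$inner_auc) && !is.na(object$cnn$inner_auc)) {
    cat("best run ", object$cnn$run, " (inner-validation AUC ",
        round(object$cnn$inner_auc, 3), ")\n", sep = "")
  }
  invisible(object)
}
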