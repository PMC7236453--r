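# Comparison classifiers: t-test + fold-change gene filter feeding an SVM
# (RBF kernel, grid-searched), a random forest, or logistic regression.

#' Differential-expression gene filter
#'
#' Per-gene two-sample Student's t-test (pooled variance) between the two
#' label classes plus a fold-change criterion. A gene is retained when
#' p < `p_cutoff` and its class-mean ratio differs from 1 by more than
#' `fc_cutoff`-fold in either direction (|log2 FC| > log2(`fc_cutoff`)). A
#' small pseudocount guards zero class means.
#'
#' @param expr Numeric matrix, genes x samples (optionally `log2(x + 1)`
#'   transformed first; see `log_transform`).
#' @param labels Binary labels (0/1), one per sample.
#' @param p_cutoff t-test threshold (default 0.05).
#' @param fc_cutoff Fold-change threshold (default 2).
#' @param log_transform Apply `log2(x + 1)` before testing (default FALSE).
#' @param eps Pseudocount guarding zero means.
#' @return A data.frame with `gene_id`, `p_value`, `fold_change`
#'   (class-1 mean over class-0 mean) and `retained`.
#' @export
ttest_fc_filter <- function(expr, labels, p_cutoff = 0.05, fc_cutoff = 2,
                            log_transform = FALSE, eps = 1e-9) {
  expr <- as.matrix(expr)
  labels <- as.integer(labels)
  stopifnot(ncol(expr) == length(labels))
  if (sum(labels == 1) < 2 || sum(labels == 0) < 2) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  if (log_transform) expr <- log2(expr + 1)
  i1 <- labels == 1; i0 <- labels == 0
  pv <- apply(expr, 1, function(x) {
    if (stats::var(x[i1]) == 0 && stats::var(x[i0]) == 0) return(1)
    stats::t.test(x[i1], x[i0], var.equal = TRUE)$p.value
  })
  fc <- (rowMeans(expr[, i1, drop = FALSE]) + eps) /
        (rowMeans(expr[, i0, drop = FALSE]) + eps)
  retained <- pv < p_cutoff & abs(log2(fc)) > log2(fc_cutoff)
  if (!any(retained)) message("t-test/fold-change filter retained no gene")
  out <- data.frame(gene_id = rownames(expr) %||% paste0("g", seq_len(nrow(expr))),
                    p_value = pv, fold_change = fc, retained = retained,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fit a baseline classifier
#'
#' Trains one of the comparison models on a (typically filtered) expression
#' matrix. The SVM uses an RBF kernel with cost and kernel width optimized on
#' a logarithmic grid by inner 3-fold cross-validation; the random forest and
#' logistic regression run at library defaults.
#'
#' @param kind `"svm"`, `"random_forest"` or `"logistic"`.
#' @param expr Numeric matrix, genes x samples (already filtered).
#' @param labels Binary training labels.
#' @param seed Integer seed.
#' @param cost_grid,gamma_grid SVM search grids.
#' @return A list of class `baseline_model` with a `predict`-style scoring
#'   function in `$score` (takes a genes x samples matrix, returns
#'   positive-class scores).
#' @export
fit_baseline <- function(kind = c("svm", "random_forest", "logistic"),
                         expr, labels, seed = 1L,
                         cost_grid = 10^seq(-3, 3, by = 1.5),
                         gamma_grid = 10^seq(-3, 3, by = 1.5)) {
  kind <- match.arg(kind)
  expr <- as.matrix(expr)
  if (nrow(expr) == 0L) {
    stop("empty gene set; relax the filter thresholds", call. = FALSE)
  }
  labels <- factor(as.integer(labels), levels = c(0, 1))
  xt <- t(expr)
  colnames(xt) <- rownames(expr) %||% paste0("g", seq_len(nrow(expr)))
  set.seed(seed)
  if (kind == "svm") {
    gamma_grid <- gamma_grid / ncol(xt)  # scaled to feature count
    tuned <- e1071::tune(e1071::svm, train.x = xt, train.y = labels,
                         kernel = "radial", probability = TRUE,
                         ranges = list(cost = cost_grid, gamma = gamma_grid),
                         tunecontrol = e1071::tune.control(sampling = "cross",
                                                           cross = 3))
    fit <- tuned$best.model
    score <- function(newx) {
      pr <- attr(stats::predict(fit, t(as.matrix(newx)), probability = TRUE),
                 "probabilities")
      unname(pr[, "1"])
    }
    pars <- tuned$best.parameters
  } else if (kind == "random_forest") {
    fit <- randomForest::randomForest(xt, labels)
    score <- function(newx) {
      unname(stats::predict(fit, t(as.matrix(newx)), type = "prob")[, "1"])
    }
    pars <- NULL
  } else {
    df <- data.frame(.y = labels, xt, check.names = TRUE)
    fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    score <- function(newx) {
      nd <- data.frame(t(as.matrix(newx)), check.names = TRUE)
      unname(suppressWarnings(stats::predict(fit, nd, type = "response")))
    }
    pars <- NULL
  }
  structure(list(kind = kind, fit = fit, score = score, parameters = pars,
                 gene_ids = rownames(expr)),
            class = "baseline_model")
}

#' @export
print.baseline_model <- function(x, ...) {
  cat("Baseline model: ", x$kind, " on ", length(x$gene_ids), " genes\n", sep = "")
  if (!is.null(x$parameters)) {
    cat("  tuned parameters: ",
        paste(names(x$parameters), signif(unlist(x$parameters), 3),
              sep = " = ", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
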