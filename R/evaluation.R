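# Performance metrics and the repeated random-split benchmark.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' scores above a random negative, with ties counting one half.
#'
#' @param labels Binary labels (0/1).
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc(c(0, 0, 1, 1), c(0.1, 0.8, 0.4, 0.9))
auc <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), !anyNA(scores))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("both classes required for AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Repeated random-split benchmark
#'
#' For every split of the plan, fits a model on the training side, scores the
#' validation side, and records the validation AUC. Split failures are
#' excluded with a warning; if more than 10% of splits fail the benchmark
#' errors out.
#'
#' @param model_factory Function `(expr_train, labels_train, seed)` returning
#'   a scoring function `(expr_new) -> numeric scores`.
#' @param expr Expression matrix, genes x samples (columns named by
#'   sample id).
#' @param cohort Labeled cohort covering the plan's samples.
#' @param plan A [make_splits()] plan.
#' @param model Identifier stored in the report.
#' @return A list of class `benchmark_report`: `auc_values`, `auc_mean`,
#'   `auc_se` (sample SD / sqrt(#splits); NA for a single split), `model`,
#'   `endpoint`, `n_splits`.
#' @export
run_benchmark <- function(model_factory, expr, cohort, plan, model = "model") {
  stopifnot(inherits(plan, "split_plan"))
  expr <- as.matrix(expr)
  lab <- stats::setNames(cohort$label, cohort$sample_id)
  aucs <- rep(NA_real_, length(plan$splits))
  for (r in seq_along(plan$splits)) {
    sp <- plan$splits[[r]]
    aucs[r] <- tryCatch({
      scorer <- model_factory(expr[, sp$train, drop = FALSE], lab[sp$train],
                              seed = plan$seed + r)
      auc(lab[sp$validation], scorer(expr[, sp$validation, drop = FALSE]))
    }, error = function(e) NA_real_)
  }
  failed <- sum(is.na(aucs))
  if (failed > 0) {
    warning(failed, " of ", length(aucs), " splits failed and were excluded",
            call. = FALSE)
  }
  if (failed > 0.1 * length(aucs)) {
    stop("more than 10% of the benchmark splits failed", call. = FALSE)
  }
  ok <- aucs[!is.na(aucs)]
  structure(list(auc_values = ok,
                 auc_mean = mean(ok),
                 auc_se = if (length(ok) > 1) stats::sd(ok) / sqrt(length(ok))
                          else NA_real_,
                 model = model,
                 endpoint = attr(cohort, "endpoint") %||% "unknown",
                 n_splits = length(ok), seed = plan$seed),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Benchmark: ", x$model, " on endpoint '", x$endpoint, "', ",
      x$n_splits, " splits\n  mean AUC ", round(x$auc_mean, 4),
      if (!is.na(x$auc_se)) paste0(" (SE ", signif(x$auc_se, 3), ")"),
      "\n", sep = "")
  invisible(x)
}
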