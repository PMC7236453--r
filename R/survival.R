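# Cox proportional-hazards gene selection and risk stratification.
#
# Genes pass a univariate Cox screen (Wald p < 0.05), enter a joint
# multivariate fit, and the jointly significant ones form the signature. The
# risk score of a patient is the Cox linear predictor sum(beta_i * x_i); a
# ROC-derived cutoff (Youden's J, chosen on training data only) splits
# patients into high and low risk. All partial-likelihood fits use the Efron
# approximation for ties. When the joint fit does not converge (more genes
# than events, collinearity), a ridge-penalized Cox model is fitted instead,
# with the penalty chosen by cross-validated partial likelihood.

#' Univariate Cox screen
#'
#' Fits one proportional-hazards model per gene (Efron ties) and reports the
#' Wald test. Genes whose fit is degenerate (constant expression,
#' non-convergence) are skipped with a warning.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param os_days Follow-up time per sample (days).
#' @param event Event indicator per sample (1 = death observed).
#' @param p_cutoff Selection threshold on the Wald p-value (default 0.05).
#' @return A data.frame with `gene_id`, `coef`, `hr` (`exp(coef)`),
#'   `p_value` and `selected`.
#' @export
univariate_cox <- function(expr, os_days, event, p_cutoff = 0.05) {
  expr <- as.matrix(expr)
  stopifnot(ncol(expr) == length(os_days), length(os_days) == length(event))
  if (sum(event) < 2) stop("need at least 2 events", call. = FALSE)
  if (anyNA(os_days) || anyNA(event)) stop("missing survival data", call. = FALSE)
  y <- survival::Surv(os_days, event)
  ctl <- survival::coxph.control()
  n_genes <- nrow(expr)
  coefs <- ps <- rep(NA_real_, n_genes)
  skipped <- character(0)
  for (g in seq_len(n_genes)) {
    x <- expr[g, ]
    if (stats::var(x) == 0) { skipped <- c(skipped, rownames(expr)[g]); next }
    fit <- tryCatch(
      suppressWarnings(survival::coxph.fit(matrix(x, ncol = 1), y,
                                           strata = NULL, offset = NULL,
                                           init = 0, control = ctl,
                                           weights = NULL, method = "efron",
                                           rownames = NULL)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$coefficients) ||
        !is.finite(fit$var[1]) || fit$var[1] <= 0 ||
        abs(fit$coefficients) > 50) {
      skipped <- c(skipped, rownames(expr)[g]); next
    }
    coefs[g] <- fit$coefficients
    ps[g] <- 2 * stats::pnorm(-abs(fit$coefficients / sqrt(fit$var[1])))
  }
  if (length(skipped)) {
    warning(length(skipped), " gene(s) skipped (degenerate or non-convergent fit): ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ...", call. = FALSE)
  }
  out <- data.frame(gene_id = rownames(expr) %||% paste0("g", seq_len(n_genes)),
                    coef = coefs, hr = exp(coefs), p_value = ps,
                    selected = !is.na(ps) & ps < p_cutoff,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# joint Efron coxph fit; NULL when degenerate / non-convergent
.try_coxph <- function(xt, y) {
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(y ~ ., data = as.data.frame(xt), ties = "efron"),
      warning = function(w) {
        if (grepl("converge|infinite|singular|beta may be infinite",
                  conditionMessage(w))) invokeRestart("muffleWarning")
        else invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  if (anyNA(cf) || any(!is.finite(cf)) || any(!is.finite(se)) ||
      any(abs(cf) > 50)) return(NULL)
  fit
}

#' Multivariate Cox signature fit
#'
#' Jointly fits the univariately selected genes; genes with joint Wald
#' p < `p_cutoff` are retained as the signature, whose coefficients are then
#' re-estimated on the retained set. When the standard fit fails to converge
#' (collinearity, more genes than events) the model falls back to
#' ridge-penalized Cox regression with the penalty chosen by cross-validated
#' partial likelihood, in which case every input gene is kept with its
#' shrunken coefficient.
#'
#' @param expr Numeric matrix, selected genes x samples.
#' @param os_days,event Survival outcome per sample.
#' @param p_cutoff Retention threshold on the joint Wald p-value.
#' @param nfolds Folds for the penalized fallback's cross-validation.
#' @return An object of class `cox_risk_model`: `gene_ids`, `betas`,
#'   `cutoff` (NA until [choose_cutoff_roc()]), `fit_mode`
#'   (`"standard"`/`"penalized"`) and `penalty` (the ridge strength, if any).
#' @export
multivariate_cox <- function(expr, os_days, event, p_cutoff = 0.05,
                             nfolds = 5L) {
  expr <- as.matrix(expr)
  stopifnot(ncol(expr) == length(os_days))
  y <- survival::Surv(os_days, event)
  xt <- t(expr)
  colnames(xt) <- rownames(expr) %||% paste0("g", seq_len(nrow(expr)))

  .risk_model <- function(betas, fit_mode, penalty = NA_real_, p_values = NULL) {
    structure(list(gene_ids = names(betas), betas = betas, cutoff = NA_real_,
                   fit_mode = fit_mode, penalty = penalty,
                   p_values = p_values),
              class = "cox_risk_model")
  }

  .penalized <- function(x, why) {
    message("multivariate Cox: ", why, "; fitting ridge-penalized model")
    cv <- glmnet::cv.glmnet(x, y, family = "cox", alpha = 0, nfolds = nfolds)
    betas <- as.numeric(stats::coef(cv, s = "lambda.min"))
    names(betas) <- colnames(x)
    .risk_model(betas, "penalized", penalty = cv$lambda.min)
  }

  fit <- if (ncol(xt) < length(os_days)) .try_coxph(xt, y) else NULL
  if (is.null(fit)) return(.penalized(xt, "standard fit failed to converge"))

  cf <- stats::coef(fit)
  p <- 2 * stats::pnorm(-abs(cf / sqrt(diag(fit$var))))
  keep <- names(cf)[p < p_cutoff]
  if (length(keep) == 0L) {
    stop("no gene reached joint p < ", p_cutoff,
         "; consider a larger cohort or a different endpoint", call. = FALSE)
  }
  if (length(keep) == ncol(xt)) {
    return(.risk_model(cf, "standard", p_values = p))
  }
  refit <- .try_coxph(xt[, keep, drop = FALSE], y)
  if (is.null(refit)) return(.penalized(xt[, keep, drop = FALSE],
                                        "refit on retained genes failed"))
  cf2 <- stats::coef(refit)
  p2 <- 2 * stats::pnorm(-abs(cf2 / sqrt(diag(refit$var))))
  .risk_model(cf2, "standard", p_values = p2)
}

#' @export
print.cox_risk_model <- function(x, ...) {
  cat("Cox risk model (", x$fit_mode, "): ", length(x$gene_ids),
      " signature gene(s)", sep = "")
  if (!is.na(x$cutoff)) cat(", cutoff ", signif(x$cutoff, 4), sep = "")
  cat("\n")
  print(utils::head(data.frame(gene_id = x$gene_ids, beta = unname(x$betas)), 10))
  if (length(x$gene_ids) > 10) cat("... and", length(x$gene_ids) - 10, "more\n")
  invisible(x)
}

#' Risk score of one or more patients
#'
#' The Cox linear predictor `sum(beta_i * x_i)` over the signature genes.
#'
#' @param model A `cox_risk_model`.
#' @param x Named numeric vector of one patient's expression, or a matrix
#'   (genes x samples) covering all signature genes.
#' @return Numeric risk score(s).
#' @export
risk_score <- function(model, x) {
  stopifnot(inherits(model, "cox_risk_model"))
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    miss <- setdiff(model$gene_ids, rownames(x))
    if (length(miss)) stop("missing signature gene(s): ",
                           paste(utils::head(miss, 5), collapse = ", "),
                           call. = FALSE)
    drop(crossprod(x[model$gene_ids, , drop = FALSE], model$betas))
  } else {
    miss <- setdiff(model$gene_ids, names(x))
    if (length(miss)) stop("missing signature gene(s): ",
                           paste(utils::head(miss, 5), collapse = ", "),
                           call. = FALSE)
    sum(model$betas * x[model$gene_ids])
  }
}

#' @export
predict.cox_risk_model <- function(object, newdata, ...) {
  risk_score(object, newdata)
}

#' ROC-optimal classification cutoff (Youden's J)
#'
#' Scans every achievable threshold of the rule `score > cutoff` and returns
#' the one maximizing sensitivity + specificity - 1; ties go to the lowest
#' threshold.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Binary labels (0/1).
#' @return The cutoff value.
#' @export
choose_cutoff_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2L) stop("both classes required", call. = FALSE)
  if (length(unique(scores)) < 2L) stop("scores are constant; no ROC cutoff exists",
                                        call. = FALSE)
  cand <- c(-Inf, sort(unique(scores)))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  j <- vapply(cand, function(cc) {
    pred <- scores > cc
    sum(pred & labels == 1) / npos + sum(!pred & labels == 0) / nneg - 1
  }, numeric(1))
  cand[which.max(j)]  # which.max takes the first (lowest) maximizer
}

#' Assign risk groups
#'
#' Patients scoring strictly above the cutoff are high-risk; a score equal to
#' the cutoff is low-risk.
#'
#' @param scores Numeric risk scores.
#' @param cutoff Finite cutoff (see [choose_cutoff_roc()]).
#' @return Factor with levels `low`, `high`.
#' @export
stratify <- function(scores, cutoff) {
  stopifnot(is.finite(cutoff))
  factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier curves and the two-group log-rank test
#'
#' @param groups Two-level factor (e.g. from [stratify()]).
#' @param os_days,event Survival outcome per sample.
#' @return A list: `fit` (the `survfit` object), `median` (median survival
#'   per group, NA when the curve never reaches 0.5), `chisq` (log-rank
#'   statistic, 1 df) and `p_value`.
#' @export
km_logrank <- function(groups, os_days, event) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("exactly two non-empty groups required",
                                  call. = FALSE)
  ev_by_group <- tapply(event, groups, sum)
  if (any(ev_by_group == 0)) {
    warning("a group has zero events; the log-rank statistic is still computed",
            call. = FALSE)
  }
  df <- data.frame(os_days = os_days, event = event, group = groups)
  fit <- survival::survfit(survival::Surv(os_days, event) ~ group, data = df)
  med <- summary(fit)$table[, "median"]
  names(med) <- sub("^group=", "", names(med))
  sd <- survival::survdiff(survival::Surv(os_days, event) ~ group, data = df)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(fit = fit, median = med, chisq = unname(sd$chisq), p_value = p,
       observed = sd$obs, expected = sd$exp)
}

#' Tune the number of top-scoring genes
#'
#' For each candidate `n`, runs the univariate-then-multivariate Cox
#' selection on the top `n` genes using an inner 70/30 split of the training
#' cohort and measures the risk-score AUC on the inner validation side.
#' Returns the `n` with the highest inner-validation AUC (ties to the
#' smallest `n`). Grid points that fail to produce a signature score NA.
#'
#' @param expr Training expression matrix, genes x samples.
#' @param cohort Training labeled cohort aligned with the columns of `expr`
#'   (needs `label`, `os_days`, `event`).
#' @param scores Gene-score table from [gene_scores()].
#' @param grid Candidate values of n (default 100 to 1000 by 100).
#' @param inner_fraction Inner training fraction (default 0.7).
#' @param seed Seed for the inner split.
#' @return A list with `n` (the chosen value) and `auc` (named vector over
#'   the grid).
#' @export
tune_top_n <- function(expr, cohort, scores, grid = seq(100L, 1000L, by = 100L),
                       inner_fraction = 0.7, seed = 1L) {
  expr <- as.matrix(expr)
  grid <- grid[grid <= nrow(scores)]
  if (length(grid) == 0L) stop("no grid value is <= the number of genes",
                               call. = FALSE)
  if (length(grid) == 1L) return(list(n = grid, auc = stats::setNames(NA_real_,
                                                                      grid)))
  set.seed(seed)
  idx <- .split_indices(cohort$label, inner_fraction)
  aucs <- stats::setNames(rep(NA_real_, length(grid)), grid)
  for (i in seq_along(grid)) {
    genes <- top_n_genes(scores, grid[i])
    res <- tryCatch({
      tr_expr <- expr[genes, idx$train, drop = FALSE]
      uni <- suppressWarnings(univariate_cox(tr_expr, cohort$os_days[idx$train],
                                             cohort$event[idx$train]))
      sel <- uni$gene_id[uni$selected]
      if (length(sel) == 0L) stop("no univariately significant gene")
      mod <- suppressMessages(
        multivariate_cox(tr_expr[sel, , drop = FALSE],
                         cohort$os_days[idx$train], cohort$event[idx$train]))
      sc <- risk_score(mod, expr[genes, idx$test, drop = FALSE])
      auc(cohort$label[idx$test], sc)
    }, error = function(e) NA_real_)
    aucs[i] <- res
  }
  if (all(is.na(aucs))) stop("no grid value yielded a signature", call. = FALSE)
  list(n = grid[which.max(aucs)], auc = aucs)
}
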