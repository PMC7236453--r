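# One-convolutional-layer classifier for wavelet tensors.
#
# Architecture: input (p positions x m channels) -> conv1d (n_filters,
# kernel_length, stride 1, length-preserving zero padding, relu) -> max
# pooling (window pool_window, ceiling padding) -> flatten -> dense
# (dense_units, relu) -> dense(2, softmax). Trained with RMSprop on the
# cross-entropy of the two-class softmax. Implemented directly on BLAS
# matrix products: the convolution is an im2col gather followed by a single
# GEMM per batch.

#' CNN configuration
#'
#' Hyperparameters of the one-convolutional-layer classifier. Defaults follow
#' the architecture used throughout the package: 64 filters of length 8,
#' max-pooling window 8 (so a 26,270-position input yields 3,284 pooled
#' features), a 32-unit dense layer, RMSprop at learning rate 1e-4, 50
#' epochs, batch size 16.
#'
#' @param n_filters Number of convolutional filters.
#' @param kernel_length Filter length (positions).
#' @param pool_window Max-pooling window; pooled feature count is
#'   `ceiling(p / pool_window)`.
#' @param dense_units Width of the fully connected hidden layer.
#' @param learning_rate,rho,epsilon RMSprop parameters.
#' @param epochs,batch_size Training schedule.
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(n_filters = 64L, kernel_length = 8L, pool_window = 8L,
                       dense_units = 32L, learning_rate = 1e-4, rho = 0.9,
                       epsilon = 1e-8, epochs = 50L, batch_size = 16L) {
  stopifnot(n_filters >= 1, kernel_length >= 1, pool_window >= 1,
            dense_units >= 1, learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(list(n_filters = as.integer(n_filters),
                 kernel_length = as.integer(kernel_length),
                 pool_window = as.integer(pool_window),
                 dense_units = as.integer(dense_units),
                 learning_rate = learning_rate, rho = rho, epsilon = epsilon,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size)),
            class = "cnn_config")
}

#' Describe the network for a given input shape
#'
#' Lays out the layer stack for an input of `p` coefficient positions and `m`
#' channels without fitting anything; useful for checking the pooled-feature
#' arithmetic.
#'
#' @param config A [cnn_config()].
#' @param p Number of input positions (genes).
#' @param m Number of input channels (decomposition levels).
#' @return A list of class `cnn_model` with element `f`, the pooled-feature
#'   count `ceiling(p / pool_window)`.
#' @export
#' @examples
#' build_cnn(cnn_config(), p = 26270, m = 3)$f  # 3284
build_cnn <- function(config = cnn_config(), p, m) {
  stopifnot(inherits(config, "cnn_config"), m >= 1)
  if (p < config$pool_window) {
    stop("input length p = ", p, " is smaller than the pooling window ",
         config$pool_window, call. = FALSE)
  }
  f <- as.integer(ceiling(p / config$pool_window))
  structure(list(config = config, p = as.integer(p), m = as.integer(m), f = f),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cfg <- x$config
  cat("CNN architecture for input ", x$p, " x ", x$m, ":\n",
      "  conv1d:  ", cfg$n_filters, " filters x ", cfg$kernel_length,
      " taps, relu, same padding -> ", x$p, " x ", cfg$n_filters, "\n",
      "  maxpool: window ", cfg$pool_window, ", ceiling -> ", x$f, " x ",
      cfg$n_filters, "\n",
      "  dense:   ", cfg$dense_units, " units, relu\n",
      "  output:  2 units, softmax\n", sep = "")
  invisible(x)
}

# ---- internal tensor plumbing -------------------------------------------

.coeff_array <- function(x) {
  if (inherits(x, "wavelet_tensor")) x <- x$coeffs
  if (length(dim(x)) != 3L) stop("expected a samples x positions x levels array",
                                 call. = FALSE)
  x
}

# gather index turning a zero-padded (P x m) sample into kernel columns:
# rows are (tap, channel) pairs, columns are output positions
.im2col_index <- function(p, m, kl) {
  P <- p + kl - 1L
  k <- rep(seq_len(kl), m)
  c_ <- rep(seq_len(m), each = kl)
  t(outer(seq_len(p), k + (c_ - 1L) * P - 1L, "+"))  # (kl*m) x p
}

# kernel-column matrix for the given samples: (kl*m) x (p * length(samples))
.im2col <- function(xarr, samples, config) {
  p <- dim(xarr)[2]; m <- dim(xarr)[3]
  kl <- config$kernel_length
  pl <- (kl - 1L) %/% 2L
  P <- p + kl - 1L
  B <- length(samples)
  Xp <- array(0, c(P, m, B))
  Xp[pl + seq_len(p), , ] <- aperm(xarr[samples, , , drop = FALSE], c(2, 3, 1))
  dim(Xp) <- c(P * m, B)
  M <- Xp[as.vector(.im2col_index(p, m, kl)), , drop = FALSE]
  dim(M) <- c(kl * m, p * B)
  M
}

.glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

.init_params <- function(config, p, m, f) {
  kl <- config$kernel_length; Fn <- config$n_filters; d <- config$dense_units
  list(W  = .glorot(Fn, kl * m, kl * m, kl * Fn), b  = numeric(Fn),
       W1 = .glorot(d, Fn * f, Fn * f, d),        b1 = numeric(d),
       W2 = .glorot(2L, d, d, 2L),                b2 = numeric(2L))
}

#' Train the convolutional classifier
#'
#' Fits the one-convolutional-layer network on a wavelet tensor by RMSprop
#' on the two-class cross-entropy. Fully reproducible given `seed`.
#'
#' @param x A `wavelet_tensor` (see [decompose_cohort()]) or an array of
#'   shape samples x positions x levels.
#' @param labels Binary labels (0/1), one per sample.
#' @param config A [cnn_config()].
#' @param seed Integer seed for initialization and batch shuffling.
#' @return An object of class `trained_cnn`: fitted parameters, the config,
#'   the input shape, and the per-epoch mean training loss in `history`.
#' @export
train_cnn <- function(x, labels, config = cnn_config(), seed = 1L) {
  xarr <- .coeff_array(x)
  labels <- as.integer(labels)
  n <- dim(xarr)[1]; p <- dim(xarr)[2]; m <- dim(xarr)[3]
  if (length(labels) != n) stop("label count (", length(labels),
                                ") does not match sample count (", n, ")",
                                call. = FALSE)
  if (length(unique(labels)) < 2L) stop("training labels contain a single class",
                                        call. = FALSE)
  model <- build_cnn(config, p, m)
  f <- model$f
  set.seed(seed)
  params <- .init_params(config, p, m, f)
  perms <- vapply(seq_len(config$epochs), function(i) sample.int(n), integer(n))
  K_all <- .im2col(xarr, seq_len(n), config)
  res <- .cnn_train_cpp(K_all, labels, as.integer(p), params,
                        matrix(perms, nrow = n), min(config$batch_size, n),
                        config$learning_rate, config$rho, config$epsilon,
                        config$pool_window)
  params <- res$params
  for (nm in c("b", "b1", "b2")) params[[nm]] <- drop(params[[nm]])
  structure(list(params = params, config = config, p = as.integer(p),
                 m = as.integer(m), f = f, history = drop(res$history),
                 seed = as.integer(seed)),
            class = "trained_cnn")
}

#' @export
print.trained_cnn <- function(x, ...) {
  cat("Trained CNN (", x$p, " positions x ", x$m, " channels, ",
      x$config$n_filters, " filters, ", x$f, " pooled features); final loss ",
      signif(utils::tail(x$history, 1), 4), " after ", length(x$history),
      " epochs\n", sep = "")
  invisible(x)
}

.check_shape <- function(model, xarr) {
  if (dim(xarr)[2] != model$p || dim(xarr)[3] != model$m) {
    stop("input shape ", dim(xarr)[2], " x ", dim(xarr)[3],
         " does not match the model's ", model$p, " x ", model$m, call. = FALSE)
  }
}

#' Positive-class probabilities
#'
#' Softmax probability of the high-risk class for each sample in the tensor.
#'
#' @param model A `trained_cnn`.
#' @param x A `wavelet_tensor` or samples x positions x levels array whose
#'   shape matches the model input.
#' @param chunk Samples per forward pass (memory control).
#' @return Numeric vector in `[0, 1]`, one value per sample.
#' @export
predict_proba <- function(model, x, chunk = 64L) {
  stopifnot(inherits(model, "trained_cnn"))
  xarr <- .coeff_array(x)
  .check_shape(model, xarr)
  n <- dim(xarr)[1]
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    sel <- start:min(start + chunk - 1L, n)
    K <- .im2col(xarr, sel, model$config)
    fw <- .cnn_forward_cpp(K, model$params, model$p, length(sel),
                           model$config$pool_window, TRUE)
    out[sel] <- fw$probs[2L, ]
  }
  names(out) <- dimnames(xarr)[[1]]
  out
}

#' @export
predict.trained_cnn <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  pr <- predict_proba(object, newdata)
  if (type == "prob") pr else as.integer(pr > 0.5)
}

#' Representative feature matrix
#'
#' Post-pooling activations averaged over the filter channels: the features
#' x samples matrix X that the gene-scoring step maps back onto genes.
#'
#' @param model A `trained_cnn` (or an `swt_cnn` fit, in which case `x` is an
#'   expression matrix).
#' @param x Tensor (or expression matrix) of the samples to featurize.
#' @param chunk Samples per forward pass.
#' @return Numeric matrix, pooled features x samples.
#' @export
extract_representative_features <- function(model, x, chunk = 64L) {
  UseMethod("extract_representative_features")
}

#' @export
extract_representative_features.trained_cnn <- function(model, x, chunk = 64L) {
  xarr <- .coeff_array(x)
  .check_shape(model, xarr)
  n <- dim(xarr)[1]
  X <- matrix(0, model$f, n)
  for (start in seq(1L, n, by = chunk)) {
    sel <- start:min(start + chunk - 1L, n)
    K <- .im2col(xarr, sel, model$config)
    fw <- .cnn_forward_cpp(K, model$params, model$p, length(sel),
                           model$config$pool_window, FALSE)
    # mean over the filter axis; pooled is filters x (features * batch)
    X[, sel] <- matrix(colMeans(fw$pooled), model$f, length(sel))
  }
  colnames(X) <- dimnames(xarr)[[1]]
  X
}

#' Best-of-several-runs training
#'
#' Trains `runs` networks with derived seeds on an inner 70/30 split of the
#' supplied training data and keeps the one with the highest
#' inner-validation AUC (ties broken by run order). This repeated-training
#' selection stands in for early stopping.
#'
#' @param x Tensor of the training samples.
#' @param labels Binary training labels.
#' @param config A [cnn_config()].
#' @param runs Number of training runs (default 100).
#' @param seed Integer seed; run seeds are derived from it.
#' @param inner_fraction Fraction of the training data each run is fitted on.
#' @return The winning `trained_cnn`, with elements `inner_auc` (its
#'   inner-validation AUC) and `run` (its index) added.
#' @export
repeat_train_select_best <- function(x, labels, config = cnn_config(),
                                     runs = 100L, seed = 1L,
                                     inner_fraction = 0.7) {
  xarr <- .coeff_array(x)
  labels <- as.integer(labels)
  stopifnot(runs >= 1)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, runs)
  if (runs == 1L) {
    fit <- train_cnn(xarr, labels, config, seed = run_seeds[1])
    fit$inner_auc <- NA_real_; fit$run <- 1L
    return(fit)
  }
  set.seed(seed)
  idx <- .split_indices(labels, inner_fraction)
  best <- NULL; best_auc <- -Inf; best_run <- NA_integer_
  for (r in seq_len(runs)) {
    fit <- train_cnn(xarr[idx$train, , , drop = FALSE], labels[idx$train],
                     config, seed = run_seeds[r])
    a <- auc(labels[idx$test],
             predict_proba(fit, xarr[idx$test, , , drop = FALSE]))
    if (a > best_auc) { best <- fit; best_auc <- a; best_run <- r }
  }
  best$inner_auc <- best_auc
  best$run <- best_run
  best
}
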