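# Stationary (undecimated, a-trous) wavelet transform.
#
# Level j filters the previous approximation with the analysis pair dilated
# by u = 2^(j-1), under periodic extension, so every band keeps the full
# signal length. With the filter banks in this package the synthesis pair
# satisfies conv(rec, dec) summed over the two channels = 2 * z^-(L-1),
# which fixes the analysis offset u*L/2 and synthesis offset u*(L/2-1)
# used below and gives exact perfect reconstruction.

# periodic filtering of the rows of x (positions x columns) with filter h
# dilated by u and phase offset `off` (in samples)
.periodic_filter <- function(x, h, u, off) {
  n <- nrow(x)
  y <- matrix(0, n, ncol(x))
  base <- 0:(n - 1L)
  for (k in seq_along(h)) {
    if (h[k] == 0) next
    idx <- (base - u * (k - 1L) + off) %% n + 1L
    y <- y + h[k] * x[idx, , drop = FALSE]
  }
  y
}

# full decomposition of the columns of x; returns per-level approximation
# and detail bands, each positions x columns
.swt_full <- function(x, wavelet, levels) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n %% 2^levels != 0) {
    stop("signal length ", n, " is not divisible by 2^levels = ", 2^levels,
         "; pad first (see pad_profile)", call. = FALSE)
  }
  fb <- .get_filters(wavelet)
  L <- length(fb$dec_lo)
  ca <- vector("list", levels)
  cd <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    u <- 2^(j - 1L)
    off <- u * (L %/% 2L)
    ca[[j]] <- .periodic_filter(a, fb$dec_lo, u, off)
    cd[[j]] <- .periodic_filter(a, fb$dec_hi, u, off)
    a <- ca[[j]]
  }
  list(ca = ca, cd = cd)
}

# inverse of .swt_full (used by the reconstruction tests; not a public API)
.iswt_full <- function(ca, cd, wavelet) {
  fb <- .get_filters(wavelet)
  L <- length(fb$rec_lo)
  levels <- length(ca)
  a <- ca[[levels]]
  for (j in rev(seq_len(levels))) {
    u <- 2^(j - 1L)
    off <- u * (L %/% 2L - 1L)
    a <- 0.5 * (.periodic_filter(a, fb$rec_lo, u, off) +
                .periodic_filter(cd[[j]], fb$rec_hi, u, off))
  }
  a
}

#' Pad an expression profile for wavelet decomposition
#'
#' Extends a profile at the tail by symmetric reflection to the next multiple
#' of `2^levels`, the length required by a `levels`-deep stationary wavelet
#' transform.
#'
#' @param x Numeric vector (one sample's expression profile).
#' @param levels Number of decomposition levels (default 3).
#' @return A list with `x` (the padded vector), and `pad_record`, itself a
#'   list with `orig_length` and `pad` so coefficients can later be truncated
#'   back to the original positions.
#' @export
#' @examples
#' pad_profile(rnorm(26270), 3)$pad_record
pad_profile <- function(x, levels = 3L) {
  p <- length(x)
  stopifnot(p >= 1L)
  target <- as.integer(ceiling(p / 2^levels) * 2^levels)
  pad <- target - p
  if (pad > 0) {
    # symmetric (half-sample) extension, cycled for very short inputs
    j <- (p + seq_len(pad) - 1L) %% (2L * p)
    ext <- ifelse(j < p, j + 1L, 2L * p - j)
    x <- c(x, x[ext])
  }
  list(x = x, pad_record = list(orig_length = p, pad = pad))
}

#' Stationary wavelet approximation coefficients of one profile
#'
#' Computes the approximation (low-frequency) bands `cA_1 ... cA_levels` of
#' the stationary wavelet transform of `x` under periodic extension, with the
#' analysis filters dilated by `2^(j-1)` at level `j`. Detail bands are
#' discarded. The input length must be divisible by `2^levels`
#' (use [pad_profile()]); coefficients are truncated to the first
#' `orig_length` positions.
#'
#' @param x Numeric vector whose length is divisible by `2^levels`.
#' @param wavelet One of [wavelet_names()].
#' @param levels Number of decomposition levels (default 3).
#' @param orig_length Number of leading positions to keep (default: all).
#' @return Numeric matrix, `levels` rows x `orig_length` columns; row `j`
#'   holds `cA_j`.
#' @export
#' @examples
#' swt_approximations(rep(2, 16), "db1", 1)  # every coefficient 2*sqrt(2)
swt_approximations <- function(x, wavelet, levels = 3L,
                               orig_length = length(x)) {
  dec <- .swt_full(matrix(as.numeric(x), ncol = 1), wavelet, levels)
  out <- matrix(0, levels, orig_length)
  for (j in seq_len(levels)) out[j, ] <- dec$ca[[j]][seq_len(orig_length), 1]
  rownames(out) <- paste0("cA", seq_len(levels))
  out
}

#' Decompose every sample of an expression matrix
#'
#' Applies [pad_profile()] and the stationary wavelet transform to each
#' sample's profile and stacks the per-level approximation coefficients into
#' the tensor consumed by the convolutional classifier.
#'
#' @param expr Numeric matrix, genes x samples (rownames = gene ids,
#'   colnames = sample ids).
#' @param wavelet One of [wavelet_names()].
#' @param levels Number of decomposition levels (default 3).
#' @return An object of class `wavelet_tensor`: a list with `coeffs`
#'   (array, samples x positions x levels), `sample_ids`, `wavelet`,
#'   `levels` and `pad_record`.
#' @export
decompose_cohort <- function(expr, wavelet, levels = 3L) {
  expr <- as.matrix(expr)
  p <- nrow(expr)
  n <- ncol(expr)
  padded <- apply(expr, 2, function(col) pad_profile(col, levels)$x)
  padded <- matrix(padded, ncol = n)  # guard 1-row inputs collapsed by apply
  pr <- pad_profile(expr[, 1], levels)$pad_record
  dec <- .swt_full(padded, wavelet, levels)
  coeffs <- array(0, dim = c(n, p, levels),
                  dimnames = list(colnames(expr), NULL,
                                  paste0("cA", seq_len(levels))))
  for (j in seq_len(levels)) coeffs[, , j] <- t(dec$ca[[j]][seq_len(p), , drop = FALSE])
  structure(list(coeffs = coeffs, sample_ids = colnames(expr),
                 wavelet = wavelet, levels = levels, pad_record = pr),
            class = "wavelet_tensor")
}

#' @export
print.wavelet_tensor <- function(x, ...) {
  d <- dim(x$coeffs)
  cat("Stationary wavelet tensor (", x$wavelet, "): ",
      d[1], " samples x ", d[2], " positions x ", d[3], " levels\n", sep = "")
  invisible(x)
}

# raw-input tensor (no wavelet transform): single channel holding the
# untransformed profile, used for with/without-SWT comparisons
.raw_tensor <- function(expr) {
  expr <- as.matrix(expr)
  coeffs <- array(t(expr), dim = c(ncol(expr), nrow(expr), 1L),
                  dimnames = list(colnames(expr), NULL, "raw"))
  structure(list(coeffs = coeffs, sample_ids = colnames(expr),
                 wavelet = "none", levels = 1L,
                 pad_record = list(orig_length = nrow(expr), pad = 0L)),
            class = "wavelet_tensor")
}

#' Select the best wavelet function on training data
#'
#' Trains one SWT-CNN per candidate wavelet on an inner 70/30 split of the
#' training cohort and returns the candidate with the highest
#' inner-validation AUC (ties broken by list order). Validation data must be
#' kept outside this search.
#'
#' @param expr Training expression matrix (genes x samples).
#' @param labels Binary training labels (0/1), one per sample.
#' @param candidates Character vector of wavelet names to evaluate
#'   (default: all twelve).
#' @param levels Decomposition levels (default 3).
#' @param config CNN configuration from [cnn_config()].
#' @param inner_fraction Fraction of the training data used to fit the inner
#'   models (default 0.7).
#' @param seed Integer seed controlling the inner split and training.
#' @return A list with `wavelet` (the selected name) and `auc` (named vector
#'   of inner-validation AUCs, one per candidate).
#' @export
select_wavelet <- function(expr, labels, candidates = wavelet_names(),
                           levels = 3L, config = cnn_config(),
                           inner_fraction = 0.7, seed = 1L) {
  stopifnot(all(candidates %in% wavelet_names()))
  if (length(candidates) == 1L) {
    return(list(wavelet = candidates, auc = stats::setNames(NA_real_, candidates)))
  }
  labels <- as.integer(labels)
  set.seed(seed)
  idx <- .split_indices(labels, inner_fraction)
  aucs <- stats::setNames(numeric(length(candidates)), candidates)
  for (wv in candidates) {
    tens <- decompose_cohort(expr, wv, levels)
    fit <- train_cnn(tens$coeffs[idx$train, , , drop = FALSE],
                     labels[idx$train], config = config, seed = seed)
    sc <- predict_proba(fit, tens$coeffs[idx$test, , , drop = FALSE])
    aucs[wv] <- auc(labels[idx$test], sc)
  }
  list(wavelet = candidates[which.max(aucs)], auc = aucs)
}
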