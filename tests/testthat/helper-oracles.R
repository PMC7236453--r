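# Independent oracles shared by module and acceptance tests. These recompute
# results by brute force / explicit formulas and never call the code paths
# they check.

# a-trous stationary wavelet decomposition by scalar loops under periodic
# extension (filter taps dilated by 2^(j-1), phase offset u*L/2)
oracle_swt_brute <- function(x, wavelet, levels) {
  fb <- swtcnn:::.wavelet_filters[[wavelet]]
  h <- fb$dec_lo
  L <- length(h); N <- length(x)
  ca <- matrix(0, levels, N)
  a <- x
  for (j in seq_len(levels)) {
    u <- 2^(j - 1)
    anew <- numeric(N)
    for (i in seq_len(N)) {
      s <- 0
      for (k in seq_len(L)) {
        s <- s + h[k] * a[((i - 1) - u * (k - 1) + u * (L %/% 2)) %% N + 1]
      }
      anew[i] <- s
    }
    ca[j, ] <- anew
    a <- anew
  }
  ca
}

# explicit Efron partial log-likelihood for a single covariate
oracle_efron_loglik <- function(b, time, event, x) {
  ll <- 0
  for (t in unique(sort(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sR <- sum(exp(x[R] * b))
    sD <- sum(exp(x[D] * b))
    ll <- ll + sum(x[D]) * b -
      sum(vapply(0:(d - 1), function(l) log(sR - (l / d) * sD), numeric(1)))
  }
  ll
}
oracle_efron_mle <- function(time, event, x) {
  stats::optimize(function(b) oracle_efron_loglik(b, time, event, x),
                  c(-15, 15), maximum = TRUE, tol = 1e-10)$maximum
}

# least squares row by row via an explicit SVD pseudoinverse of X X^T
oracle_score_matrix <- function(Y, X) {
  G <- X %*% t(X)
  s <- svd(G)
  tol <- max(dim(G)) * .Machine$double.eps * max(s$d)
  dinv <- ifelse(s$d > tol, 1 / s$d, 0)
  Y %*% t(X) %*% (s$v %*% (dinv * t(s$u)))
}

# AUC by exhaustive positive-negative pair enumeration (ties count 1/2)
oracle_auc_pairs <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# two-group log-rank chi-square by explicit observed-minus-expected tabulation
oracle_logrank_chisq <- function(grp, time, event) {
  lev <- sort(unique(grp))[1]
  OmE <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == lev)
    n <- sum(at); n1 <- sum(at & grp == lev)
    OmE <- OmE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  OmE^2 / V
}

# gene-score ranking of planted genes for one simulated cohort: runs the
# SWT -> CNN -> representative-features -> least-squares scoring chain on the
# training split and returns the number of planted genes in the top `top`
run_scoring_chain <- function(sim_cfg, seed, epochs = 25L, top = 100L) {
  sim <- simulate_cohort(sim_cfg)
  coh <- suppressMessages(derive_survival_labels(sim$clinical))
  expr <- sim$expression[, coh$sample_id]
  set.seed(seed)
  idx <- swtcnn:::.split_indices(coh$label, 0.7)
  tr <- expr[, idx$train]
  fit <- swt_cnn(tr, coh$label[idx$train], wavelet = "db3",
                 config = cnn_config(epochs = epochs), seed = seed)
  X <- extract_representative_features(fit, tr)
  sc <- gene_scores(score_matrix(tr, X))
  sum(sim$truth$planted %in% top_n_genes(sc, top))
}
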