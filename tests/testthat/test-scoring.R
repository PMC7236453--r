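test_that("score_matrix solves minimum-norm least squares (oracle + identities)", {
  set.seed(3)
  # rank-deficient case: more features than samples, the pipeline's regime
  for (rep in 1:5) {
    Y <- matrix(rnorm(40 * 20), 40, 20)
    X <- matrix(rnorm(12 * 20), 12, 20)
    B <- score_matrix(Y, X)
    O <- oracle_score_matrix(Y, X)
    expect_lt(norm(B - O, "F") / norm(O, "F"), 1e-6)
    # residual orthogonal to the rows of X
    expect_lt(max(abs((Y - B %*% X) %*% t(X))), 1e-8)
  }
  # square invertible X: exact identity B = Y X^-1
  Xs <- matrix(rnorm(64), 8, 8) + diag(8)
  Y <- matrix(rnorm(5 * 8), 5, 8)
  expect_equal(score_matrix(Y, Xs), Y %*% solve(Xs), tolerance = 1e-8,
               ignore_attr = TRUE)
  # Y = X gives the identity matrix
  expect_equal(score_matrix(Xs, Xs), diag(8), tolerance = 1e-8,
               ignore_attr = TRUE)
  # scale equivariance
  X <- matrix(rnorm(6 * 10), 6, 10)
  Y <- matrix(rnorm(4 * 10), 4, 10)
  expect_equal(score_matrix(3.7 * Y, X), 3.7 * score_matrix(Y, X))
  expect_error(score_matrix(Y, X[, 1:5]), "samples")
})

test_that("gene scores are row means with deterministic tie-broken ranks", {
  B <- rbind(a = rep(1, 4), z = c(2, 2, 2, 2), m = c(0, 4, 2, 2))
  sc <- gene_scores(B)
  expect_equal(sc$score[sc$gene_id == "a"], 1)
  # z and m tie at 2: lexical order puts m before z, both ahead of a
  expect_identical(sc$gene_id, c("m", "z", "a"))
  expect_identical(sc$rank, 1:3)
  # score vector length equals gene count
  set.seed(1)
  B2 <- matrix(rnorm(200 * 3), 200)
  expect_identical(nrow(gene_scores(B2)), 200L)
})

test_that("top_n_genes honours rank order and bounds", {
  B <- matrix(c(3, 1, 2), 3, 2, dimnames = list(c("g1", "g2", "g3"), NULL))
  sc <- gene_scores(B)
  expect_identical(top_n_genes(sc, 1), "g1")
  expect_identical(top_n_genes(sc, 3), c("g1", "g3", "g2"))
  expect_error(top_n_genes(sc, 4), "between")
  expect_error(top_n_genes(sc, 0), "between")
})

test_that("kendall tau stability matches a brute-force pair count", {
  # exhaustive concordant/discordant enumeration (tau-a on tie-free data)
  tau_brute <- function(a, b) {
    conc <- disc <- 0
    n <- length(a)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      s <- sign(a[i] - a[j]) * sign(b[i] - b[j])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
    (conc - disc) / choose(n, 2)
  }
  set.seed(8)
  genes <- paste0("g", 1:10)
  r1 <- setNames(sample(10), genes)
  r2 <- setNames(sample(10), genes)
  got <- kendall_tau_stability(list(r1, r2), k = 10)
  expect_equal(got$tau, tau_brute(r1[genes], r2[genes]))
  # identical lists -> tau 1; reversed -> tau -1
  expect_equal(kendall_tau_stability(list(r1, r1), k = 10)$tau, 1)
  rrev <- setNames(11 - r1, names(r1))
  expect_equal(kendall_tau_stability(list(r1, rrev), k = 10)$tau, -1)
  # disjoint universes refused
  r3 <- setNames(1:5, paste0("x", 1:5))
  expect_error(kendall_tau_stability(list(r1, r3)), "universe")
})

test_that("wavelet preprocessing improves the rank of low-expressed informative genes", {
  # mirrors the magnitude-bias observation: scored on raw profiles, lowly
  # expressed prognostic genes sink by sheer magnitude; the wavelet channels
  # soften that, so their median rank should not be worse
  med_rank <- function(seed, wavelet) {
    sim <- simulate_cohort(sim_config(n_samples = 160, n_genes = 512,
                                      n_prognostic = 20, beta = 2,
                                      n_low_informative = 10,
                                      n_high_nuisance = 10, seed = seed))
    coh <- suppressMessages(derive_survival_labels(sim$clinical))
    expr <- sim$expression[, coh$sample_id]
    fit <- swt_cnn(expr, coh$label, wavelet = wavelet,
                   config = cnn_config(n_filters = 16, epochs = 10),
                   seed = seed)
    X <- extract_representative_features(fit, expr)
    sc <- gene_scores(score_matrix(expr, X))
    rk <- setNames(sc$rank, sc$gene_id)
    median(rk[sim$truth$low_informative])
  }
  for (s in c(1, 2)) {
    expect_lte(med_rank(s, "db3"), med_rank(s, "none"))
  }
})
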