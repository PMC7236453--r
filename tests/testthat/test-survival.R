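test_that("univariate Cox matches explicit Efron partial-likelihood maximization", {
  # 6-patient toy set: times 1..6, all events, two-group covariate
  # (groups interleaved so the partial likelihood has an interior maximum)
  x <- c(0, 1, 0, 1, 0, 1)
  got <- univariate_cox(matrix(x, 1, dimnames = list("g1", NULL)),
                        os_days = 1:6, event = rep(1, 6))
  expect_equal(got$coef, oracle_efron_mle(1:6, rep(1, 6), x), tolerance = 1e-6)
  expect_equal(got$hr, exp(got$coef))

  # random small datasets with tied times (Efron correction active)
  set.seed(14)
  for (rep in 1:20) {
    n <- 8
    time <- sample(1:6, n, replace = TRUE)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) < 2) event[1:2] <- 1
    x <- rnorm(n, sd = 0.5)
    ref <- oracle_efron_mle(time, event, x)
    if (abs(ref) > 5) next  # near-boundary likelihood: estimate not stable
    got <- univariate_cox(matrix(x, 1), time, event)
    expect_lt(abs(got$coef - ref), 1e-6)
  }
})

test_that("univariate Cox skips degenerate genes and recovers planted effects", {
  set.seed(2)
  expr <- rbind(flat = rep(2, 30), ok = rnorm(30))
  expect_warning(res <- univariate_cox(expr, rexp(30, 0.01), rbinom(30, 1, 0.8)),
                 "skipped")
  expect_true(is.na(res$coef[res$gene_id == "flat"]))
  expect_false(is.na(res$coef[res$gene_id == "ok"]))

  # beta = 1 recovered within +-0.3 at n = 500 in at least 9/10 seeds
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 500
    x <- rnorm(n)
    time <- rexp(n, rate = 0.001 * exp(x))
    cens <- runif(n, 0, quantile(time, 0.9) * 2)
    res <- univariate_cox(matrix(x, 1), pmin(time, cens),
                          as.integer(time <= cens))
    if (abs(res$coef - 1) <= 0.3) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("multivariate Cox retains strong genes and falls back to ridge", {
  set.seed(7)
  n <- 500
  g1 <- rnorm(n); g2 <- rnorm(n)
  time <- rexp(n, rate = 0.001 * exp(1 * g1 - 0.8 * g2))
  event <- rep(1L, n)
  expr <- rbind(g1 = g1, g2 = g2)
  mod <- multivariate_cox(expr, time, event)
  expect_identical(mod$fit_mode, "standard")
  expect_setequal(mod$gene_ids, c("g1", "g2"))
  expect_gt(mod$betas["g1"], 0)
  expect_lt(mod$betas["g2"], 0)

  # single selected gene reduces to the univariate fit
  uni <- univariate_cox(expr["g1", , drop = FALSE], time, event)
  solo <- multivariate_cox(expr["g1", , drop = FALSE], time, event)
  expect_equal(unname(solo$betas), uni$coef, tolerance = 1e-8)

  # perfectly collinear duplicates force the penalized path
  dup <- rbind(a = g1, b = g1)
  pen <- suppressMessages(multivariate_cox(dup, time, event))
  expect_identical(pen$fit_mode, "penalized")
  expect_length(pen$betas, 2)
  expect_true(is.finite(pen$penalty))
})

test_that("risk scores are the Cox linear predictor", {
  mod <- structure(list(gene_ids = c("a", "b", "c"),
                        betas = c(a = 1, b = -1, c = 0.5),
                        cutoff = NA_real_, fit_mode = "standard"),
                   class = "cox_risk_model")
  expect_equal(risk_score(mod, c(a = 2, b = 3, c = 4)), 1)
  m <- matrix(c(2, 3, 4, 1, 1, 1), 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(unname(risk_score(mod, m)), c(1, 0.5))
  expect_equal(unname(predict(mod, m)), c(1, 0.5))
  mod0 <- mod; mod0$betas[] <- 0
  expect_equal(risk_score(mod0, c(a = 9, b = 9, c = 9)), 0)
  expect_error(risk_score(mod, c(a = 1, b = 2)), "missing signature")
  # monotonicity in a positive-beta gene
  lo <- risk_score(mod, c(a = 1, b = 0, c = 0))
  hi <- risk_score(mod, c(a = 2, b = 0, c = 0))
  expect_gt(hi, lo)
})

test_that("Youden cutoff equals an exhaustive scan and stratification is strict", {
  # perfectly separated toy sets
  sc <- c(1, 2, 8, 9); lab <- c(0, 0, 1, 1)
  cut <- choose_cutoff_roc(sc, lab)
  expect_true(all((sc > cut) == (lab == 1)))
  expect_equal(choose_cutoff_roc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 2)

  # 20-point set vs brute-force threshold scan
  set.seed(4)
  sc <- round(rnorm(20), 2)
  lab <- rbinom(20, 1, plogis(2 * sc))
  if (length(unique(lab)) == 1) lab[1] <- 1 - lab[1]
  youden <- function(cc) {
    mean(sc[lab == 1] > cc) + mean(sc[lab == 0] <= cc) - 1
  }
  cut <- choose_cutoff_roc(sc, lab)
  grid <- seq(min(sc) - 1, max(sc) + 1, by = 0.001)
  expect_equal(youden(cut), max(vapply(grid, youden, numeric(1))),
               tolerance = 1e-12)
  expect_error(choose_cutoff_roc(rep(1, 5), c(0, 1, 0, 1, 0)), "constant")

  # equality goes to the low-risk group; group sizes conserved
  g <- stratify(c(1, 2, 3), cutoff = 2)
  expect_identical(as.character(g), c("low", "low", "high"))
  expect_identical(length(g), 3L)
  expect_true(all(stratify(c(0, 1), cutoff = 5) == "low"))
})

test_that("log-rank matches hand tabulation and KM medians are step-function reads", {
  # identical event times split across groups -> statistic exactly 0
  km0 <- km_logrank(rep(c("a", "b"), 5), rep(1:5, each = 2), rep(1, 10))
  expect_equal(km0$chisq, 0, tolerance = 1e-12)

  # median survival of events {2, 4, 6} with no censoring is 4
  km1 <- km_logrank(factor(c(rep("x", 3), rep("y", 3))),
                    c(2, 4, 6, 10, 12, 14), rep(1, 6))
  expect_equal(unname(km1$median["x"]), 4)

  # 10-patient toy set vs explicit observed-minus-expected tabulation
  time <- c(3, 5, 5, 7, 9, 2, 4, 6, 6, 11)
  event <- c(1, 1, 0, 1, 1, 1, 1, 1, 0, 1)
  grp <- rep(c("a", "b"), each = 5)
  OmE <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == "a")
    n <- sum(at); n1 <- sum(at & grp == "a")
    OmE <- OmE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  km2 <- km_logrank(grp, time, event)
  expect_equal(km2$chisq, OmE^2 / V, tolerance = 1e-10)
  expect_equal(km2$p_value, pchisq(OmE^2 / V, 1, lower.tail = FALSE))

  # zero-event group still yields a statistic, with a warning
  expect_warning(km3 <- km_logrank(rep(c("a", "b"), each = 4),
                                   c(1, 2, 3, 4, 5, 6, 7, 8),
                                   c(1, 1, 1, 1, 0, 0, 0, 0)),
                 "zero events")
  expect_true(is.finite(km3$chisq))
})

test_that("tune_top_n is a seeded argmax over the grid", {
  sim <- separable_sim(seed = 17, n = 150, p = 200, beta = 2)
  coh <- suppressMessages(derive_survival_labels(sim$clinical))
  expr <- sim$expression[, coh$sample_id]
  # a simple score table ranking genes by variance (content irrelevant here)
  sc <- gene_scores(matrix(apply(expr, 1, var), ncol = 1,
                           dimnames = list(rownames(expr), NULL)))
  one <- tune_top_n(expr, coh, sc, grid = 50)
  expect_identical(one$n, 50)
  t1 <- tune_top_n(expr, coh, sc, grid = c(50, 100, 150), seed = 3)
  t2 <- tune_top_n(expr, coh, sc, grid = c(50, 100, 150), seed = 3)
  expect_identical(t1$n, t2$n)
  expect_gte(max(t1$auc, na.rm = TRUE), min(t1$auc, na.rm = TRUE))
  expect_identical(unname(t1$auc[as.character(t1$n)]),
                   max(t1$auc, na.rm = TRUE))
})
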