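# Shared fixtures, built in code.

# tiny deterministic expression matrix with named genes/samples
toy_expr <- function(p = 6, n = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(round(exp(rnorm(p * n, 2, 1)), 4), p, n,
              dimnames = list(sprintf("g%02d", 1:p), sprintf("s%02d", 1:n)))
  m
}

# small labelled cohort with survival fields
toy_cohort <- function(n = 20, seed = 1) {
  set.seed(seed)
  df <- data.frame(
    sample_id = sprintf("s%02d", 1:n),
    label = rep(c(0L, 1L), length.out = n),
    os_days = sample(100:2000, n),
    event = rbinom(n, 1, 0.7),
    stringsAsFactors = FALSE
  )
  attr(df, "endpoint") <- "survival3y"
  class(df) <- c("labeled_cohort", "data.frame")
  df
}

# a quick strongly separable simulated cohort for classifier tests
separable_sim <- function(seed = 3, n = 200, p = 512, k = 20, beta = 1.5) {
  simulate_cohort(sim_config(n_samples = n, n_genes = p, n_prognostic = k,
                             beta = beta, seed = seed))
}

# small CNN config so unit tests stay fast
small_cnn <- function(epochs = 10L, ...) {
  cnn_config(n_filters = 8L, kernel_length = 4L, pool_window = 4L,
             dense_units = 8L, epochs = epochs, batch_size = 16L, ...)
}

# write a matrix as a TSV expression file (genes in rows)
write_expr_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
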