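test_that("read_expression handles both orientations and reports bad cells", {
  m <- toy_expr(3, 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expr_tsv(m, path)
  got <- read_expression(path)
  expect_identical(dim(got), c(3L, 2L))
  expect_equal(got, m)

  # transposed file with genes in columns round-trips to the same matrix
  path2 <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = colnames(m), t(m), check.names = FALSE)
  utils::write.table(df, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  got2 <- read_expression(path2, dialect = "genes-in-columns")
  expect_equal(got2, m)

  # negative cell is refused with its location
  bad <- m; bad[2, 1] <- -1.0
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write_expr_tsv(bad, path3)
  expect_error(read_expression(path3), "negative.*g02", ignore.case = TRUE)

  # duplicate gene ids are named in the error
  dup <- m; rownames(dup) <- c("gA", "gA", "gB")
  path4 <- withr::local_tempfile(fileext = ".tsv")
  write_expr_tsv(dup, path4)
  expect_error(read_expression(path4), "duplicate.*gA")
})

test_that("filter_low_expression applies the strict over-half rule", {
  m <- matrix(1, 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  m["a", 1:3] <- 0  # zero in 3 of 4 -> removed
  m["b", 1:2] <- 0  # zero in exactly half -> kept
  got <- filter_low_expression(m)
  expect_identical(rownames(got), c("b", "c"))

  # all-positive matrix unchanged, and the filter is idempotent
  mp <- toy_expr(5, 4)
  expect_equal(filter_low_expression(mp), mp)
  expect_equal(filter_low_expression(got), got)

  expect_error(filter_low_expression(matrix(0, 2, 4)), "all genes")
})

test_that("stage labels: III/IV high risk, sub-stages normalized, missing excluded", {
  cl <- data.frame(
    sample_id = sprintf("s%d", 1:6),
    os_days = rep(1000, 6),
    vital_status = rep("alive", 6),
    tumor_stage = c("Stage IIIA", "Stage I", "stage iv", "Stage IIB", NA, "X"),
    stringsAsFactors = FALSE
  )
  coh <- suppressMessages(derive_stage_labels(cl))
  expect_identical(coh$sample_id, sprintf("s%d", 1:4))  # s5/s6 excluded
  expect_identical(coh$label, c(1L, 0L, 1L, 0L))
  expect_identical(attr(coh, "endpoint"), "stage")
})

test_that("3-year survival labels follow the removal rule and conserve counts", {
  cl <- data.frame(
    sample_id = sprintf("s%02d", 1:12),
    os_days = c(400, 400, 2000, 1095, 500, 1200, 900, 3000, 200, 1100, 800, 1500),
    vital_status = c("dead", "alive", "alive", "alive", "dead", "dead",
                     "dead", "alive", "dead", "dead", "alive", "alive"),
    stringsAsFactors = FALSE
  )
  coh <- suppressMessages(derive_survival_labels(cl))
  by_id <- setNames(coh$label, coh$sample_id)
  expect_identical(unname(by_id["s01"]), 1L)   # died before horizon
  expect_false("s02" %in% coh$sample_id)       # alive, censored early: removed
  expect_identical(unname(by_id["s03"]), 0L)   # followed past horizon
  expect_identical(unname(by_id["s04"]), 0L)   # exactly at horizon: low risk
  # conservation: labelled + removed = input
  removed <- setdiff(cl$sample_id, coh$sample_id)
  expect_identical(nrow(coh) + length(removed), nrow(cl))
  # removed samples are exactly the early-censored ones
  expect_true(all(cl$os_days[cl$sample_id %in% removed] < 1095))
  expect_true(all(cl$vital_status[cl$sample_id %in% removed] == "alive"))
})

test_that("split plans partition the cohort with floor-rounded train size", {
  coh <- toy_cohort(30)
  plan <- make_splits(coh, train_fraction = 0.7, repeats = 5, seed = 9)
  for (sp in plan$splits) {
    expect_identical(length(sp$train), 21L)  # floor(0.7 * 30)
    expect_setequal(c(sp$train, sp$validation), coh$sample_id)
    expect_length(intersect(sp$train, sp$validation), 0)
  }
  # reproducibility from the seed
  plan2 <- make_splits(coh, train_fraction = 0.7, repeats = 5, seed = 9)
  expect_identical(plan, plan2)
  expect_error(make_splits(coh, train_fraction = 1.0), "empty")
})
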