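# Clinical tables, endpoint labels and the repeated random-split plan.
#
# A clinical table is a data.frame with columns sample_id, os_days (overall
# survival in days), vital_status ("alive"/"dead") and tumor_stage. A
# labeled cohort is a data.frame with columns sample_id, label (1 =
# high-risk positive), os_days and event, carrying an "endpoint" attribute.

.as_cohort <- function(df, endpoint) {
  rownames(df) <- NULL
  attr(df, "endpoint") <- endpoint
  class(df) <- c("labeled_cohort", "data.frame")
  df
}

#' Read a clinical table
#'
#' @param path Path to a TSV/CSV file with columns `sample_id`, `os_days`,
#'   `vital_status` and `tumor_stage`.
#' @param sep Field separator; guessed from the extension by default.
#' @return A data.frame with one row per sample.
#' @export
read_clinical <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "os_days", "vital_status")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("clinical table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table",
                                        call. = FALSE)
  df
}

# "Stage IIIA" -> "III"; NA when unparseable
.normalize_stage <- function(stage) {
  s <- toupper(trimws(as.character(stage)))
  s <- sub("^STAGE\\s*", "", s)
  s <- sub("[ABC][0-9]*$", "", s)
  s[!s %in% c("I", "II", "III", "IV")] <- NA
  s
}

#' Derive high/low-risk labels from tumor stage
#'
#' Stages III and IV form the high-risk (positive) group, stages I and II the
#' low-risk group. Sub-stages ("Stage IIIA") are normalized to their major
#' stage; samples with missing or unparseable stage are excluded with a
#' message.
#'
#' @param clinical Clinical data.frame (see [read_clinical()]).
#' @return A labeled cohort data.frame (columns `sample_id`, `label`,
#'   `os_days`, `event`) with `endpoint = "stage"`.
#' @export
derive_stage_labels <- function(clinical) {
  st <- .normalize_stage(clinical$tumor_stage)
  drop <- is.na(st)
  if (any(drop)) {
    message("excluding ", sum(drop), " sample(s) with missing/unparseable stage")
  }
  keep <- clinical[!drop, , drop = FALSE]
  st <- st[!drop]
  .as_cohort(data.frame(
    sample_id = keep$sample_id,
    label = as.integer(st %in% c("III", "IV")),
    os_days = if ("os_days" %in% names(keep)) keep$os_days else NA_real_,
    event = as.integer(tolower(keep$vital_status) == "dead"),
    stringsAsFactors = FALSE
  ), endpoint = "stage")
}

#' Derive 3-year overall-survival labels
#'
#' Patients who died before the horizon are high-risk (label 1); patients
#' observed at or beyond the horizon are low-risk (label 0) regardless of
#' vital status. Patients censored alive before the horizon carry no label
#' and are removed, as are samples with missing survival data.
#'
#' @param clinical Clinical data.frame.
#' @param horizon_days Endpoint horizon in days (default 1095 = 3 years).
#' @return A labeled cohort data.frame with `endpoint = "survival3y"`.
#' @export
derive_survival_labels <- function(clinical, horizon_days = 1095) {
  stopifnot(horizon_days > 0)
  os <- as.numeric(clinical$os_days)
  dead <- tolower(clinical$vital_status) == "dead"
  drop <- is.na(os) | is.na(dead) | (os < horizon_days & !dead)
  if (any(drop)) {
    message("removing ", sum(drop),
            " sample(s) censored alive before the horizon or with missing data")
  }
  keep <- clinical[!drop, , drop = FALSE]
  os <- os[!drop]
  lab <- as.integer(os < horizon_days)  # surviving past horizon -> 0
  if (sum(lab == 1) < 2 || sum(lab == 0) < 2) {
    stop("fewer than 2 samples per class after horizon filtering", call. = FALSE)
  }
  .as_cohort(data.frame(
    sample_id = keep$sample_id,
    label = lab,
    os_days = os,
    event = as.integer(tolower(keep$vital_status) == "dead"),
    stringsAsFactors = FALSE
  ), endpoint = "survival3y")
}

# one class-safe random split of 1..n; plain uniform sampling without
# replacement, redrawn (bounded) if either side loses a class
.split_indices <- function(labels, fraction, max_retry = 100L) {
  n <- length(labels)
  n_train <- floor(fraction * n)
  if (n_train < 1 || n_train >= n) {
    stop("train_fraction ", fraction, " leaves an empty train or validation set",
         call. = FALSE)
  }
  for (i in seq_len(max_retry)) {
    tr <- sort(sample.int(n, n_train))
    te <- setdiff(seq_len(n), tr)
    if (length(unique(labels[tr])) == 2L && length(unique(labels[te])) == 2L) {
      return(list(train = tr, test = te))
    }
  }
  stop("could not draw a split with both classes on each side after ",
       max_retry, " attempts", call. = FALSE)
}

#' Build a repeated random-split plan
#'
#' Draws `repeats` independent train/validation partitions by seeded uniform
#' sampling without replacement; the training set holds
#' `floor(train_fraction * n)` samples. Splits leaving a class empty on
#' either side are redrawn (bounded retries).
#'
#' @param cohort A labeled cohort (see [derive_survival_labels()]).
#' @param train_fraction Fraction of samples in the training set (default 0.7).
#' @param repeats Number of random splits (default 100).
#' @param seed Integer seed; the same seed reproduces the same plan.
#' @return An object of class `split_plan`: list with `repeats`,
#'   `train_fraction`, `seed` and `splits`, each split a list of `train` and
#'   `validation` sample-id vectors.
#' @export
make_splits <- function(cohort, train_fraction = 0.7, repeats = 100L, seed = 1L) {
  stopifnot(is.data.frame(cohort), repeats >= 1)
  labels <- cohort$label
  if (sum(labels == 1) < 2 || sum(labels == 0) < 2) {
    stop("need at least 2 samples per class to split", call. = FALSE)
  }
  set.seed(seed)
  splits <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    idx <- .split_indices(labels, train_fraction)
    splits[[r]] <- list(train = cohort$sample_id[idx$train],
                        validation = cohort$sample_id[idx$test])
  }
  structure(list(repeats = as.integer(repeats), train_fraction = train_fraction,
                 seed = as.integer(seed), splits = splits),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  n <- length(x$splits[[1]]$train) + length(x$splits[[1]]$validation)
  cat("Split plan: ", x$repeats, " random splits of ", n, " samples (",
      length(x$splits[[1]]$train), " train / ",
      length(x$splits[[1]]$validation), " validation), seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}
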