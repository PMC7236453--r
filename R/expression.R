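# Expression-matrix ingest and gene filtering.
#
# An expression matrix is represented as a plain numeric matrix, genes in
# rows and samples in columns, with rownames = gene ids and colnames =
# sample ids; values are non-negative FPKM-like abundances.

#' Read a gene-expression table
#'
#' Reads a delimited text file with one header line of identifiers and a
#' first column of identifiers, and returns a genes x samples matrix
#' whichever way the table is oriented on disk.
#'
#' @param path Path to a TSV/CSV file.
#' @param dialect `"genes-in-rows"` (default: rows are genes, columns are
#'   samples) or `"genes-in-columns"` (the transpose).
#' @param sep Field separator; guessed from the file extension by default
#'   (`.csv` = comma, otherwise tab).
#' @return Numeric matrix, genes x samples.
#' @export
read_expression <- function(path, dialect = c("genes-in-rows", "genes-in-columns"),
                            sep = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate row identifiers in '", path, "': ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]))
    if (length(bad)) {
      stop("non-numeric value '", body[[j]][bad[1]], "' at row ", bad[1] + 1L,
           " (", ids[bad[1]], "), column '", colnames(body)[j], "'",
           call. = FALSE)
    }
    body[[j]] <- v
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (dialect == "genes-in-columns") m <- t(m)
  cdup <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(cdup)) {
    stop("duplicate identifiers: ", paste(utils::head(cdup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(m)) stop("missing values in expression table", call. = FALSE)
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop("negative expression value ", m[neg[1, 1], neg[1, 2]], " at gene '",
         rownames(m)[neg[1, 1]], "', sample '", colnames(m)[neg[1, 2]], "'",
         call. = FALSE)
  }
  m
}

#' Remove genes that are zero in more than half the samples
#'
#' Drops every gene whose expression is zero in strictly more than half of
#' the samples; a gene zero in exactly half of them is kept. Gene order is
#' preserved.
#'
#' @param expr Numeric matrix, genes x samples.
#' @return The filtered matrix.
#' @export
filter_low_expression <- function(expr) {
  expr <- as.matrix(expr)
  stopifnot(nrow(expr) > 0, ncol(expr) > 0)
  zeros <- rowSums(expr == 0)
  keep <- zeros <= floor(ncol(expr) / 2)
  if (!any(keep)) {
    stop("all genes are zero in over half the samples; check the input matrix",
         call. = FALSE)
  }
  expr[keep, , drop = FALSE]
}
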