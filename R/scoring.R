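# Least-squares back-mapping of representative features to gene scores.
#
# With Y the genes x samples matrix and X the pooled-features x samples
# matrix, the score matrix solves min ||Y - B X||_F row by row:
# B = Y X^T (X X^T)^-1. Whenever there are more pooled features than
# samples, X X^T is singular, so the Moore-Penrose pseudoinverse (the
# minimum-norm least-squares solution) replaces the plain inverse. A gene's
# score is the mean of its row of B.

#' Score matrix mapping representative features onto genes
#'
#' @param Y Numeric matrix, genes x samples. By default this is the original
#'   expression matrix of the training samples; level-1 wavelet
#'   approximations may be used instead (see [run_pipeline()]).
#' @param X Numeric matrix, pooled features x samples (same samples as `Y`;
#'   see [extract_representative_features()]).
#' @return Numeric matrix B, genes x features: the minimum-norm least-squares
#'   solution of Y = B X. The residual Y - B X is orthogonal to the rows
#'   of X.
#' @export
score_matrix <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (ncol(Y) != ncol(X)) {
    stop("Y has ", ncol(Y), " samples but X has ", ncol(X), call. = FALSE)
  }
  B <- Y %*% MASS::ginv(X)  # X^T (X X^T)^+ = ginv(X)
  rownames(B) <- rownames(Y)
  B
}

#' Per-gene importance scores and ranks
#'
#' Averages each gene's row of the score matrix and ranks genes by
#' descending score; ties are broken by gene id (lexical, deterministic).
#'
#' @param B Score matrix from [score_matrix()] (genes x features).
#' @param gene_ids Gene identifiers; defaults to `rownames(B)`.
#' @return A data.frame with columns `gene_id`, `score` and `rank`
#'   (1 = most important), ordered by rank.
#' @export
gene_scores <- function(B, gene_ids = rownames(B)) {
  B <- as.matrix(B)
  stopifnot(nrow(B) >= 1)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(B)))
  sc <- rowMeans(B)
  ord <- order(-sc, gene_ids)
  out <- data.frame(gene_id = gene_ids[ord], score = sc[ord],
                    rank = seq_along(sc), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Top-ranked genes
#'
#' @param scores A gene-score table from [gene_scores()].
#' @param n Number of genes to take from the top of the ranking.
#' @return Character vector of the first `n` gene ids by rank.
#' @export
top_n_genes <- function(scores, n) {
  if (n < 1 || n > nrow(scores)) {
    stop("n must be between 1 and ", nrow(scores), call. = FALSE)
  }
  scores$gene_id[order(scores$rank)][seq_len(n)]
}

#' Stability of top-k gene rankings across repeated fits
#'
#' For every pair of rankings, takes the union of the two top-`k` gene sets,
#' forms the two full-list rank vectors over that union, and computes
#' Kendall's tau-b with its two-sided p-value. Used to quantify how stable
#' the head of the importance ranking is across bootstraps or refits.
#'
#' @param rankings A list of gene-score tables ([gene_scores()]) or of named
#'   rank vectors over a shared gene universe.
#' @param k Size of the top list compared (default 100).
#' @return A data.frame with one row per pair: `i`, `j`, `tau`, `p_value`.
#' @export
kendall_tau_stability <- function(rankings, k = 100L) {
  stopifnot(length(rankings) >= 2L)
  as_rank <- function(r) {
    if (is.data.frame(r)) stats::setNames(r$rank, r$gene_id)
    else if (!is.null(names(r))) r
    else stop("rankings must be gene_scores() tables or named rank vectors",
              call. = FALSE)
  }
  rk <- lapply(rankings, as_rank)
  universe <- Reduce(intersect, lapply(rk, names))
  if (length(universe) == 0L) {
    stop("rankings share no genes; they must cover a common universe",
         call. = FALSE)
  }
  pairs <- utils::combn(length(rk), 2)
  out <- data.frame(i = pairs[1, ], j = pairs[2, ], tau = NA_real_,
                    p_value = NA_real_)
  for (q in seq_len(ncol(pairs))) {
    a <- rk[[pairs[1, q]]]; b <- rk[[pairs[2, q]]]
    top <- union(names(sort(a))[seq_len(min(k, length(a)))],
                 names(sort(b))[seq_len(min(k, length(b)))])
    top <- intersect(top, intersect(names(a), names(b)))
    ct <- suppressWarnings(
      stats::cor.test(a[top], b[top], method = "kendall", exact = FALSE))
    out$tau[q] <- unname(ct$estimate)
    out$p_value[q] <- ct$p.value
  }
  out
}
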