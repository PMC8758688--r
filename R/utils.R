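#' @importFrom stats cor cutree dist hclust p.adjust pchisq pnorm rexp rlnorm
#'   rnbinom rnorm rpois sd var rgamma
NULL

#' Linear relative expression
#'
#' Library-size normalization to a fixed scale: each cell's counts are divided
#' by its total and multiplied by `scale_factor`. Cells with zero total counts
#' are returned as all-zero columns.
#'
#' @param counts genes x cells numeric matrix of non-negative counts.
#' @param scale_factor target column sum (default 1e4, i.e. CPM/100).
#' @return genes x cells matrix on the linear normalized scale.
#' @export
relative_expression <- function(counts, scale_factor = 1e4) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  lib[lib == 0] <- 1
  sweep(counts, 2, lib, "/") * scale_factor
}

#' Log-normalized expression
#'
#' `log(counts/libsize * scale_factor + 1)` with the given log base; the
#' natural-log, `scale_factor = 1e4` default matches the common single-cell
#' "LogNormalize" convention.
#'
#' @inheritParams relative_expression
#' @param base log base (exp(1) for natural log, 2 for log2).
#' @return genes x cells matrix of log-normalized values.
#' @export
log_normalize <- function(counts, scale_factor = 1e4, base = exp(1)) {
  log(relative_expression(counts, scale_factor) + 1, base = base)
}

#' Rank-sum AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney U statistic of the
#' scores, normalized: P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @param scores numeric vector of classifier scores.
#' @param positive logical vector, TRUE for the positive class.
#' @return AUC in [0, 1], or NA if either class is empty.
#' @export
auc_score <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Dirichlet draws: n x length(alpha) matrix, rows on the simplex.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = alpha, rate = 1), nrow = n, byrow = TRUE)
  zero <- rowSums(g) == 0
  if (any(zero)) g[zero, ] <- 1 / k  # degenerate underflow guard
  g / rowSums(g)
}

# Stratified fold assignment: within each class, folds 1..n_folds are dealt
# round-robin after a random shuffle. Returns an integer vector.
stratified_folds <- function(labels, n_folds) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

# Silhouette-based choice of k over an hclust tree. Returns the k in
# 2..k_max with the largest mean silhouette width (first on ties).
select_k_silhouette <- function(d, hc, k_max) {
  n <- attr(d, "Size")
  ks <- seq(2L, min(k_max, n - 1L))
  if (length(ks) == 0L) return(1L)
  widths <- vapply(ks, function(k) {
    cl <- cutree(hc, k = k)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1))
  ks[which.max(widths)]
}

#' Vectorized two-sided Wilcoxon rank-sum test across genes
#'
#' Normal-approximation rank-sum test (tie-corrected, with continuity
#' correction) applied row-wise, numerically identical to
#' `stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)` gene by gene but
#' computed in one pass over the matrix.
#'
#' @param x genes x cells matrix restricted to the cells under test.
#' @param in_a logical vector over columns of `x`, TRUE for group A.
#' @return numeric vector of two-sided p-values, one per row.
#' @keywords internal
ranksum_pvalues <- function(x, in_a) {
  n1 <- sum(in_a)
  n2 <- sum(!in_a)
  n <- n1 + n2
  r <- t(apply(x, 1, rank))
  W <- rowSums(r[, in_a, drop = FALSE]) - n1 * (n1 + 1) / 2
  # tie correction per gene
  tie_term <- apply(r, 1, function(rr) {
    tt <- table(rr)
    sum(tt^3 - tt)
  })
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  z <- W - n1 * n2 / 2
  correction <- sign(z) * 0.5
  sigma <- sqrt(sigma2)
  p <- ifelse(sigma == 0, 1, 2 * pnorm(-abs((z - correction) / pmax(sigma, .Machine$double.eps))))
  pmin(p, 1)
}

# Resolve cell identifiers (names or indices) against matrix columns.
resolve_cells <- function(ids, cell_ids, what = "cells") {
  if (is.logical(ids)) ids <- which(ids)
  if (is.numeric(ids)) {
    if (any(ids < 1 | ids > length(cell_ids)))
      stop(what, ": index out of range", call. = FALSE)
    return(as.integer(ids))
  }
  idx <- match(ids, cell_ids)
  if (anyNA(idx))
    stop(what, ": unknown cell id(s): ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "), call. = FALSE)
  idx
}
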