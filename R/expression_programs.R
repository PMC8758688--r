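#' Differential expression between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test per gene on log-normalized expression
#' (natural-log `log(counts/libsize * 1e4 + 1)`), with Benjamini-Hochberg
#' adjustment over the tested genes. The log fold change is the natural log of
#' the ratio of group means on the linear normalized scale with a +1
#' pseudocount: `log((mean_a + 1)/(mean_b + 1))`. A gene is `up` when
#' `log_fc > logfc_threshold` and `adjusted_p < alpha`, `down` symmetrically,
#' otherwise `unchanged`. Genes that are all-zero across both groups get
#' p = 1, log_fc = 0 and are excluded from the adjustment.
#'
#' @param cells a [cell_matrix] or genes x cells counts matrix.
#' @param group_a,group_b disjoint cell-id (or index) sets, each >= 3 cells.
#' @param logfc_threshold natural-log fold-change threshold for calling
#'   direction (0.25 is the single-cell convention, 1 the bulk convention).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return data.frame (`deg_table`): gene_id, log_fc, p_value, adjusted_p,
#'   direction.
#' @export
differential_expression <- function(cells, group_a, group_b,
                                    logfc_threshold = 0.25, alpha = 0.05) {
  counts <- as_counts(cells)
  ia <- resolve_cells(group_a, colnames(counts), "group_a")
  ib <- resolve_cells(group_b, colnames(counts), "group_b")
  if (length(intersect(ia, ib)))
    stop("group_a and group_b must be disjoint", call. = FALSE)
  if (length(ia) < 3 || length(ib) < 3)
    stop("each group needs at least 3 cells", call. = FALSE)

  ls <- relative_expression(counts, 1e4)
  sub <- ls[, c(ia, ib), drop = FALSE]
  in_a <- seq_along(c(ia, ib)) <= length(ia)

  nonzero <- rowSums(sub) > 0
  p <- rep(1, nrow(sub))
  if (any(nonzero))
    p[nonzero] <- ranksum_pvalues(log1p(sub[nonzero, , drop = FALSE]), in_a)
  adj <- rep(1, nrow(sub))
  adj[nonzero] <- p.adjust(p[nonzero], method = "BH")

  mean_a <- rowMeans(sub[, in_a, drop = FALSE])
  mean_b <- rowMeans(sub[, !in_a, drop = FALSE])
  log_fc <- ifelse(nonzero, log((mean_a + 1) / (mean_b + 1)), 0)

  direction <- rep("unchanged", nrow(sub))
  direction[log_fc > logfc_threshold & adj < alpha] <- "up"
  direction[log_fc < -logfc_threshold & adj < alpha] <- "down"
  out <- data.frame(gene_id = rownames(counts), log_fc = log_fc,
                    p_value = p, adjusted_p = adj, direction = direction)
  rownames(out) <- NULL
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Tau cell-specificity index
#'
#' `tau = sum(1 - x_hat) / (n - 1)` with `x_hat = x / max(x)` over per-type
#' mean expression: 0 for a gene expressed uniformly across types, 1 for a
#' gene expressed in a single type.
#'
#' @param mean_expr_per_type non-negative numeric vector (length >= 2) of a
#'   gene's mean expression per cell type.
#' @return tau in [0, 1].
#' @export
tau_specificity <- function(mean_expr_per_type) {
  x <- as.numeric(mean_expr_per_type)
  if (length(x) < 2) stop("tau needs at least 2 cell types", call. = FALSE)
  if (any(x < 0)) stop("expression must be non-negative", call. = FALSE)
  m <- max(x)
  if (m == 0) stop("tau undefined for an all-zero expression vector", call. = FALSE)
  sum(1 - x / m) / (length(x) - 1)
}

#' Partition up-regulated genes into condition-specific and shared fractions
#'
#' Given DEG tables for the same gene universe under two conditions, computes
#' the fractions of the union of up-regulated genes that are specific to each
#' condition or shared (shared genes counted once; the three fractions sum
#' to 1).
#'
#' @param deg_a,deg_b `deg_table`s over the same genes.
#' @return list: `a_specific`, `b_specific`, `shared` (fractions of the
#'   union), counts `n_a`, `n_b`, `n_shared`, `n_union`, and `empty` flag.
#' @export
partition_shared_degs <- function(deg_a, deg_b) {
  if (!setequal(deg_a$gene_id, deg_b$gene_id))
    stop("DEG tables must cover the same gene universe", call. = FALSE)
  up_a <- deg_a$gene_id[deg_a$direction == "up"]
  up_b <- deg_b$gene_id[deg_b$direction == "up"]
  u <- union(up_a, up_b)
  if (length(u) == 0)
    return(list(a_specific = NA_real_, b_specific = NA_real_,
                shared = NA_real_, n_a = 0L, n_b = 0L, n_shared = 0L,
                n_union = 0L, empty = TRUE))
  sh <- intersect(up_a, up_b)
  list(a_specific = length(setdiff(up_a, up_b)) / length(u),
       b_specific = length(setdiff(up_b, up_a)) / length(u),
       shared = length(sh) / length(u),
       n_a = length(up_a), n_b = length(up_b), n_shared = length(sh),
       n_union = length(u), empty = FALSE)
}

#' Assign genes to tumor-stage-specific modules
#'
#' For each stage, runs a one-vs-rest [differential_expression]; a gene joins
#' the module of the stage where it is up-regulated with the largest log fold
#' change, and `none` when it is up-regulated in no stage. Stages with fewer
#' than 3 cells are excluded with a warning.
#'
#' @param cells a [cell_matrix] or counts matrix.
#' @param stage_labels per-cell stage labels aligned with columns.
#' @param logfc_threshold,alpha passed to [differential_expression].
#' @return data.frame: gene_id, module (stage name or "none"), best log_fc.
#' @export
stage_modules <- function(cells, stage_labels, logfc_threshold = 0.25,
                          alpha = 0.05) {
  counts <- as_counts(cells)
  stage_labels <- as.character(stage_labels)
  stopifnot(length(stage_labels) == ncol(counts))
  tab <- table(stage_labels)
  small <- names(tab)[tab < 3]
  if (length(small))
    warning("excluding stage(s) with < 3 cells: ",
            paste(small, collapse = ", "), call. = FALSE)
  stages <- setdiff(names(tab), small)
  if (length(stages) < 2) stop("need at least 2 usable stages", call. = FALSE)
  keep <- stage_labels %in% stages
  counts <- counts[, keep, drop = FALSE]
  stage_labels <- stage_labels[keep]
  lfc_up <- sapply(stages, function(s) {
    deg <- differential_expression(counts, which(stage_labels == s),
                                   which(stage_labels != s),
                                   logfc_threshold, alpha)
    ifelse(deg$direction == "up", deg$log_fc, -Inf)
  })
  best <- max.col(lfc_up, ties.method = "first")
  module <- ifelse(apply(lfc_up, 1, max) > -Inf, stages[best], "none")
  data.frame(gene_id = rownames(counts), module = module,
             log_fc = ifelse(module == "none", NA_real_,
                             lfc_up[cbind(seq_along(best), best)]))
}

#' Per-cell gene-set score
#'
#' Mean normalized expression (linear scale, `counts/libsize * 1e4`) over the
#' set's genes present in the matrix, optionally `log2(x + 1)` transformed —
#' the stemness/cycling score construction.
#'
#' @param cells a [cell_matrix] or counts matrix.
#' @param gene_set character vector of gene ids.
#' @param log2_transform apply `log2(score + 1)`?
#' @param set_id label carried in the result (default deparsed).
#' @return a `gene_set_score`: list with `score` (named per-cell vector),
#'   `set_id`, `transform`, `genes_used`.
#' @export
gene_set_score <- function(cells, gene_set, log2_transform = FALSE,
                           set_id = "gene_set") {
  counts <- as_counts(cells)
  present <- intersect(gene_set, rownames(counts))
  if (length(present) == 0)
    stop("gene set '", set_id, "' shares no genes with the matrix",
         call. = FALSE)
  ls <- relative_expression(counts, 1e4)
  score <- colMeans(ls[present, , drop = FALSE])
  if (log2_transform) score <- log2(score + 1)
  structure(list(score = score, set_id = set_id,
                 transform = if (log2_transform) "log2" else "identity",
                 genes_used = present),
            class = "gene_set_score")
}

#' Assign cells to the gene set with maximal score
#'
#' Argmax per cell over a cells x sets score matrix; exact ties go to the
#' lexicographically first set name and are flagged.
#'
#' @param scores cells x sets numeric matrix with set names as colnames.
#' @return data.frame: cell_id, label, tie.
#' @export
assign_by_max_score <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 1) stop("need at least one set", call. = FALSE)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("set", seq_len(ncol(scores)))
  scores <- scores[, order(colnames(scores)), drop = FALSE]
  best <- max.col(scores, ties.method = "first")
  rowmax <- scores[cbind(seq_len(nrow(scores)), best)]
  tie <- rowSums(scores == rowmax) > 1
  data.frame(cell_id = if (!is.null(rownames(scores))) rownames(scores)
             else sprintf("cell%d", seq_len(nrow(scores))),
             label = colnames(scores)[best], tie = tie)
}
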