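#' Build a cell-type signature matrix from single-cell data
#'
#' For each cell type, runs a one-vs-rest [differential_expression]; candidate
#' markers are genes with `adjusted_p < alpha`, `log_fc > logfc_threshold`,
#' tau specificity >= `tau_min` (computed on per-type mean linear expression)
#' and whose source type attains the row maximum across types (marker
#' coherence). The top `n_markers_per_type` by log fold change are kept per
#' type. Signature entries are mean linear-scale normalized expression per
#' type over the selected marker genes.
#'
#' @param cells a [cell_matrix] (uses `meta$cell_type` unless `type_labels`
#'   given) or a counts matrix plus `type_labels`.
#' @param type_labels optional per-cell type labels.
#' @param n_markers_per_type markers retained per type (default 50).
#' @param tau_min minimum tau specificity for a candidate marker (default 0.6).
#' @param logfc_threshold,alpha marker-candidacy thresholds (defaults 0.25,
#'   0.05).
#' @return a `signature_matrix`: list with `matrix` (marker genes x types) and
#'   `provenance` (gene_id, source_type, log_fc, tau).
#' @export
build_signature_matrix <- function(cells, type_labels = NULL,
                                   n_markers_per_type = 50L, tau_min = 0.6,
                                   logfc_threshold = 0.25, alpha = 0.05) {
  counts <- as_counts(cells)
  if (is.null(type_labels)) {
    if (!inherits(cells, "cell_matrix"))
      stop("type_labels required for a bare matrix", call. = FALSE)
    type_labels <- cells$meta$cell_type
  }
  type_labels <- as.character(type_labels)
  tab <- table(type_labels)
  if (length(tab) < 2) stop("need at least 2 cell types", call. = FALSE)
  if (any(tab < 3)) stop("every cell type needs >= 3 cells", call. = FALSE)
  types <- sort(names(tab))

  ls <- relative_expression(counts, 1e4)
  type_means <- sapply(types, function(t)
    rowMeans(ls[, type_labels == t, drop = FALSE]))
  tau <- apply(type_means, 1, function(x) {
    if (max(x) == 0) NA_real_ else sum(1 - x / max(x)) / (length(x) - 1)
  })

  prov <- list()
  for (t in types) {
    deg <- differential_expression(counts, which(type_labels == t),
                                   which(type_labels != t),
                                   logfc_threshold, alpha)
    is_max <- type_means[, t] >= apply(type_means, 1, max)
    cand <- which(deg$direction == "up" & !is.na(tau) & tau >= tau_min & is_max)
    if (length(cand) == 0)
      stop("no markers found for cell type '", t,
           "' (thresholds too strict or types indistinguishable)",
           call. = FALSE)
    cand <- cand[order(deg$log_fc[cand], decreasing = TRUE)]
    cand <- utils::head(cand, n_markers_per_type)
    prov[[t]] <- data.frame(gene_id = deg$gene_id[cand], source_type = t,
                            log_fc = deg$log_fc[cand], tau = tau[cand])
  }
  prov <- do.call(rbind, prov)
  prov <- prov[!duplicated(prov$gene_id), ]
  rownames(prov) <- NULL
  sig <- type_means[prov$gene_id, , drop = FALSE]
  structure(list(matrix = sig, provenance = prov),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("signature_matrix: %d marker genes x %d cell types\n",
              nrow(x$matrix), ncol(x$matrix)))
  print(table(x$provenance$source_type))
  invisible(x)
}

#' Deconvolve bulk profiles into cell-type compositions
#'
#' For each bulk sample, solves non-negative least squares
#' `min || S w - b ||` over the genes shared between the signature and the
#' bulk matrix, after scaling each shared gene to unit variance across
#' signature columns (genes with zero signature variance are dropped). The
#' solution is normalized to sum to 1; the pre-normalization residual norm is
#' recorded per sample. Signature genes missing from the bulk are dropped,
#' and an error is raised when fewer than `min_overlap` of them remain.
#'
#' @param signature a `signature_matrix` (or bare genes x types matrix).
#' @param bulk genes x samples non-negative matrix.
#' @param min_overlap minimum fraction of signature genes required in the
#'   bulk matrix (default 0.5).
#' @return a `composition_matrix`: list with `weights` (samples x types, rows
#'   sum to 1), `residual` (per-sample), `n_genes_used`.
#' @export
deconvolve <- function(signature, bulk, min_overlap = 0.5) {
  S0 <- if (inherits(signature, "signature_matrix")) signature$matrix
        else as.matrix(signature)
  bulk <- as.matrix(bulk)
  if (any(bulk < 0)) stop("bulk matrix must be non-negative", call. = FALSE)
  shared <- intersect(rownames(S0), rownames(bulk))
  frac <- length(shared) / nrow(S0)
  if (frac < min_overlap)
    stop(sprintf("only %.1f%% of signature genes found in bulk (need >= %.0f%%)",
                 100 * frac, 100 * min_overlap), call. = FALSE)
  S <- S0[shared, , drop = FALSE]
  B <- bulk[shared, , drop = FALSE]
  g_sd <- apply(S, 1, sd)
  use <- g_sd > 0
  S <- S[use, , drop = FALSE] / g_sd[use]
  B <- B[use, , drop = FALSE] / g_sd[use]
  n_types <- ncol(S)
  W <- matrix(0, nrow = ncol(B), ncol = n_types,
              dimnames = list(colnames(B), colnames(S)))
  residual <- numeric(ncol(B))
  for (j in seq_len(ncol(B))) {
    fit <- pracma::lsqnonneg(S, B[, j])
    w <- fit$x
    residual[j] <- sqrt(sum((S %*% w - B[, j])^2))
    if (sum(w) == 0) {
      warning("sample ", colnames(B)[j],
              ": all-zero NNLS solution, returning uniform weights",
              call. = FALSE)
      w <- rep(1 / n_types, n_types)
    } else w <- w / sum(w)
    W[j, ] <- w
  }
  structure(list(weights = W, residual = stats::setNames(residual, colnames(B)),
                 n_genes_used = sum(use)),
            class = "composition_matrix")
}

#' @export
print.composition_matrix <- function(x, ...) {
  cat(sprintf("composition_matrix: %d samples x %d cell types (%d genes used)\n",
              nrow(x$weights), ncol(x$weights), x$n_genes_used))
  invisible(x)
}

#' Cross-source consistency of compositions
#'
#' Pearson correlation per cell type over paired samples, plus the overall
#' correlation over the flattened paired matrices. Cell types with a constant
#' weight vector in either source are flagged and get NA.
#'
#' @param comp_a,comp_b `composition_matrix` objects (or bare samples x types
#'   matrices) sharing a cell-type set.
#' @param pairing named character vector mapping rownames of `comp_a` to
#'   rownames of `comp_b`; default pairs identical rownames.
#' @return list: `per_type` (named r), `overall`, `flagged` (constant types),
#'   `n_pairs`.
#' @export
evaluate_consistency <- function(comp_a, comp_b, pairing = NULL) {
  A <- if (inherits(comp_a, "composition_matrix")) comp_a$weights else as.matrix(comp_a)
  B <- if (inherits(comp_b, "composition_matrix")) comp_b$weights else as.matrix(comp_b)
  types <- intersect(colnames(A), colnames(B))
  if (length(types) == 0) stop("no shared cell types", call. = FALSE)
  if (is.null(pairing))
    pairing <- stats::setNames(intersect(rownames(A), rownames(B)),
                               intersect(rownames(A), rownames(B)))
  if (length(pairing) < 3) stop("need >= 3 paired samples", call. = FALSE)
  A <- A[names(pairing), types, drop = FALSE]
  B <- B[pairing, types, drop = FALSE]
  per_type <- vapply(types, function(t) {
    if (sd(A[, t]) == 0 || sd(B[, t]) == 0) NA_real_ else cor(A[, t], B[, t])
  }, numeric(1))
  flagged <- types[is.na(per_type)]
  overall <- cor(as.vector(A), as.vector(B))
  list(per_type = per_type, overall = overall, flagged = flagged,
       n_pairs = length(pairing))
}
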