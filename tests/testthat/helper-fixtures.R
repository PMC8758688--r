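# Shared fixture builders. Everything is generated in code; no files on disk.

# Small deterministic counts matrix with metadata.
make_cells <- function(counts, cell_type = NULL, condition = NULL) {
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  meta <- data.frame(cell_id = colnames(counts))
  meta$cell_type <- if (is.null(cell_type)) "T" else cell_type
  if (!is.null(condition)) meta$condition <- condition
  cell_matrix(counts, meta)
}

# Random count matrix, seeded.
random_counts <- function(n_genes, n_cells, seed = 1, lambda = 2) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("c%03d", seq_len(n_cells))))
  m
}

# A minimal two-type design without malignancy, for marker/DEG fixtures.
two_type_design <- function(n_cells = 120, n_markers = 20, marker_fold = 8,
                            seed = 1, dispersion = 0.5) {
  cohort_design(
    cell_types = c("A", "B"), immune_types = character(0),
    n_markers_per_type = n_markers, marker_fold = marker_fold,
    cells_per_type = n_cells,
    samples = data.frame(sample = "s1", condition = "LUAD", stage = "I"),
    malignant = list(), dispersion = dispersion, seed = seed)
}

# Independent brute-force CNV profile oracle: plain loops, no shared code
# with compute_cnv_profile beyond the published definition.
oracle_cnv_profile <- function(counts, catalog, ref_ids, window_size,
                               clamp = 3) {
  keep <- intersect(catalog$gene_id, rownames(counts))
  keep <- keep[rowSums(counts[keep, , drop = FALSE]) > 0]
  cat_use <- catalog[match(keep, catalog$gene_id), ]
  cat_use <- cat_use[order(match(cat_use$chromosome, unique(catalog$chromosome)),
                           cat_use$order_index), ]
  lib <- colSums(counts)
  x <- log2(sweep(counts[cat_use$gene_id, , drop = FALSE], 2, lib, "/") * 1e5 + 1)
  ref <- match(ref_ids, colnames(counts))
  for (g in seq_len(nrow(x))) x[g, ] <- x[g, ] - mean(x[g, ref])
  for (j in seq_len(ncol(x))) x[, j] <- x[, j] - median(x[, j])
  x[x > clamp] <- clamp; x[x < -clamp] <- -clamp
  rows_list <- list()
  for (ch in unique(cat_use$chromosome)) {
    idx <- which(cat_use$chromosome == ch)
    g <- length(idx)
    min_len <- min(ceiling(window_size / 2), g)
    for (i in seq_len(g)) {
      last <- min(i + window_size - 1, g)
      if (last - i + 1 < min_len) break
      rows_list[[length(rows_list) + 1]] <- colMeans(x[idx[i:last], , drop = FALSE])
    }
  }
  M <- do.call(rbind, rows_list)
  for (j in seq_len(ncol(M))) M[, j] <- M[, j] - median(M[, j])
  for (w in seq_len(nrow(M))) M[w, ] <- M[w, ] - mean(M[w, ref])
  t(M)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
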