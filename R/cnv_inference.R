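#' Infer relative copy-number profiles from expression
#'
#' inferCNV-style windowed expression smoothing. Expression is normalized to
#' `log2(counts/libsize * 1e5 + 1)` (log2 of CPM/10 + 1, so a doubled dosage
#' adds ~1 in the high-expression limit), centered gene-wise on the mean of
#' the reference (non-malignant) cells, re-centered per cell by its median
#' (removing residual library-depth shifts), clamped to `+/- clamp`, averaged
#' over sliding windows of `window_size` genes (step 1) in chromosome order,
#' re-centered per cell by its median over windows, and finally re-centered
#' window-wise on the reference so reference window means are exactly zero.
#' Windows never span chromosomes; windows truncated at a chromosome end are
#' kept while they hold at least `ceiling(window_size/2)` genes (a chromosome
#' shorter than that contributes one whole-chromosome window).
#'
#' @param cells a [cell_matrix] (or bare genes x cells counts matrix with
#'   dimnames).
#' @param catalog gene catalog defining chromosome order
#'   ([generate_gene_catalog]).
#' @param reference_cells ids (or indices) of reference cells assumed free of
#'   copy-number changes.
#' @param window_size genes per window (default 100).
#' @param clamp symmetric bound applied to centered log expression before
#'   smoothing (default 3); `Inf` disables clamping.
#' @return a `cnv_profile`: list with `matrix` (cells x windows), `windows`
#'   (window map: chromosome, first/last order_index, n_genes),
#'   `reference_cells`, `window_size`, `clamp`.
#' @export
compute_cnv_profile <- function(cells, catalog, reference_cells,
                                window_size = 100L, clamp = 3) {
  counts <- as_counts(cells)
  if (window_size < 1) stop("window_size must be >= 1", call. = FALSE)
  if (length(reference_cells) == 0)
    stop("reference_cells must be non-empty", call. = FALSE)
  ref_idx <- resolve_cells(reference_cells, colnames(counts), "reference_cells")

  keep <- intersect(catalog$gene_id, rownames(counts))
  keep <- keep[rowSums(counts[keep, , drop = FALSE]) > 0]
  if (!length(keep)) stop("no non-zero catalog genes in matrix", call. = FALSE)
  cat_use <- catalog[match(keep, catalog$gene_id), ]
  ord <- order(match(cat_use$chromosome, unique(catalog$chromosome)),
               cat_use$order_index)
  cat_use <- cat_use[ord, ]

  x <- log_normalize(counts[cat_use$gene_id, , drop = FALSE],
                     scale_factor = 1e5, base = 2)
  x <- x - rowMeans(x[, ref_idx, drop = FALSE])
  x <- sweep(x, 2, apply(x, 2, stats::median))
  if (is.finite(clamp)) x <- pmin(pmax(x, -clamp), clamp)

  min_len <- min(window_size, ceiling(window_size / 2))
  win_rows <- list(); win_map <- list()
  for (ch in unique(cat_use$chromosome)) {
    rows <- which(cat_use$chromosome == ch)
    g <- length(rows)
    cs <- apply(x[rows, , drop = FALSE], 2, cumsum)
    cs <- rbind(0, cs)
    min_here <- min(min_len, g)
    for (i in seq_len(g)) {
      last <- min(i + window_size - 1L, g)
      len <- last - i + 1L
      if (len < min_here) break
      win_rows[[length(win_rows) + 1L]] <- (cs[last + 1L, ] - cs[i, ]) / len
      win_map[[length(win_map) + 1L]] <- data.frame(
        chromosome = ch,
        first_index = cat_use$order_index[rows[i]],
        last_index = cat_use$order_index[rows[last]],
        n_genes = len)
    }
  }
  M <- do.call(rbind, win_rows)           # windows x cells
  wmap <- do.call(rbind, win_map)
  wmap$window <- seq_len(nrow(wmap))
  M <- sweep(M, 2, apply(M, 2, stats::median))
  M <- M - rowMeans(M[, ref_idx, drop = FALSE])
  prof <- t(M)                            # cells x windows
  rownames(prof) <- colnames(counts)
  colnames(prof) <- sprintf("w%04d", wmap$window)
  structure(list(matrix = prof, windows = wmap,
                 reference_cells = colnames(counts)[ref_idx],
                 window_size = as.integer(window_size), clamp = clamp),
            class = "cnv_profile")
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat(sprintf("cnv_profile: %d cells x %d windows (window_size %d, %d reference cells)\n",
              nrow(x$matrix), ncol(x$matrix), x$window_size,
              length(x$reference_cells)))
  invisible(x)
}

#' Call malignant cells from CNV burden
#'
#' Per-cell burden is the mean squared window deviation of the CNV profile,
#' computed on denoised deviations: window values within `denoise_sd`
#' reference SDs of zero (per window, SD over the reference cells) are set to
#' zero before squaring, mirroring inferCNV's denoising of values inside the
#' reference noise band. The threshold is the reference cells' burden mean
#' plus `threshold_sd` reference SDs; cells above it are labeled malignant.
#'
#' @param profile a `cnv_profile`.
#' @param threshold_sd number of reference-burden SDs above the reference mean
#'   (default 3).
#' @param denoise_sd width of the reference noise band zeroed before the
#'   burden is computed (default 1.5; 0 disables denoising).
#' @return a `malignancy_call`: list with `calls` (data.frame cell_id, burden,
#'   label) and `threshold`.
#' @export
call_malignancy <- function(profile, threshold_sd = 3, denoise_sd = 1.5) {
  stopifnot(inherits(profile, "cnv_profile"))
  M <- profile$matrix
  if (denoise_sd > 0) {
    ref_sd <- apply(M[profile$reference_cells, , drop = FALSE], 2, sd)
    M <- M * (abs(M) > rep(denoise_sd * ref_sd, each = nrow(M)))
  }
  burden <- rowMeans(M^2)
  ref <- burden[profile$reference_cells]
  s <- sd(ref)
  if (!is.finite(s) || s == 0)
    stop("degenerate reference: zero burden variance across the ",
         length(ref), " reference cells", call. = FALSE)
  threshold <- mean(ref) + threshold_sd * s
  calls <- data.frame(cell_id = rownames(profile$matrix), burden = burden,
                      label = ifelse(burden > threshold, "malignant",
                                     "non_malignant"))
  structure(list(calls = calls, threshold = threshold,
                 threshold_sd = threshold_sd), class = "malignancy_call")
}

#' Cluster malignant cells into subclones
#'
#' Agglomerative clustering (Ward linkage on Euclidean distance in window
#' space) of the malignant cells' CNV profiles. With `k = "auto"` the number
#' of subclones is chosen in `2..k_max` by mean silhouette width. Cells are
#' processed in lexicographic id order so ties resolve deterministically.
#'
#' @param profile a `cnv_profile`.
#' @param malignant_cells ids of cells to cluster.
#' @param k integer number of subclones, or "auto".
#' @param k_max upper bound for automatic selection (default 8).
#' @return a `subclone_assignment`: list with `subclone` (named integer
#'   vector, ids contiguous 1..k), `k`, `linkage`.
#' @export
cluster_subclones <- function(profile, malignant_cells, k = "auto", k_max = 8L) {
  stopifnot(inherits(profile, "cnv_profile"))
  ids <- sort(as.character(malignant_cells))
  idx <- resolve_cells(ids, rownames(profile$matrix), "malignant_cells")
  n <- length(idx)
  if (!identical(k, "auto")) {
    if (k > n) stop("k exceeds the number of malignant cells", call. = FALSE)
    if (k == 1) {
      cl <- stats::setNames(rep(1L, n), ids)
      return(structure(list(subclone = cl, k = 1L, linkage = "ward.D2"),
                       class = "subclone_assignment"))
    }
  }
  d <- dist(profile$matrix[idx, , drop = FALSE])
  hc <- hclust(d, method = "ward.D2")
  kk <- if (identical(k, "auto")) select_k_silhouette(d, hc, k_max) else as.integer(k)
  raw <- cutree(hc, k = kk)
  # relabel in order of first appearance for determinism
  cl <- as.integer(factor(raw, levels = unique(raw)))
  names(cl) <- ids
  structure(list(subclone = cl, k = kk, linkage = "ward.D2"),
            class = "subclone_assignment")
}

#' Mean inferred-CNV score of driver genes per subclone
#'
#' For each driver gene, the score of a subclone is the mean over its cells of
#' the mean of all windows containing that gene. Driver genes absent from the
#' catalog (or falling in no retained window) are reported in a warning and in
#' the `missing_genes` attribute, not silently dropped.
#'
#' @param profile a `cnv_profile`.
#' @param assignment a `subclone_assignment`.
#' @param driver_genes character vector of gene ids.
#' @param catalog gene catalog.
#' @return subclones x genes matrix of mean scores, with attribute
#'   `missing_genes`.
#' @export
score_driver_genes <- function(profile, assignment, driver_genes, catalog) {
  stopifnot(inherits(profile, "cnv_profile"),
            inherits(assignment, "subclone_assignment"))
  wmap <- profile$windows
  gene_windows <- lapply(driver_genes, function(g) {
    row <- catalog[catalog$gene_id == g, ]
    if (nrow(row) == 0) return(integer(0))
    which(wmap$chromosome == row$chromosome &
            wmap$first_index <= row$order_index &
            wmap$last_index >= row$order_index)
  })
  names(gene_windows) <- driver_genes
  missing <- driver_genes[lengths(gene_windows) == 0]
  if (length(missing))
    warning("driver gene(s) not scoreable: ", paste(missing, collapse = ", "),
            call. = FALSE)
  present <- setdiff(driver_genes, missing)
  ks <- sort(unique(assignment$subclone))
  scores <- matrix(NA_real_, nrow = length(ks), ncol = length(present),
                   dimnames = list(paste0("subclone", ks), present))
  for (g in present) {
    per_cell <- rowMeans(profile$matrix[names(assignment$subclone),
                                        gene_windows[[g]], drop = FALSE])
    for (k in ks)
      scores[paste0("subclone", k), g] <-
        mean(per_cell[assignment$subclone == k])
  }
  attr(scores, "missing_genes") <- missing
  scores
}

#' Malignant to non-malignant cell ratio per cell type
#'
#' Counts malignant and non-malignant calls per cell type and reports their
#' ratio. When a type has zero non-malignant cells the ratio uses a +0.5
#' continuity correction on both counts and the row is flagged.
#'
#' @param calls a `malignancy_call`.
#' @param cell_types per-cell type labels, aligned with the call table (or a
#'   named vector over cell ids).
#' @return data.frame: cell_type, n_malignant, n_non_malignant, ratio,
#'   corrected.
#' @export
malignant_ratio <- function(calls, cell_types) {
  stopifnot(inherits(calls, "malignancy_call"))
  df <- calls$calls
  if (!is.null(names(cell_types))) cell_types <- cell_types[df$cell_id]
  if (length(cell_types) != nrow(df) || anyNA(cell_types))
    stop("every cell must have a type", call. = FALSE)
  out <- do.call(rbind, lapply(sort(unique(as.character(cell_types))), function(t) {
    m <- sum(df$label == "malignant" & cell_types == t)
    n <- sum(df$label == "non_malignant" & cell_types == t)
    corrected <- n == 0
    data.frame(cell_type = t, n_malignant = m, n_non_malignant = n,
               ratio = if (corrected) (m + 0.5) / (n + 0.5) else m / n,
               corrected = corrected)
  }))
  rownames(out) <- NULL
  out
}
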