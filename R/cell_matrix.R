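#' Single-cell expression container
#'
#' Bundles a genes x cells counts matrix with per-cell metadata. Metadata must
#' carry `cell_id` (matching the matrix column names) and `cell_type`; the
#' synthetic generator adds `sample`, `condition`, `stage` and truth columns.
#'
#' @param counts genes x cells numeric matrix with gene-id rownames and
#'   cell-id colnames.
#' @param meta data.frame of per-cell metadata with a `cell_id` column.
#' @return an object of class `cell_matrix` (list with `counts`, `meta`).
#' @export
cell_matrix <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene-id rownames and cell-id colnames", call. = FALSE)
  if (!"cell_id" %in% names(meta))
    stop("meta must contain a cell_id column", call. = FALSE)
  if (!identical(as.character(meta$cell_id), colnames(counts)))
    stop("meta$cell_id must match counts colnames in order", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in counts", call. = FALSE)
  structure(list(counts = counts, meta = as.data.frame(meta)),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  if ("cell_type" %in% names(x$meta)) {
    tt <- table(x$meta$cell_type)
    cat("cell types:", paste(sprintf("%s (%d)", names(tt), tt), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

# Accept either a cell_matrix or a bare matrix (+ optional labels).
as_counts <- function(x) {
  if (inherits(x, "cell_matrix")) x$counts else as.matrix(x)
}

#' Write a single-cell cohort to disk
#'
#' Writes MatrixMarket counts (`matrix.mtx`), `genes.tsv`, `metadata.tsv`,
#' gene coordinates as BED (`genes.bed`, 0-based half-open) and, when truth is
#' supplied, `truth.json`.
#'
#' @param cells a [cell_matrix].
#' @param catalog a gene catalog (see [generate_gene_catalog]).
#' @param dir output directory (created if missing).
#' @param truth optional synthetic-truth list to serialize as JSON.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cells, catalog, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(cells$counts, sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(gene_id = rownames(cells$counts)),
                     file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cells$meta, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bed <- data.frame(chrom = catalog$chromosome,
                    start = catalog$start,
                    end = catalog$start + 1L,
                    name = catalog$gene_id)
  utils::write.table(bed, file.path(dir, "genes.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a single-cell cohort written by [write_cohort]
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `metadata.tsv`.
#' @return a [cell_matrix].
#' @export
read_cohort <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"))
  meta <- utils::read.delim(file.path(dir, "metadata.tsv"))
  rownames(m) <- genes$gene_id
  colnames(m) <- meta$cell_id
  cell_matrix(m, meta)
}

#' Read gene coordinates from a BED file into a gene catalog
#'
#' Expects 0-based half-open BED with columns chrom/start/end/name. Genes are
#' ordered by start within each chromosome; `order_index` is the 0-based rank.
#'
#' @param path BED file path.
#' @return a gene catalog data.frame (see [generate_gene_catalog]).
#' @export
read_gene_catalog <- function(path) {
  bed <- utils::read.delim(path, header = FALSE)
  names(bed)[1:4] <- c("chromosome", "start", "end", "gene_id")
  cat_df <- bed[order(bed$chromosome, bed$start), ]
  idx <- unlist(lapply(split(seq_len(nrow(cat_df)), cat_df$chromosome),
                       function(i) seq_along(i) - 1L), use.names = FALSE)
  out <- data.frame(gene_id = cat_df$gene_id, chromosome = cat_df$chromosome,
                    start = as.integer(cat_df$start),
                    order_index = integer(nrow(cat_df)))
  out$order_index[order(out$chromosome, out$start)] <- idx
  validate_catalog(out)
  out
}

#' Write / read a bulk expression matrix as TSV (genes x samples)
#'
#' @param bulk genes x samples matrix with dimnames.
#' @param path file path.
#' @return `path` (write) or the matrix (read), invisibly for write.
#' @export
write_bulk <- function(bulk, path) {
  df <- data.frame(gene_id = rownames(bulk), bulk, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bulk
#' @export
read_bulk <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
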