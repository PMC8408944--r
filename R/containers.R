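#' Single-cell count matrix with cell and gene metadata
#'
#' Light container for a genes x cells UMI count matrix plus the per-cell
#' metadata the downstream analytics need (stage, treatment, and optionally
#' mother and state labels) and a per-gene transcription-factor flag.
#'
#' @param counts genes x cells matrix of non-negative integers (base matrix
#'   or any [Matrix::Matrix] sparse form). Must have unique row and column
#'   names (gene ids, cell barcodes).
#' @param cell_meta data.frame with one row per cell. Must contain a
#'   `stage` column and a `treatment` column (`"control"`/`"treated"`);
#'   `mother` and `state` columns are optional. Row order must match the
#'   columns of `counts`.
#' @param gene_meta optional data.frame with one row per gene and a logical
#'   `is_tf` column. Defaults to all-FALSE.
#' @return An object of class `sc_counts`: a list with elements `counts`,
#'   `cell_meta` (with a `barcode` column), and `gene_meta` (with a `gene`
#'   column).
#' @export
sc_counts <- function(counts, cell_meta, gene_meta = NULL) {
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stopf("counts must carry gene rownames and cell barcodes as colnames")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate gene identifiers in counts")
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate cell barcodes in counts")
  if (any(!is.finite(as.vector(counts[seq_len(min(nrow(counts), 1L)), ]))))
    stopf("counts contain non-finite values")
  if (nrow(cell_meta) != ncol(counts))
    stopf("cell_meta has %d rows but counts has %d cells",
          nrow(cell_meta), ncol(counts))
  if (!all(c("stage", "treatment") %in% names(cell_meta)))
    stopf("cell_meta must contain 'stage' and 'treatment' columns")
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  cell_meta$barcode <- colnames(counts)
  if (is.null(gene_meta)) {
    gene_meta <- data.frame(gene = rownames(counts),
                            is_tf = FALSE, stringsAsFactors = FALSE)
  } else {
    gene_meta <- as.data.frame(gene_meta, stringsAsFactors = FALSE)
    if (nrow(gene_meta) != nrow(counts))
      stopf("gene_meta has %d rows but counts has %d genes",
            nrow(gene_meta), nrow(counts))
    gene_meta$gene <- rownames(counts)
    if (is.null(gene_meta$is_tf)) gene_meta$is_tf <- FALSE
  }
  rownames(cell_meta) <- NULL
  rownames(gene_meta) <- NULL
  structure(list(counts = counts, cell_meta = cell_meta,
                 gene_meta = gene_meta),
            class = "sc_counts")
}

#' @export
print.sc_counts <- function(x, ...) {
  cat(sprintf("sc_counts: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  stages: %s\n",
              paste(unique(x$cell_meta$stage), collapse = ", ")))
  cat(sprintf("  treatments: %s\n",
              paste(unique(x$cell_meta$treatment), collapse = ", ")))
  if (!is.null(x$cell_meta$mother))
    cat(sprintf("  mothers: %s\n",
                paste(unique(x$cell_meta$mother), collapse = ", ")))
  invisible(x)
}

#' @export
dim.sc_counts <- function(x) dim(x$counts)

# subset cells of an sc_counts (internal)
subset_cells <- function(x, keep) {
  sc_counts(x$counts[, keep, drop = FALSE],
            x$cell_meta[keep, setdiff(names(x$cell_meta), "barcode"),
                        drop = FALSE],
            x$gene_meta)
}

#' Normalized expression container
#'
#' Genes x cells matrix of depth-normalized, log1p-transformed (and
#' optionally batch-corrected) expression together with the metadata of the
#' originating [sc_counts].
#'
#' @param expr genes x cells numeric matrix.
#' @param cell_meta,gene_meta as in [sc_counts()].
#' @param batch_corrected logical flag recording whether maternal batch
#'   regression was applied.
#' @return An object of class `sc_expr`.
#' @export
sc_expr <- function(expr, cell_meta, gene_meta, batch_corrected = FALSE) {
  structure(list(expr = expr, cell_meta = cell_meta, gene_meta = gene_meta,
                 batch_corrected = batch_corrected),
            class = "sc_expr")
}

#' @export
print.sc_expr <- function(x, ...) {
  cat(sprintf("sc_expr: %d genes x %d cells (batch_corrected = %s)\n",
              nrow(x$expr), ncol(x$expr), x$batch_corrected))
  invisible(x)
}

#' @export
dim.sc_expr <- function(x) dim(x$expr)
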