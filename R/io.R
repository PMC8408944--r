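#' Write a count matrix as Matrix Market + TSV sidecars
#'
#' Emits `matrix.mtx` (genes x cells), `genes.tsv` (gene id, is_tf flag),
#' `barcodes.tsv`, and `cell_metadata.tsv` into `dir`.
#'
#' @param x an [sc_counts] object.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(x, dir) {
  stopifnot(inherits(x, "sc_counts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(methods::as(Matrix::Matrix(x$counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  write.table(x$gene_meta[, c("gene", "is_tf")],
              file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  write.table(x$cell_meta, file.path(dir, "cell_metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix bundle written by [write_counts_mtx()]
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`, and `cell_metadata.tsv`.
#' @return An [sc_counts] object.
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- read.delim(file.path(dir, "genes.tsv"),
                      stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  meta <- read.delim(file.path(dir, "cell_metadata.tsv"),
                     stringsAsFactors = FALSE)
  if (nrow(m) != nrow(genes) || ncol(m) != length(barcodes))
    stopf("MTX dimensions (%d x %d) disagree with sidecar files in %s",
          nrow(m), ncol(m), dir)
  dimnames(m) <- list(genes$gene, barcodes)
  meta$barcode <- NULL
  sc_counts(m, meta, genes)
}

#' Write / read a cell x SNP dosage matrix as TSV
#'
#' Dosages are 0/1/2 with missing entries written as `NA`. Cells are rows;
#' the first column holds barcodes.
#'
#' @param g cells x SNPs integer matrix with dimnames (barcodes, SNP ids);
#'   missing calls are `NA`.
#' @param path file path.
#' @return `path` invisibly (write); the dosage matrix (read).
#' @export
write_dosage_tsv <- function(g, path) {
  df <- data.frame(barcode = rownames(g), g, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  g <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(g) <- "integer"
  rownames(g) <- df[[1]]
  g
}

#' Write / read a lineage edge list as TSV
#'
#' Columns `parent_state`, `child_state`, `stage` (stage of the child).
#'
#' @param edges data.frame with those three columns.
#' @param path file path.
#' @export
write_lineage_tsv <- function(edges, path) {
  stopifnot(all(c("parent_state", "child_state", "stage") %in% names(edges)))
  write.table(edges[, c("parent_state", "child_state", "stage")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lineage_tsv
#' @export
read_lineage_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a differential-expression table as TSV
#'
#' @param de data.frame as returned by [wilcoxon_de()].
#' @param path file path.
#' @export
write_de_tsv <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# named-list truth serialization helpers
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
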