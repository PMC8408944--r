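#' Filter cells by per-stage detected-gene thresholds
#'
#' Removes likely empty droplets / low-quality transcriptomes: a cell is
#' kept when the number of genes with at least one count meets the
#' threshold for its developmental stage. Defaults follow common practice
#' for staged whole-embryo data (64-cell: 1750, 112-cell: 2500,
#' mid-gastrula: 1500).
#'
#' @param x an [sc_counts] object.
#' @param min_genes named numeric vector mapping stage to the minimum
#'   number of detected genes.
#' @return The filtered [sc_counts]; cell order preserved.
#' @export
filter_cells <- function(x,
                         min_genes = c("64-cell" = 1750,
                                       "112-cell" = 2500,
                                       "mid-gastrula" = 1500)) {
  stopifnot(inherits(x, "sc_counts"))
  if (ncol(x$counts) == 0) return(x)
  stages <- x$cell_meta$stage
  missing_stage <- setdiff(unique(stages), names(min_genes))
  if (length(missing_stage))
    stopf("no detected-gene threshold configured for stage '%s'",
          missing_stage[1])
  detected <- Matrix::colSums(x$counts > 0)
  keep <- detected >= unname(min_genes[stages])
  subset_cells(x, keep)
}

#' Depth-normalize, log-transform, and batch-correct counts
#'
#' Per-cell counts are scaled so every cell has the median total count,
#' then log1p-transformed. When `batch` labels (mother-of-origin) are
#' given, each gene's within-batch mean is equalized to its global mean,
#' removing additive maternal offsets in log space. This is a deliberately
#' simple stand-in for regularized variance-stabilizing transforms: the
#' downstream statistics only require a normalized space with the maternal
#' batch signal removed.
#'
#' @param x an [sc_counts] object (or an `sc_expr` when `log1p = FALSE`,
#'   for re-running batch correction on already-transformed values).
#' @param batch optional per-cell batch labels (length = n cells), or the
#'   string `"mother"` to take them from `cell_meta$mother`.
#' @param log1p apply the log1p transform after depth scaling
#'   (default TRUE). With `log1p = FALSE` the depth-scaling step alone is
#'   idempotent on equal-depth input.
#' @return An [sc_expr] object.
#' @export
normalize_counts <- function(x, batch = NULL, log1p = TRUE) {
  stopifnot(inherits(x, "sc_counts"))
  m <- as.matrix(x$counts)
  depth <- colSums(m)
  if (any(depth == 0)) stopf("cells with zero total counts; filter first")
  sf <- depth / median(depth)
  expr <- sweep(m, 2, sf, "/")
  if (log1p) expr <- log1p(expr)

  corrected <- FALSE
  if (!is.null(batch)) {
    if (identical(batch, "mother")) batch <- x$cell_meta$mother
    if (length(batch) != ncol(expr))
      stopf("batch labels (%d) do not match cell count (%d)",
            length(batch), ncol(expr))
    sizes <- table(batch)
    small <- names(sizes)[sizes < 2]
    if (length(small))
      warnf("batch term skipped for singleton batch(es): %s",
            paste(small, collapse = ", "))
    use <- !(batch %in% small)
    if (any(use)) {
      b <- factor(batch[use])
      gmean <- rowMeans(expr[, use, drop = FALSE])
      bmean <- t(rowsum(t(expr[, use, drop = FALSE]), b) /
                   as.vector(table(b)))
      expr[, use] <- expr[, use, drop = FALSE] -
        bmean[, as.integer(b), drop = FALSE] + gmean
      corrected <- TRUE
    }
  }
  sc_expr(expr, x$cell_meta, x$gene_meta, batch_corrected = corrected)
}

#' Pseudo-bulk expression per cell state
#'
#' Arithmetic mean of normalized expression over the cells of each state.
#'
#' @param expr an [sc_expr] object or genes x cells matrix.
#' @param labels per-cell state labels; defaults to `cell_meta$state`.
#' @return A states x genes matrix (row per state).
#' @export
pseudobulk <- function(expr, labels = NULL) {
  m <- if (inherits(expr, "sc_expr")) expr$expr else expr
  if (is.null(labels)) labels <- expr$cell_meta$state
  if (length(labels) != ncol(m)) stopf("one label per cell required")
  if (anyNA(labels)) stopf("every cell must be labeled")
  f <- if (is.factor(labels)) labels else factor(labels)
  empty <- setdiff(levels(f), unique(as.character(f)))
  if (length(empty)) {
    warnf("states with no cells excluded: %s", paste(empty, collapse = ", "))
    f <- droplevels(f)
  }
  rowsum(t(m), f) / as.vector(table(f))
}

# Seurat-style log2 fold change between two cell groups of log1p expression
log2fc_groups <- function(m, cells_a, cells_b) {
  ma <- rowMeans(expm1(m[, cells_a, drop = FALSE]))
  mb <- rowMeans(expm1(m[, cells_b, drop = FALSE]))
  log2((ma + 1) / (mb + 1))
}

# two-sided Wilcoxon rank-sum p-value; exact enumeration when both groups
# are small (handles ties by enumerating the observed values), otherwise
# normal approximation with tie and continuity correction
ranksum_p <- function(xa, xb, exact_max = 8L) {
  na <- length(xa); nb <- length(xb); n <- na + nb
  r <- rank(c(xa, xb))
  w <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  if (na <= exact_max && nb <= exact_max) {
    sums <- colSums(combn(n, na, FUN = function(i) r[i]))
    return(mean(abs(sums - mu) >= abs(w - mu) - 1e-12))
  }
  ties <- table(r)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per-gene two-sided rank-sum test on normalized expression with tie
#' correction; exact enumeration is used when both groups have at most
#' `exact_max` cells, a tie/continuity-corrected normal approximation
#' otherwise. The fold change is the pseudocount-1 log2 ratio of de-logged
#' group means, the scale on which the package's 0.3 and 0.3475 cutoffs
#' are applied. Swapping the groups negates `log2FC` and leaves `p_value`
#' unchanged.
#'
#' @param expr an [sc_expr] object or genes x cells matrix of log1p values.
#' @param cells_a,cells_b column indices or barcode names of the two
#'   groups; both must be nonempty.
#' @param min_lfc report only genes with `|log2FC| >=` this (default 0:
#'   report all).
#' @param alpha report only genes with `p_value <` this (default 1).
#' @param genes optional subset of gene ids to test.
#' @param adjust_bh also report Benjamini-Hochberg adjusted p-values
#'   (computed over the tested genes) in column `p_adj`. Off by default;
#'   trio TF selection deliberately uses unadjusted p-values.
#' @param exact_max group-size bound for exact enumeration (default 8).
#' @return data.frame with columns `gene`, `log2FC`, `p_value`, `pct1`,
#'   `pct2` (fraction of expressing cells per group), ordered by p then
#'   |log2FC| descending.
#' @export
wilcoxon_de <- function(expr, cells_a, cells_b, min_lfc = 0, alpha = 1,
                        genes = NULL, adjust_bh = FALSE, exact_max = 8L) {
  m <- if (inherits(expr, "sc_expr")) expr$expr else expr
  if (is.character(cells_a)) cells_a <- match(cells_a, colnames(m))
  if (is.character(cells_b)) cells_b <- match(cells_b, colnames(m))
  if (length(cells_a) == 0 || length(cells_b) == 0)
    stopf("both cell groups must be nonempty")
  if (anyNA(cells_a) || anyNA(cells_b)) stopf("unknown cell barcodes")
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]

  lfc <- log2fc_groups(m, cells_a, cells_b)
  p <- vapply(seq_len(nrow(m)), function(g)
    ranksum_p(m[g, cells_a], m[g, cells_b], exact_max = exact_max),
    numeric(1))
  out <- data.frame(
    gene = rownames(m), log2FC = unname(lfc), p_value = p,
    pct1 = rowMeans(m[, cells_a, drop = FALSE] > 0),
    pct2 = rowMeans(m[, cells_b, drop = FALSE] > 0),
    stringsAsFactors = FALSE, row.names = NULL)
  if (adjust_bh) out$p_adj <- p.adjust(out$p_value, "BH")
  # strict p < alpha cutoff; the all-genes default (alpha = 1) must still
  # report genes with p exactly 1
  keep <- if (alpha >= 1) rep(TRUE, nrow(out)) else out$p_value < alpha
  out <- out[keep & abs(out$log2FC) >= min_lfc, , drop = FALSE]
  out[order(out$p_value, -abs(out$log2FC)), , drop = FALSE]
}

#' PCA embedding of cells
#'
#' Genes are centered (and unit-scaled when `scale_genes`); a deterministic
#' sign convention makes the embedding reproducible: within each component
#' the loading of largest magnitude is made positive.
#'
#' @param expr an [sc_expr] object or genes x cells matrix.
#' @param n_pcs number of components; must be `<= min(genes, cells) - 1`.
#' @param scale_genes unit-scale genes; constant genes are dropped with a
#'   warning.
#' @return An object of class `sc_embedding`: list with `scores`
#'   (cells x n_pcs), `rotation`, `center`, `scale`, `sdev`, `genes`.
#' @export
pca_embed <- function(expr, n_pcs, scale_genes = FALSE) {
  m <- if (inherits(expr, "sc_expr")) expr$expr else expr
  if (n_pcs > min(dim(m)) - 1)
    stopf("n_pcs = %d exceeds min(genes, cells) - 1 = %d",
          n_pcs, min(dim(m)) - 1)
  if (scale_genes) {
    v <- apply(m, 1, var)
    if (any(v == 0)) {
      warnf("%d constant gene(s) dropped before scaling", sum(v == 0))
      m <- m[v > 0, , drop = FALSE]
    }
  }
  pc <- prcomp(t(m), center = TRUE, scale. = scale_genes, rank. = n_pcs)
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  structure(list(scores = pc$x, rotation = pc$rotation,
                 center = pc$center,
                 scale = if (scale_genes) pc$scale else FALSE,
                 sdev = pc$sdev, genes = rownames(m)),
            class = "sc_embedding")
}

#' @export
print.sc_embedding <- function(x, ...) {
  cat(sprintf("sc_embedding: %d cells x %d PCs\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

# project new cells into an existing embedding
project_embedding <- function(emb, m) {
  m <- m[emb$genes, , drop = FALSE]
  xs <- t(m) - rep(emb$center, each = ncol(m))
  if (!identical(emb$scale, FALSE))
    xs <- xs / rep(emb$scale, each = ncol(m))
  xs %*% emb$rotation
}

#' Nearest-centroid label transfer
#'
#' Stand-in classifier for anchor-based label transfer: a PCA embedding is
#' fit on the reference cells, query cells are projected into it, and each
#' is assigned the label of the nearest reference class centroid.
#' Confidence is the softmax of negative centroid distances. Ties break
#' deterministically towards the first label in sort order.
#'
#' @param ref_expr,query_expr [sc_expr] objects or genes x cells matrices
#'   sharing (a superset of) the same gene space.
#' @param ref_labels per-reference-cell state labels.
#' @param n_pcs number of reference PCs (default 20, capped at valid max).
#' @return data.frame with columns `barcode`, `label`, `confidence`.
#' @export
transfer_labels <- function(ref_expr, ref_labels, query_expr, n_pcs = 20) {
  rm_ <- if (inherits(ref_expr, "sc_expr")) ref_expr$expr else ref_expr
  qm <- if (inherits(query_expr, "sc_expr")) query_expr$expr else query_expr
  shared <- intersect(rownames(rm_), rownames(qm))
  if (length(shared) == 0) stopf("reference and query share no genes")
  rm_ <- rm_[shared, , drop = FALSE]; qm <- qm[shared, , drop = FALSE]
  n_pcs <- min(n_pcs, min(dim(rm_)) - 1)
  emb <- pca_embed(rm_, n_pcs = n_pcs)
  labs <- sort(unique(as.character(ref_labels)))
  cent <- rowsum(emb$scores, factor(ref_labels, levels = labs)) /
    as.vector(table(factor(ref_labels, levels = labs)))
  q <- project_embedding(emb, qm)
  d2 <- outer(rowSums(q^2), rep(1, nrow(cent))) -
    2 * q %*% t(cent) + outer(rep(1, nrow(q)), rowSums(cent^2))
  d <- sqrt(pmax(d2, 0))
  # tolerant argmin: exact ties (up to float noise) break towards the
  # first label in sort order
  pick <- apply(d, 1, function(x) which(x <= min(x) + 1e-9)[1])
  sm <- exp(-d - apply(-d, 1, max))
  conf <- sm[cbind(seq_len(nrow(sm)), pick)] / rowSums(sm)
  data.frame(barcode = colnames(qm) %||% as.character(seq_len(ncol(qm))),
             label = labs[pick], confidence = unname(conf),
             stringsAsFactors = FALSE)
}
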