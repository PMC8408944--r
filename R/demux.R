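#' Pairwise Ajk genetic relatedness between cells
#'
#' For cells j and k the unadjusted Ajk statistic is the allele-frequency
#' standardized genotype covariance averaged over the SNPs called in both
#' cells:
#' \deqn{A_{jk} = \frac{1}{N_{jk}} \sum_i
#'   \frac{(g_{ij} - 2p_i)(g_{ik} - 2p_i)}{2 p_i (1 - p_i)}}
#' with dosages \eqn{g \in \{0,1,2\}} and in-sample alternate-allele
#' frequency \eqn{p_i} computed over non-missing calls. Cells sharing a
#' mother have systematically elevated Ajk.
#'
#' SNPs are used only when they have at least `min_calls` non-missing
#' calls and `p_i` inside `maf_range` (degenerate denominators excluded).
#'
#' @param g cells x SNPs dosage matrix (0/1/2, `NA` = missing) with cell
#'   barcodes as rownames.
#' @param allele_freq optional per-SNP alternate-allele frequencies; by
#'   default computed in-sample.
#' @param min_calls minimum non-missing calls for a SNP to be used.
#' @param maf_range allowed frequency range (inclusive).
#' @return An object of class `relatedness`: list with `A` (cells x cells
#'   symmetric Ajk matrix; entries with no shared SNP are `NA`), `N`
#'   (per-pair shared-SNP counts), and `snps_used`.
#' @export
ajk_relatedness <- function(g, allele_freq = NULL, min_calls = 10,
                            maf_range = c(0.05, 0.95)) {
  if (nrow(g) < 2) stopf("at least two cells required")
  if (ncol(g) == 0) stopf("no SNPs supplied (no information)")
  called <- colSums(!is.na(g))
  p <- if (is.null(allele_freq)) colMeans(g, na.rm = TRUE) / 2
       else allele_freq
  usable <- called >= min_calls & !is.na(p) &
    p >= maf_range[1] & p <= maf_range[2]
  if (!any(usable))
    stopf("no usable SNP after filtering (min_calls = %d, maf in [%g, %g])",
          min_calls, maf_range[1], maf_range[2])
  g <- g[, usable, drop = FALSE]
  p <- p[usable]

  x <- sweep(g, 2, 2 * p, "-")
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  m <- !is.na(g)
  x[!m] <- 0
  num <- x %*% t(x)
  n_jk <- m %*% t(m)
  a <- num / n_jk
  if (any(n_jk == 0)) {
    warnf("%d cell pair(s) share no called SNP; entries set to NA",
          sum(n_jk[upper.tri(n_jk)] == 0))
    a[n_jk == 0] <- NA
  }
  dimnames(a) <- dimnames(n_jk) <- list(rownames(g), rownames(g))
  structure(list(A = a, N = n_jk, snps_used = colnames(g) %||% which(usable)),
            class = "relatedness")
}

#' @export
print.relatedness <- function(x, ...) {
  cat(sprintf("relatedness: %d cells, %d usable SNPs\n",
              nrow(x$A), length(x$snps_used)))
  invisible(x)
}

#' Cluster cells into mothers-of-origin from a relatedness matrix
#'
#' Relatedness is turned into the distance `max(A) - A` (Ajk is unbounded
#' above, so `1 - A` would go negative), cells are clustered
#' agglomeratively, and the tree is cut at exactly `k_mothers` clusters --
#' the codified version of selecting a dendrogram cutoff that mirrors the
#' known number of adults.
#'
#' @param rel a [ajk_relatedness()] result or a symmetric relatedness
#'   matrix.
#' @param k_mothers number of adults; must be `>= 2` and `<=` cell count.
#' @param linkage agglomeration method (default `"average"`, robust for
#'   block-structured relatedness).
#' @return list with `labels` (named integer vector of mother ids),
#'   `hclust` (the dendrogram), and `distance` (the distance matrix used).
#' @export
cluster_mothers <- function(rel, k_mothers, linkage = "average") {
  a <- if (inherits(rel, "relatedness")) rel$A else rel
  if (k_mothers < 2) stopf("k_mothers must be at least 2")
  if (k_mothers > nrow(a))
    stopf("k_mothers = %d exceeds the number of cells (%d)",
          k_mothers, nrow(a))
  if (anyNA(a[upper.tri(a)])) {
    warnf("missing relatedness entries imputed to column medians")
    for (j in seq_len(ncol(a))) {
      miss <- is.na(a[, j]); miss[j] <- FALSE
      a[miss, j] <- median(a[, j], na.rm = TRUE)
    }
    a <- (a + t(a)) / 2
  }
  d <- max(a[upper.tri(a)]) - a
  diag(d) <- 0
  h <- hclust(as.dist(d), method = linkage)
  labels <- cutree(h, k = k_mothers)
  list(labels = labels, hclust = h, distance = d)
}

#' Flag cells that sit poorly in their mother cluster
#'
#' A cell is dropped when its mean relatedness to the other members of its
#' cluster falls below the cluster's lower `min_quantile` quantile of that
#' statistic (strict inequality, so a degenerate cluster where every cell
#' is identical keeps all members). Clusters with fewer than 3 cells are
#' too small for the statistic: all their members are flagged for manual
#' review rather than auto-dropped.
#'
#' @param rel a [ajk_relatedness()] result or relatedness matrix.
#' @param labels per-cell cluster labels from [cluster_mothers()].
#' @param min_quantile lower quantile threshold (default 0.01).
#' @return data.frame with columns `barcode`, `mother`,
#'   `mean_within_relatedness`, `keep`, `review`.
#' @export
flag_outliers <- function(rel, labels, min_quantile = 0.01) {
  a <- if (inherits(rel, "relatedness")) rel$A else rel
  stopifnot(length(labels) == nrow(a))
  bc <- rownames(a) %||% as.character(seq_len(nrow(a)))
  mean_within <- numeric(length(labels))
  keep <- rep(TRUE, length(labels))
  review <- rep(FALSE, length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 3) {
      review[idx] <- TRUE
      mean_within[idx] <- if (length(idx) == 2)
        a[idx[1], idx[2]] else NA_real_
      next
    }
    sub <- a[idx, idx, drop = FALSE]
    diag(sub) <- NA
    mw <- rowMeans(sub, na.rm = TRUE)
    mean_within[idx] <- mw
    thr <- quantile(mw, min_quantile, na.rm = TRUE, names = FALSE)
    keep[idx] <- mw >= thr
  }
  data.frame(barcode = bc, mother = unname(labels),
             mean_within_relatedness = mean_within,
             keep = keep, review = review, stringsAsFactors = FALSE)
}

#' One-call demultiplexing: relatedness, clustering, outlier flags
#'
#' @inheritParams ajk_relatedness
#' @inheritParams cluster_mothers
#' @inheritParams flag_outliers
#' @return list with `assignments` (the [flag_outliers()] table),
#'   `relatedness`, and `hclust`.
#' @export
demux_mothers <- function(g, k_mothers, linkage = "average",
                          min_quantile = 0.01, allele_freq = NULL,
                          min_calls = 10, maf_range = c(0.05, 0.95)) {
  rel <- ajk_relatedness(g, allele_freq = allele_freq,
                         min_calls = min_calls, maf_range = maf_range)
  cl <- cluster_mothers(rel, k_mothers, linkage = linkage)
  flags <- flag_outliers(rel, cl$labels, min_quantile = min_quantile)
  list(assignments = flags, relatedness = rel, hclust = cl$hclust)
}

#' Attach mother labels to a count matrix and batch-correct
#'
#' Adds the mother-of-origin label to the cell metadata (dropping cells the
#' demultiplexer did not keep) and delegates to [normalize_counts()] with
#' mother as the batch variable, so per-gene maternal means are equalized.
#'
#' @param x an [sc_counts] object.
#' @param assignments [flag_outliers()]/[demux_mothers()] assignment table,
#'   or a named vector of mother labels keyed by barcode.
#' @param drop_unkept drop cells with `keep == FALSE` (default TRUE).
#' @return list with `counts` (the labeled, subset [sc_counts]) and `expr`
#'   (the batch-corrected [sc_expr]).
#' @export
attach_and_regress <- function(x, assignments, drop_unkept = TRUE) {
  stopifnot(inherits(x, "sc_counts"))
  if (is.data.frame(assignments)) {
    keep_bc <- assignments$barcode[
      if (drop_unkept) assignments$keep else TRUE]
    mother <- setNames(assignments$mother, assignments$barcode)
  } else {
    keep_bc <- names(assignments)
    mother <- assignments
  }
  # every cell of x must be accounted for: either labeled or explicitly
  # flagged for dropping by the demultiplexer
  unlabeled <- setdiff(colnames(x$counts), names(mother))
  if (length(unlabeled))
    stopf("retained cells without a mother label: %s",
          paste(head(unlabeled, 5), collapse = ", "))
  retained <- colnames(x$counts)[colnames(x$counts) %in% keep_bc]
  xs <- subset_cells(x, colnames(x$counts) %in% retained)
  xs$cell_meta$mother <- unname(mother[xs$cell_meta$barcode])
  expr <- normalize_counts(xs, batch = "mother")
  list(counts = xs, expr = expr)
}
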