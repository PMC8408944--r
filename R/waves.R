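#' Union of per-stage enriched genes
#'
#' A gene belongs to the focal tissue's enriched set if it passes the
#' significance and fold-change cutoffs in the focal-vs-all-others
#' comparison at any stage.
#'
#' @param de_by_stage list of [wilcoxon_de()] data.frames (one per stage).
#' @param alpha p-value cutoff (default 0.05).
#' @param min_lfc minimum (positive) log2 fold-change (default 0.3).
#' @return Character vector of gene ids.
#' @export
enriched_union <- function(de_by_stage, alpha = 0.05, min_lfc = 0.3) {
  sets <- lapply(de_by_stage, function(de)
    de$gene[de$p_value < alpha & de$log2FC >= min_lfc])
  unique(unlist(sets))
}

#' Ward clustering of temporal expression profiles into waves
#'
#' Rows (genes) are scaled (default: divided by their maximum, so each
#' profile peaks at 1 and the clustering is invariant to uniform positive
#' rescaling), then clustered with Ward's variance-minimization linkage on
#' Euclidean distances. The tree is cut either to `k` clusters or at
#' `cut_height`. Wave ids are relabeled in order of each wave's
#' mean-profile peak stage, for stable cross-run naming.
#'
#' @param profiles genes x stages numeric matrix, columns in developmental
#'   time order.
#' @param k target number of waves (default mode).
#' @param cut_height alternative: cut the dendrogram at this height.
#' @param scale `"max"` (default), `"zscore"`, or `"none"`.
#' @return list of class `wave_assignment`: `waves` (named integer vector,
#'   gene -> wave), `hclust`, `k`, `scaled` (the matrix clustered),
#'   `peak_stage` (named by wave id).
#' @export
wave_cluster <- function(profiles, k = NULL, cut_height = NULL,
                         scale = c("max", "zscore", "none")) {
  scale <- match.arg(scale)
  if (nrow(profiles) < 2) stopf("at least two genes required")
  if (is.null(k) == is.null(cut_height))
    stopf("supply exactly one of k or cut_height")
  if (!is.null(k) && k > nrow(profiles))
    stopf("k = %d exceeds the number of genes (%d)", k, nrow(profiles))
  m <- as.matrix(profiles)
  if (scale == "max") {
    mx <- apply(m, 1, max)
    m[mx > 0, ] <- m[mx > 0, , drop = FALSE] / mx[mx > 0]
  } else if (scale == "zscore") {
    m <- t(scale(t(m)))
    m[is.nan(m)] <- 0
  }
  h <- hclust(dist(m), method = "ward.D2")
  cl <- if (!is.null(k)) cutree(h, k = k) else cutree(h, h = cut_height)
  # order wave ids by peak stage of the wave mean profile
  waves <- sort(unique(cl))
  peak <- vapply(waves, function(w)
    which.max(colMeans(m[cl == w, , drop = FALSE])), integer(1))
  relabel <- match(cl, waves[order(peak, waves)])
  names(relabel) <- rownames(profiles)
  structure(list(waves = relabel, hclust = h, k = length(waves),
                 scaled = m,
                 peak_stage = setNames(sort(peak),
                                       seq_along(peak))),
            class = "wave_assignment")
}

#' @export
print.wave_assignment <- function(x, ...) {
  cat(sprintf("wave_assignment: %d genes in %d waves\n",
              length(x$waves), x$k))
  print(table(x$waves))
  invisible(x)
}

#' Write a wave dendrogram as Newick
#'
#' @param wc a [wave_cluster()] result.
#' @param path output file.
#' @export
wave_newick <- function(wc, path) {
  ph <- ape::as.phylo(wc$hclust)
  ape::write.tree(ph, file = path)
  invisible(path)
}

#' Per-stage motif enrichment time course
#'
#' For each motif and stage, the combined enrichment z of the stage's
#' enriched gene set (target) versus its depleted set (control), via
#' [tfbs_enrichment()]. Early/late epoch means summarize the trajectory
#' (defaults: first half of the stages vs the rest).
#'
#' @param regions an [extract_regions()] result.
#' @param pwms list of [pwm_build()] objects.
#' @param enriched_by_stage,depleted_by_stage named lists (stage ->
#'   gene id vector), in developmental order.
#' @param early_stages,late_stages stage name vectors for the epoch means.
#' @inheritParams tfbs_enrichment
#' @return list with `z` (pwm x stage matrix, NA where a stage had an
#'   empty set), `early_mean`, `late_mean` (named by pwm),
#'   `missing_stages`.
#' @export
tfbs_timecourse <- function(regions, pwms, enriched_by_stage,
                            depleted_by_stage, early_stages = NULL,
                            late_stages = NULL, min_rel = 0.85) {
  stages <- names(enriched_by_stage)
  stopifnot(identical(stages, names(depleted_by_stage)))
  if (is.null(names(pwms)))
    names(pwms) <- vapply(pwms, `[[`, "", "name")
  z <- matrix(NA_real_, nrow = length(pwms), ncol = length(stages),
              dimnames = list(names(pwms), stages))
  missing_stages <- character()
  for (s in stages) {
    tg <- enriched_by_stage[[s]]; cg <- depleted_by_stage[[s]]
    if (length(tg) == 0 || length(cg) == 0) {
      missing_stages <- c(missing_stages, s)
      next
    }
    for (p in names(pwms))
      z[p, s] <- tfbs_enrichment(regions, pwms[[p]], tg, cg,
                                 min_rel = min_rel)$z
  }
  if (is.null(early_stages))
    early_stages <- stages[seq_len(ceiling(length(stages) / 2))]
  if (is.null(late_stages))
    late_stages <- setdiff(stages, early_stages)
  list(z = z,
       early_mean = rowMeans(z[, early_stages, drop = FALSE], na.rm = TRUE),
       late_mean = rowMeans(z[, late_stages, drop = FALSE], na.rm = TRUE),
       missing_stages = missing_stages)
}
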