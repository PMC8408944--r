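#' Yates-corrected chi-square test for a 2x2 table
#'
#' Textbook test of independence with continuity correction: expected
#' counts from the margins, correction `min(0.5, |O - E|)` per cell,
#' statistic `sum((|O - E| - correction)^2 / E)` on 1 degree of freedom.
#' Matches the base-R default for 2x2 tables.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return list with `statistic`, `p_value` (NA when a margin is zero).
#' @export
yates_chisq <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  if (any(e == 0) || n == 0)
    return(list(statistic = NA_real_, p_value = NA_real_))
  dev <- abs(tab - e)
  stat <- sum((dev - pmin(0.5, dev))^2 / e)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Score every bifurcation for sensitivity to a lineage-ablating treatment
#'
#' For each bifurcation, each sibling's cell count is the sum over its
#' terminal-stage descendant states, per treatment. A Yates-corrected
#' chi-square test on the resulting 2x2 table (sibling x treatment) asks
#' whether treatment shifts the sibling proportions; the score is
#' `-log10(p)` with p floored at 1e-300. When a bifurcation is sensitive,
#' the sibling depleted under treatment is considered eliminated and every
#' bifurcation inside its subtree is marked untestable (its cell types are
#' typically absent from treated embryos). A bifurcation where both
#' siblings have zero cells in a treatment is untestable with a recorded
#' reason.
#'
#' @param tree a [build_lineage()] tree.
#' @param cell_meta data.frame with `state` and `treatment` columns (one
#'   row per cell), or a precomputed state x treatment count table.
#' @param alpha significance level (default 0.05).
#' @param treatments the two treatment labels, control first.
#' @return data.frame, one row per bifurcation: sibling descendant counts
#'   per treatment, `chisq`, `p_value`, `score`, `status` (`sensitive`,
#'   `insensitive`, `untestable`), `eliminated_sibling`, `reason`.
#' @export
fgf_sensitivity <- function(tree, cell_meta, alpha = 0.05,
                            treatments = c("control", "treated")) {
  stopifnot(inherits(tree, "lineage_tree"))
  counts <- if (is.table(cell_meta) || is.matrix(cell_meta)) {
    as.matrix(cell_meta)
  } else {
    as.matrix(table(factor(cell_meta$state,
                           levels = tree$nodes$state),
                    factor(cell_meta$treatment, levels = treatments)))
  }
  term <- tree$terminal_stage
  desc_count <- function(state, trt) {
    d <- lineage_descendants(tree, state, at_stage = term)
    sum(counts[intersect(d, rownames(counts)), trt])
  }

  bif <- tree$bifurcations
  st_idx <- setNames(tree$nodes$stage_idx, tree$nodes$state)
  bif <- bif[order(st_idx[bif$parent]), , drop = FALSE]
  excluded <- character()  # states inside eliminated subtrees
  rows <- vector("list", nrow(bif))
  for (i in seq_len(nrow(bif))) {
    p <- bif$parent[i]; s1 <- bif$sib1[i]; s2 <- bif$sib2[i]
    tab <- matrix(c(desc_count(s1, treatments[1]),
                    desc_count(s1, treatments[2]),
                    desc_count(s2, treatments[1]),
                    desc_count(s2, treatments[2])),
                  nrow = 2, byrow = TRUE)
    row <- data.frame(parent = p, sib1 = s1, sib2 = s2,
                      n1_control = tab[1, 1], n1_treated = tab[1, 2],
                      n2_control = tab[2, 1], n2_treated = tab[2, 2],
                      chisq = NA_real_, p_value = NA_real_,
                      score = NA_real_, status = "untestable",
                      eliminated_sibling = NA_character_,
                      reason = NA_character_, stringsAsFactors = FALSE)
    if (p %in% excluded) {
      row$reason <- "ancestor eliminated by treatment"
    } else if (any(colSums(tab) == 0)) {
      row$reason <- sprintf("no cells in %s condition",
                            treatments[which(colSums(tab) == 0)[1]])
    } else {
      ch <- yates_chisq(tab)
      row$chisq <- ch$statistic
      row$p_value <- ch$p_value
      row$score <- -log10(max(ch$p_value, 1e-300))
      if (is.na(ch$p_value)) {
        row$reason <- "degenerate margins"
      } else if (ch$p_value < alpha) {
        row$status <- "sensitive"
        # depleted sibling: larger drop in treated share
        ratio1 <- (tab[1, 2] + 0.5) / (tab[1, 1] + 0.5)
        ratio2 <- (tab[2, 2] + 0.5) / (tab[2, 1] + 0.5)
        elim <- if (ratio1 < ratio2) s1 else s2
        row$eliminated_sibling <- elim
        excluded <- union(excluded, lineage_descendants(tree, elim))
      } else {
        row$status <- "insensitive"
      }
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trio threshold configuration
#'
#' Houses the log2 fold-change boundaries used to call a daughter
#' up/down/unchanged versus the parental state and the significance level
#' for the sibling-vs-sibling test.
#'
#' @param up_threshold log2 units; a daughter is "up" when its
#'   daughter-vs-parent log2FC exceeds this (default 0.3475, i.e. a ~27%
#'   increase).
#' @param down_threshold must equal `-up_threshold`.
#' @param sibling_alpha p-value cutoff for sibling-DE TF selection.
#' @return list of class `trio_config`.
#' @export
trio_config <- function(up_threshold = 0.3475,
                        down_threshold = -up_threshold,
                        sibling_alpha = 0.05) {
  if (!(up_threshold > 0 && isTRUE(all.equal(down_threshold, -up_threshold))))
    stopf("up_threshold must be positive and equal to -down_threshold")
  structure(list(up_threshold = up_threshold,
                 down_threshold = down_threshold,
                 sibling_alpha = sibling_alpha), class = "trio_config")
}

#' Classify a (daughter1, daughter2) fold-change pair into a mechanism
#'
#' Daughter 1 is the sibling with the higher expression of the TF (higher
#' sibling-vs-sibling log2FC). With "up" meaning daughter-vs-parent log2FC
#' above the threshold and "down" below its negative:
#' category 1 = up / unchanged, 2 = both up (unequal), 3 = up / down,
#' 4 = unchanged / down, 5 = both down (unequal). Both unchanged is
#' unclassifiable (`NA`).
#'
#' @param d1,d2 numeric vectors of daughter-vs-parent log2 fold-changes
#'   (daughter 1 = higher-expressing sibling).
#' @param cfg a [trio_config()].
#' @return Integer vector of categories in 1..5, `NA` for unclassified.
#' @export
classify_mechanism <- function(d1, d2, cfg = trio_config()) {
  hi <- pmax(d1, d2); lo <- pmin(d1, d2)
  thr <- cfg$up_threshold
  state <- function(x) ifelse(x > thr, 1L, ifelse(x < -thr, -1L, 0L))
  s_hi <- state(hi); s_lo <- state(lo)
  out <- rep(NA_integer_, length(d1))
  out[s_hi == 1 & s_lo == 0] <- 1L
  out[s_hi == 1 & s_lo == 1] <- 2L
  out[s_hi == 1 & s_lo == -1] <- 3L
  out[s_hi == 0 & s_lo == -1] <- 4L
  out[s_hi == -1 & s_lo == -1] <- 5L
  out
}

#' Classify the sibling-DE transcription factors of a trio
#'
#' Takes a parent state and its two daughter states, finds the TFs
#' differentially expressed between the siblings (Wilcoxon,
#' `p < cfg$sibling_alpha`, unadjusted), orients each TF so daughter 1 is
#' the sibling with higher expression, computes both daughters'
#' log2 fold-changes versus the parent, and assigns the mechanism category
#' via [classify_mechanism()].
#'
#' @param expr an [sc_expr] with `state` labels in its cell metadata.
#' @param parent,sib1,sib2 state labels of the trio.
#' @param tf_genes TF gene ids; defaults to genes flagged `is_tf` in the
#'   gene metadata.
#' @param cfg a [trio_config()].
#' @return data.frame: `gene`, `sib_log2FC` (sib1 vs sib2 as supplied),
#'   `p_value`, `daughter1`, `delta1`, `delta2`, `category` (NA =
#'   unclassified).
#' @export
classify_trio_tfs <- function(expr, parent, sib1, sib2, tf_genes = NULL,
                              cfg = trio_config()) {
  stopifnot(inherits(expr, "sc_expr"))
  states <- expr$cell_meta$state
  cells_p <- which(states == parent)
  cells_1 <- which(states == sib1)
  cells_2 <- which(states == sib2)
  if (length(cells_p) == 0)
    stopf("parent state '%s' has no cells (missing parent expression)",
          parent)
  if (length(cells_1) == 0 || length(cells_2) == 0)
    stopf("sibling state without cells")
  if (is.null(tf_genes)) tf_genes <- expr$gene_meta$gene[expr$gene_meta$is_tf]
  if (length(tf_genes) == 0) stopf("no TF genes flagged or supplied")

  de <- wilcoxon_de(expr, cells_1, cells_2, genes = tf_genes,
                    alpha = cfg$sibling_alpha)
  if (nrow(de) == 0)
    return(data.frame(gene = character(), sib_log2FC = numeric(),
                      p_value = numeric(), daughter1 = character(),
                      delta1 = numeric(), delta2 = numeric(),
                      category = integer(), stringsAsFactors = FALSE))
  m <- expr$expr[de$gene, , drop = FALSE]
  lfc1 <- log2fc_groups(m, cells_1, cells_p)
  lfc2 <- log2fc_groups(m, cells_2, cells_p)
  d1 <- ifelse(de$log2FC >= 0, lfc1, lfc2)
  d2 <- ifelse(de$log2FC >= 0, lfc2, lfc1)
  data.frame(gene = de$gene, sib_log2FC = de$log2FC,
             p_value = de$p_value,
             daughter1 = ifelse(de$log2FC >= 0, sib1, sib2),
             delta1 = unname(d1), delta2 = unname(d2),
             category = classify_mechanism(d1, d2, cfg),
             stringsAsFactors = FALSE)
}

#' Summarize mechanism category proportions across trios
#'
#' Percentages are over classified TF-by-trio instances (the unclassified
#' bucket is excluded from the denominator, so categories 1-5 sum to 100).
#' "Up in either" is the share of classified instances where at least one
#' daughter is up versus the parent (categories 1-3); "down in either" is
#' the analog (categories 3-5), so category 3 contributes to both.
#'
#' @param categories integer vector of categories (NA = unclassified), or
#'   a data.frame with a `category` column (e.g. rbind-ed
#'   [classify_trio_tfs()] outputs).
#' @return list with `percent` (named, categories "1".."5"),
#'   `up_in_either`, `down_in_either` (percent), `n_classified`,
#'   `n_unclassified`.
#' @export
category_proportions <- function(categories) {
  if (is.data.frame(categories)) categories <- categories$category
  n_un <- sum(is.na(categories))
  cl <- categories[!is.na(categories)]
  if (length(cl) == 0)
    return(list(percent = setNames(rep(NA_real_, 5), as.character(1:5)),
                up_in_either = NA_real_, down_in_either = NA_real_,
                n_classified = 0L, n_unclassified = n_un))
  tab <- table(factor(cl, levels = 1:5))
  pct <- 100 * as.vector(tab) / length(cl)
  names(pct) <- as.character(1:5)
  list(percent = pct,
       up_in_either = sum(pct[c("1", "2", "3")]),
       down_in_either = sum(pct[c("3", "4", "5")]),
       n_classified = length(cl), n_unclassified = n_un)
}

#' Induction metric: which sibling carries the TF upregulation mass?
#'
#' Among the TFs differentially expressed between two siblings, each
#' sibling's upregulation mass is the summed |log2FC| of the TFs
#' upregulated in it (positive sibling-vs-sibling log2FC counts toward
#' sibling 1, negative toward sibling 2). The sibling with the larger
#' share is predicted to be the signal-induced one. A count-based variant
#' (number of upregulated TFs instead of summed mass) is available behind
#' `count_based`; no fidelity claim is attached to either reading beyond
#' their shared qualitative behavior. The metric is invariant to scaling
#' all fold-changes by a positive constant.
#'
#' @param de_tfs data.frame of sibling-DE TFs with a `log2FC` column
#'   (sib1 vs sib2), e.g. a filtered [wilcoxon_de()] result.
#' @param sib1,sib2 labels used in the output.
#' @param count_based use TF counts instead of summed |log2FC|.
#' @return list with `U1`, `U2`, `share1` (= U1/(U1+U2)), `predicted`
#'   (sibling label or NA on an exact tie), `tie` flag.
#' @export
induction_metric <- function(de_tfs, sib1 = "sib1", sib2 = "sib2",
                             count_based = FALSE) {
  if (nrow(de_tfs) == 0)
    stopf("no differentially expressed TFs; induction metric undefined")
  lfc <- de_tfs$log2FC
  if (count_based) {
    u1 <- sum(lfc > 0); u2 <- sum(lfc < 0)
  } else {
    u1 <- sum(abs(lfc[lfc > 0])); u2 <- sum(abs(lfc[lfc < 0]))
  }
  if (u1 + u2 == 0)
    stopf("zero total upregulation mass; induction metric undefined")
  share1 <- u1 / (u1 + u2)
  tie <- u1 == u2
  list(U1 = u1, U2 = u2, share1 = share1,
       predicted = if (tie) NA_character_ else if (u1 > u2) sib1 else sib2,
       tie = tie)
}

#' Euclidean distance between two state centroids in an embedding
#'
#' @param embedding an `sc_embedding` (from [pca_embed()]) or a
#'   cells x dims coordinate matrix.
#' @param labels per-cell state labels.
#' @param sib1,sib2 the two states.
#' @return Non-negative distance between the centroids.
#' @export
sibling_distance <- function(embedding, labels, sib1, sib2) {
  coords <- if (inherits(embedding, "sc_embedding")) embedding$scores
            else embedding
  if (!all(c(sib1, sib2) %in% labels))
    stopf("state '%s' absent from embedding",
          setdiff(c(sib1, sib2), labels)[1])
  c1 <- colMeans(coords[labels == sib1, , drop = FALSE])
  c2 <- colMeans(coords[labels == sib2, , drop = FALSE])
  sqrt(sum((c1 - c2)^2))
}

#' Fold-change matrix of TFs across treatment-sensitive bifurcations
#'
#' For every sensitive bifurcation, computes the log2 fold-change of TFs
#' in the treatment-dependent (eliminated) sibling versus its sibling
#' (control cells). TFs qualifying as significantly DE in at least one
#' sensitive bifurcation are kept, the `top_n` most variable across
#' bifurcations retained, and rows/columns ordered by average-linkage
#' hierarchical clustering -- the representation in which a globally
#' induced TF appears as an all-positive row.
#'
#' @param expr an [sc_expr] with `state` cell labels.
#' @param fgf_results output of [fgf_sensitivity()].
#' @param tf_genes TF gene ids; defaults to the `is_tf` flag.
#' @param alpha significance cutoff for the qualifying test.
#' @param top_n keep this many most-variable qualifying TFs (default 50).
#' @return list with `matrix` (TF x bifurcation log2FC, clustered order),
#'   `row_hclust`, `col_hclust` (NULL when fewer than 3 rows/columns).
#' @export
fgf_response_matrix <- function(expr, fgf_results, tf_genes = NULL,
                                alpha = 0.05, top_n = 50) {
  sens <- fgf_results[fgf_results$status == "sensitive", , drop = FALSE]
  if (nrow(sens) == 0) stopf("no sensitive bifurcations")
  if (is.null(tf_genes)) tf_genes <- expr$gene_meta$gene[expr$gene_meta$is_tf]
  states <- expr$cell_meta$state
  ctrl <- expr$cell_meta$treatment == "control"

  lfc <- matrix(NA_real_, nrow = length(tf_genes), ncol = nrow(sens),
                dimnames = list(tf_genes, paste0(sens$parent, ":",
                                                 sens$eliminated_sibling)))
  qualify <- rep(FALSE, length(tf_genes))
  for (i in seq_len(nrow(sens))) {
    dep <- sens$eliminated_sibling[i]
    if (is.na(dep)) dep <- sens$sib1[i]
    other <- if (dep == sens$sib1[i]) sens$sib2[i] else sens$sib1[i]
    ca <- which(states == dep & ctrl); cb <- which(states == other & ctrl)
    if (length(ca) == 0 || length(cb) == 0) next
    de <- wilcoxon_de(expr, ca, cb, genes = tf_genes)
    lfc[de$gene, i] <- de$log2FC
    qualify[match(de$gene[de$p_value < alpha], tf_genes)] <- TRUE
  }
  m <- lfc[qualify, , drop = FALSE]
  if (nrow(m) == 0) {
    warnf("no TF significantly DE in any sensitive bifurcation")
    return(list(matrix = m, row_hclust = NULL, col_hclust = NULL))
  }
  if (nrow(m) > top_n) {
    rv <- apply(m, 1, var, na.rm = TRUE)
    m <- m[order(rv, decreasing = TRUE)[seq_len(top_n)], , drop = FALSE]
  }
  m0 <- m; m0[is.na(m0)] <- 0
  rh <- if (nrow(m) >= 3) hclust(dist(m0), method = "average") else NULL
  ch <- if (ncol(m) >= 3) hclust(dist(t(m0)), method = "average") else NULL
  if (!is.null(rh)) m <- m[rh$order, , drop = FALSE]
  if (!is.null(ch)) m <- m[, ch$order, drop = FALSE]
  list(matrix = m, row_hclust = rh, col_hclust = ch)
}
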