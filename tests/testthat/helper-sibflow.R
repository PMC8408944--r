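# shared test fixtures, all built in code

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny sc_counts: g genes x n cells with supplied stage/treatment
toy_counts <- function(counts, stage = "64-cell", treatment = "control",
                       state = NULL, mother = NULL, is_tf = NULL) {
  dimnames(counts) <- list(
    rownames(counts) %||% sprintf("g%d", seq_len(nrow(counts))),
    colnames(counts) %||% sprintf("c%d", seq_len(ncol(counts))))
  meta <- data.frame(
    stage = rep_len(stage, ncol(counts))[seq_len(ncol(counts))],
    treatment = rep_len(treatment, ncol(counts))[seq_len(ncol(counts))],
    stringsAsFactors = FALSE)
  if (!is.null(state)) meta$state <- state
  if (!is.null(mother)) meta$mother <- mother
  gm <- data.frame(gene = rownames(counts),
                   is_tf = if (is.null(is_tf)) FALSE else is_tf,
                   stringsAsFactors = FALSE)
  sc_counts(counts, meta, gm)
}

# genes x cells log1p expression matrix wrapped as sc_expr
toy_expr <- function(m, state = NULL, treatment = "control",
                     stage = "64-cell", is_tf = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  meta <- data.frame(barcode = colnames(m),
                     stage = rep_len(stage, ncol(m)),
                     treatment = rep_len(treatment, ncol(m)),
                     stringsAsFactors = FALSE)
  if (!is.null(state)) meta$state <- state
  gm <- data.frame(gene = rownames(m),
                   is_tf = if (is.null(is_tf)) FALSE else is_tf,
                   stringsAsFactors = FALSE)
  sc_expr(m, meta, gm)
}

# short uniform-ish PWM for scanner tests (length 6)
toy_pwm <- function(consensus = "ACGTAC", weight = 10, name = "toy") {
  b <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  counts <- matrix(1, 4, length(b), dimnames = list(c("A", "C", "G", "T")))
  counts[cbind(b, seq_along(b))] <- weight
  pwm_build(counts, name = name)
}

# compare a pwm_score_distribution() against full enumeration of all
# 4^L sequences under the background model. Probes the two tail functions
# just below each cluster of score levels (clusters merged when closer
# than `gap`, which is far above the DP's rounding of <= L*eps/2), so
# both sides count exactly the same levels.
expect_dp_matches_enumeration <- function(pw, background = NULL,
                                          gap = 1e-6) {
  bg <- if (is.null(background)) pw$background else background
  len <- pw$length
  d <- pwm_score_distribution(pw, background = background)
  grid <- expand.grid(rep(list(1:4), len))
  probs <- apply(grid, 1, function(b) prod(bg[b]))
  scores <- apply(grid, 1, function(b)
    sum(pw$weights[cbind(b, seq_len(len))]))
  lv <- sort(unique(c(scores, d$score)))
  probes <- lv[c(TRUE, diff(lv) > gap)] - gap / 2
  enum_tail <- vapply(probes, function(q) sum(probs[scores >= q]),
                      numeric(1))
  dp_tail <- vapply(probes, function(q) sum(d$prob[d$score >= q]),
                    numeric(1))
  expect_equal(dp_tail, enum_tail, tolerance = 1e-9)
}

# brute-force Ajk for a pair of cells (independent oracle)
oracle_ajk_pair <- function(g, j, k, p) {
  num <- 0; n <- 0
  for (i in seq_along(p)) {
    if (is.na(g[j, i]) || is.na(g[k, i])) next
    num <- num + (g[j, i] - 2 * p[i]) * (g[k, i] - 2 * p[i]) /
      (2 * p[i] * (1 - p[i]))
    n <- n + 1
  }
  num / n
}

# brute-force greedy Ward agglomeration oracle: at each step merge the
# pair of clusters whose union minimally increases the total
# within-cluster sum of squares; returns the sequence of merged sets
oracle_ward_merges <- function(m) {
  clusters <- lapply(seq_len(nrow(m)), function(i) i)
  sse <- function(idx) {
    if (length(idx) == 1) return(0)
    sub <- m[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_cost <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      cost <- sse(c(clusters[[a]], clusters[[b]])) -
        sse(clusters[[a]]) - sse(clusters[[b]])
      if (cost < best_cost - 1e-12) {
        best_cost <- cost; best <- c(a, b)
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  merges
}

# cluster contents at each hclust merge step
hclust_merge_sets <- function(h) {
  n <- length(h$order)
  sets <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    get <- function(x) if (x < 0) -x else sets[[x]]
    sets[[i]] <- sort(c(get(h$merge[i, 1]), get(h$merge[i, 2])))
  }
  sets
}
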