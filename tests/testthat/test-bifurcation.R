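linear_edges <- function() {
  data.frame(parent_state = c("A", "A1"), child_state = c("A1", "A1a"),
             stage = c("112-cell", "mid-gastrula"), stringsAsFactors = FALSE)
}

test_that("build_lineage enumerates bifurcations and flags quadfurcations", {
  lin <- build_lineage(linear_edges(), root_stage = "64-cell")
  expect_equal(nrow(lin$bifurcations), 0)

  quad <- data.frame(parent_state = "A",
                     child_state = c("A1", "A2", "A3", "A4"),
                     stage = "112-cell", stringsAsFactors = FALSE)
  tq <- build_lineage(quad, root_stage = "64-cell")
  expect_identical(tq$quadfurcations, "A")
  expect_equal(nrow(tq$bifurcations), 0)
  expect_equal(nrow(tq$quad_pairs), choose(4, 2))

  tree <- build_lineage(default_lineage_edges(), stages = c("64-cell", "112-cell", "mid-gastrula"))
  expect_setequal(tree$bifurcations$parent,
                  c("A", "B", "A1", "A2", "B1", "B2"))
})

test_that("build_lineage rejects cycles, stage skips, double parents", {
  cyc <- data.frame(parent_state = c("A", "B"), child_state = c("B", "A"),
                    stage = c("112-cell", "mid-gastrula"))
  expect_error(build_lineage(cyc, root_stage = "64-cell"),
               "cycle|more than one parent")
  skip_edges <- data.frame(parent_state = "A", child_state = "A1",
                           stage = "mid-gastrula")
  expect_error(build_lineage(skip_edges,
                             stages = c("64-cell", "112-cell",
                                        "mid-gastrula")),
               "skips stages")
  dup <- data.frame(parent_state = c("A", "B"), child_state = c("C", "C"),
                    stage = "112-cell")
  expect_error(build_lineage(dup, root_stage = "64-cell"),
               "more than one parent")
})

test_that("yates chi-square matches the textbook formula and base R", {
  flat <- matrix(c(50, 50, 50, 50), 2)
  r <- yates_chisq(flat)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # frozen value from the continuity-corrected 2x2 formula
  r2 <- yates_chisq(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
  expect_equal(r2$statistic, 18.05)

  set.seed(1000)
  for (i in 1:1000) {
    tab <- matrix(rpois(4, sample(3:80, 1)) + 1, 2)
    ours <- yates_chisq(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = TRUE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("fgf_sensitivity propagates exclusion through eliminated subtrees", {
  tree <- build_lineage(default_lineage_edges(), stages = c("64-cell", "112-cell", "mid-gastrula"))
  # counts table: complete ablation of A2 subtree under treatment
  states <- tree$nodes$state
  counts <- matrix(100L, nrow = length(states), ncol = 2,
                   dimnames = list(states, c("control", "treated")))
  counts[c("A2", "A2a", "A2b"), "treated"] <- 0L
  fgf <- fgf_sensitivity(tree, counts)
  a <- fgf[fgf$parent == "A", ]
  expect_identical(a$status, "sensitive")
  expect_identical(a$eliminated_sibling, "A2")
  expect_identical(fgf$status[fgf$parent == "A2"], "untestable")
  # invariant: untestable set == bifurcations inside eliminated subtrees
  expect_setequal(fgf$parent[fgf$status == "untestable"], "A2")
  expect_identical(fgf$status[fgf$parent %in% c("B", "B1", "B2", "A1")],
                   rep("insensitive", 4))

  # both siblings absent from one treatment: untestable with reason
  counts2 <- counts
  counts2[c("A1a", "A1b", "A2a", "A2b"), "treated"] <- 0L
  fgf2 <- fgf_sensitivity(tree, counts2)
  row_a1 <- fgf2[fgf2$parent == "A1", ]
  expect_identical(row_a1$status, "untestable")
  expect_match(row_a1$reason, "treated")
})

test_that("classify_mechanism reproduces the category definitions", {
  expect_identical(classify_mechanism(0.5, 0), 1L)
  expect_identical(classify_mechanism(0.9, 0.4), 2L)
  expect_identical(classify_mechanism(0.5, -0.5), 3L)
  expect_identical(classify_mechanism(0, -0.5), 4L)
  expect_identical(classify_mechanism(-0.4, -0.9), 5L)
  expect_identical(classify_mechanism(0.3, -0.3), NA_integer_)
  # exact threshold is not crossed (strict inequality)
  expect_identical(classify_mechanism(0.3475, -0.3475), NA_integer_)
})

test_that("category_proportions counts up/down-in-either correctly", {
  single <- category_proportions(c(1L))
  expect_equal(unname(single$percent["1"]), 100)
  expect_equal(single$up_in_either, 100)
  expect_equal(single$down_in_either, 0)

  # category 3 contributes to both tallies
  both <- category_proportions(c(3L))
  expect_equal(both$up_in_either, 100)
  expect_equal(both$down_in_either, 100)

  mixed <- category_proportions(c(1L, 2L, 3L, 4L, 5L, NA))
  expect_equal(sum(mixed$percent), 100)
  expect_equal(mixed$up_in_either, 60)
  expect_equal(mixed$down_in_either, 60)
  expect_equal(mixed$n_unclassified, 1L)

  none <- category_proportions(c(NA_integer_, NA_integer_))
  expect_equal(none$n_classified, 0L)
  expect_true(all(is.na(none$percent)))
})

test_that("induction metric arithmetic, ties, and scale invariance", {
  de <- data.frame(log2FC = c(2, 1, -1))
  r <- induction_metric(de, "X", "Y")
  expect_equal(r$U1, 3); expect_equal(r$U2, 1)
  expect_equal(r$share1, 0.75)
  expect_identical(r$predicted, "X")

  tie <- induction_metric(data.frame(log2FC = c(1, -1)), "X", "Y")
  expect_true(tie$tie)
  expect_true(is.na(tie$predicted))

  scaled <- induction_metric(data.frame(log2FC = c(2, 1, -1) * 7), "X", "Y")
  expect_equal(scaled$share1, r$share1)
  expect_identical(scaled$predicted, r$predicted)

  expect_error(induction_metric(data.frame(log2FC = numeric())), "undefined")

  cb <- induction_metric(de, "X", "Y", count_based = TRUE)
  expect_equal(cb$U1, 2); expect_equal(cb$U2, 1)
})

test_that("sibling_distance is the centroid Euclidean norm", {
  coords <- rbind(c(0, 0), c(0, 0), c(3, 4), c(3, 4))
  labs <- c("a", "a", "b", "b")
  expect_equal(sibling_distance(coords, labs, "a", "b"), 5)
  expect_equal(sibling_distance(coords, labs, "a", "a"), 0)

  set.seed(5)
  m <- matrix(rnorm(30), ncol = 3)
  l3 <- rep(c("x", "y", "z"), length.out = 10)
  d <- sibling_distance(m, l3, "x", "z")
  oracle <- sqrt(sum((colMeans(m[l3 == "x", ]) -
                        colMeans(m[l3 == "z", ]))^2))
  expect_equal(d, oracle)
  expect_error(sibling_distance(coords, labs, "a", "q"), "absent")
})

test_that("classify_trio_tfs recovers planted categories on counts", {
  spec <- sim_spec(cells_per_state = 60, seed = 7)
  sim <- simulate_counts(spec)
  expr <- normalize_counts(sim$counts, batch = "mother")
  keep <- expr$cell_meta$treatment == "control"
  ec <- sc_expr(expr$expr[, keep], expr$cell_meta[keep, ],
                expr$gene_meta, TRUE)
  hits <- 0; total <- 0; detected <- 0; planted <- 0
  for (i in seq_len(nrow(spec$tree$bifurcations))) {
    b <- spec$tree$bifurcations[i, ]
    cl <- classify_trio_tfs(ec, b$parent, b$sib1, b$sib2)
    tr <- spec$planted_de[spec$planted_de$parent == b$parent, ]
    m <- merge(cl, tr, by.x = "gene", by.y = "tf")
    detected <- detected + sum(tr$tf %in% cl$gene)
    planted <- planted + nrow(tr)
    hits <- hits + sum(m$category.x == m$category.y, na.rm = TRUE)
    total <- total + nrow(m)
  }
  # power is high but not 1 in the NB count world
  expect_gte(detected / planted, 0.9)
  expect_gte(hits / total, 0.95)

  expect_error(classify_trio_tfs(ec, "no-such-state", "A1", "A2"),
               "parent")
})

test_that("fgf_response_matrix surfaces a globally induced TF", {
  spec <- sim_spec(cells_per_state = 60, seed = 7)
  sim <- simulate_counts(spec)
  expr <- normalize_counts(sim$counts, batch = "mother")
  fgf <- fgf_sensitivity(spec$tree, sim$counts$cell_meta)
  # keep only control cells for fold changes
  keep <- expr$cell_meta$treatment == "control"
  ec <- sc_expr(expr$expr[, keep], expr$cell_meta[keep, ],
                expr$gene_meta, TRUE)
  res <- fgf_response_matrix(ec, fgf)
  expect_true(spec$proxy_tf %in% rownames(res$matrix))
  # proxy TF is upregulated in every eliminated (induced) state
  expect_true(all(res$matrix[spec$proxy_tf, ] > 0))

  # single sensitive bifurcation and one TF: 1x1 matrix
  fgf1 <- fgf[fgf$status == "sensitive", ][1, , drop = FALSE]
  res1 <- fgf_response_matrix(ec, fgf1, tf_genes = spec$proxy_tf,
                              alpha = 0.05, top_n = 5)
  expect_equal(dim(res1$matrix), c(1L, 1L))

  # bifurcation input order only permutes rows/columns
  fgf_rev <- fgf[rev(seq_len(nrow(fgf))), ]
  res_rev <- fgf_response_matrix(ec, fgf_rev)
  expect_setequal(rownames(res_rev$matrix), rownames(res$matrix))
  expect_equal(res_rev$matrix[rownames(res$matrix), colnames(res$matrix)],
               res$matrix)
})
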