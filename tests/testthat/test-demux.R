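test_that("Ajk closed-form values on degenerate genotype patterns", {
  # all-heterozygous pair at p = 0.5: every term is zero
  g <- rbind(c1 = rep(1L, 6), c2 = rep(1L, 6))
  r <- ajk_relatedness(g, allele_freq = rep(0.5, 6), min_calls = 1)
  expect_equal(unname(r$A["c1", "c2"]), 0)

  # all homozygous-alternate at p = 0.5: each term (2-1)^2 / 0.5 = 2
  g2 <- rbind(c1 = rep(2L, 6), c2 = rep(2L, 6))
  r2 <- ajk_relatedness(g2, allele_freq = rep(0.5, 6), min_calls = 1)
  expect_equal(unname(r2$A["c1", "c2"]), 2)
})

test_that("Ajk matches the brute-force summation oracle with missingness", {
  set.seed(10)
  g <- matrix(sample(c(0:2, NA), 4 * 6, replace = TRUE,
                     prob = c(.3, .3, .3, .1)), nrow = 4,
              dimnames = list(paste0("c", 1:4), paste0("s", 1:6)))
  p <- runif(6, 0.2, 0.8)
  r <- ajk_relatedness(g, allele_freq = p, min_calls = 1,
                       maf_range = c(0, 1))
  for (j in 1:3) for (k in (j + 1):4)
    expect_equal(unname(r$A[j, k]), oracle_ajk_pair(g, j, k, p),
                 tolerance = 1e-12)
  expect_equal(r$A, t(r$A))

  # invariance to SNP order
  perm <- sample(6)
  r2 <- ajk_relatedness(g[, perm], allele_freq = p[perm], min_calls = 1,
                        maf_range = c(0, 1))
  expect_equal(r$A, r2$A)
})

test_that("Ajk is monotone in shared genotype fraction", {
  # constructed family: cell pairs sharing more genotypes never score lower
  set.seed(11)
  n_snp <- 400
  base <- sample(0:2, n_snp, replace = TRUE)
  other <- sample(0:2, n_snp, replace = TRUE)
  make_cell <- function(frac_shared) {
    k <- round(frac_shared * n_snp)
    c(base[seq_len(k)], other[-seq_len(k)])
  }
  g <- rbind(ref = base, s90 = make_cell(0.9), s50 = make_cell(0.5),
             s10 = make_cell(0.1))
  storage.mode(g) <- "integer"
  r <- ajk_relatedness(g, min_calls = 1)
  expect_gt(r$A["ref", "s90"], r$A["ref", "s50"])
  expect_gt(r$A["ref", "s50"], r$A["ref", "s10"])
})

test_that("cluster_mothers recovers block structure and handles edge cuts", {
  a <- matrix(0, 6, 6, dimnames = list(paste0("c", 1:6), paste0("c", 1:6)))
  a[1:3, 1:3] <- 2; a[4:6, 4:6] <- 2; diag(a) <- 2.5
  cl <- cluster_mothers(a, 2)
  expect_equal(length(unique(cl$labels[1:3])), 1)
  expect_equal(length(unique(cl$labels[4:6])), 1)
  expect_false(cl$labels[1] == cl$labels[4])

  cl6 <- cluster_mothers(a, 6)
  expect_equal(length(unique(cl6$labels)), 6)
  expect_error(cluster_mothers(a, 7), "exceeds")
})

test_that("end-to-end demux recovers planted mothers and degrades gracefully", {
  g <- simulate_genotypes(3, 1000, dropout_rate = 0.5, error_rate = 0.01,
                          cells_per_mother = 50, seed = 101)
  d <- demux_mothers(g$dosages, 3)
  ari <- adjusted_rand_index(d$assignments$mother, g$truth$cell_mother)
  expect_equal(ari, 1)

  # beyond the stated regime the ARI degrades but is still reported
  g2 <- simulate_genotypes(3, 120, dropout_rate = 0.95, error_rate = 0.2,
                           cells_per_mother = 20, seed = 102)
  # extreme dropout: empty pairs are expected and warned about
  d2 <- suppressWarnings(demux_mothers(g2$dosages, 3, min_calls = 2))
  ari2 <- adjusted_rand_index(d2$assignments$mother, g2$truth$cell_mother)
  expect_true(is.finite(ari2) && ari2 < 1)
})

test_that("one planted mother contributing no cells still yields clean cut", {
  # three adults, one without offspring: cut at the contributing count
  g <- simulate_genotypes(3, 800, dropout_rate = 0.4, error_rate = 0.01,
                          cells_per_mother = 30, seed = 103)
  keep <- g$truth$cell_mother != "m3"
  d <- demux_mothers(g$dosages[keep, ], 2)
  ari <- adjusted_rand_index(d$assignments$mother,
                             g$truth$cell_mother[keep])
  expect_equal(ari, 1)
})

test_that("flag_outliers drops doublet-like cells, keeps typical ones", {
  set.seed(12)
  g <- simulate_genotypes(2, 1500, dropout_rate = 0.2, error_rate = 0,
                          cells_per_mother = 50, seed = 104)
  # planted doublet: average of the two mothers' dosages
  mg <- g$truth$mother_genotypes
  doublet <- as.integer(round((mg["m1", ] + mg["m2", ]) / 2))
  gd <- rbind(g$dosages, doublet = doublet)
  rel <- ajk_relatedness(gd)
  labels <- cluster_mothers(rel, 2)$labels
  fl <- flag_outliers(rel, labels)
  expect_false(fl$keep[fl$barcode == "doublet"])
  # the literal lower-quantile rule may shave the weakest ~1% of a clean
  # cluster; essentially all genuine cells survive
  expect_gte(mean(fl$keep[fl$barcode != "doublet"]), 0.98)

  # all cells identical: nobody is dropped
  gi <- matrix(rep(c(0L, 1L, 2L, 1L), each = 6), nrow = 6)
  rownames(gi) <- paste0("c", 1:6)
  ri <- ajk_relatedness(gi, allele_freq = rep(0.5, 4), min_calls = 1)
  fi <- flag_outliers(ri, rep(1, 6))
  expect_true(all(fi$keep))

  # small cluster: flagged for review, not dropped
  f2 <- flag_outliers(ri, c(1, 1, 2, 2, 1, 1))
  expect_true(all(f2$review[f2$mother == 2]))
  expect_true(all(f2$keep))
})

test_that("attach_and_regress removes maternal variance", {
  edges <- data.frame(parent_state = "A", child_state = c("A1", "A2"),
                      stage = "112-cell", stringsAsFactors = FALSE)
  spec <- sim_spec(n_mothers = 3, cells_per_state = 40, n_genes = 100,
                   n_tfs = 20, lineage = edges,
                   stages = c("64-cell", "112-cell"),
                   maternal_offset_sd = 0.5, program_genes_per_state = 3,
                   ablated_states = character(), seed = 105)
  sim <- simulate_counts(spec)
  labels <- sim$truth$cell_mother
  ar <- attach_and_regress(sim$counts,
                           data.frame(barcode = names(labels),
                                      mother = unname(labels),
                                      keep = TRUE))
  m <- ar$expr$expr
  mo <- ar$expr$cell_meta$mother

  # per-gene mother means coincide
  mm <- rowsum(t(m), mo) / as.vector(table(mo))
  expect_lt(max(apply(mm, 2, function(x) diff(range(x)))), 1e-10)

  # ANOVA-style decomposition: mother explains < 1% of variance
  frac <- vapply(sample(nrow(m), 30), function(g) {
    fit <- stats::anova(stats::lm(m[g, ] ~ mo))
    fit$`Sum Sq`[1] / sum(fit$`Sum Sq`)
  }, numeric(1))
  expect_lt(max(frac), 0.01)

  # label renaming leaves corrected expression unchanged
  ren <- c(m1 = "x9", m2 = "x1", m3 = "x5")[labels]
  ar2 <- attach_and_regress(sim$counts,
                            data.frame(barcode = names(labels),
                                       mother = unname(ren), keep = TRUE))
  expect_equal(ar$expr$expr, ar2$expr$expr)

  # unlabeled retained cell is an error naming barcodes
  bad <- data.frame(barcode = names(labels)[-1],
                    mother = unname(labels)[-1], keep = TRUE)
  expect_error(attach_and_regress(sim$counts, bad), "without a mother")
})

test_that("pairs with no shared SNPs are flagged and imputed", {
  g <- rbind(c1 = c(0L, 2L, NA, NA), c2 = c(2L, 0L, NA, NA),
             c3 = c(NA, NA, 0L, 2L), c4 = c(NA, NA, 2L, 0L))
  colnames(g) <- paste0("s", 1:4)
  expect_warning(r <- ajk_relatedness(g, allele_freq = rep(0.5, 4),
                                      min_calls = 1),
                 "share no called SNP")
  expect_true(is.na(r$A["c1", "c3"]))
  expect_warning(cluster_mothers(r, 2), "imputed")
})
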