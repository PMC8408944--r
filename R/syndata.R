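#' Default three-stage bifurcating lineage (edge list)
#'
#' Two founder states at the first stage, each bifurcating at every
#' subsequent stage: 14 states, 6 bifurcations over
#' 64-cell / 112-cell / mid-gastrula.
#'
#' @return data.frame with `parent_state`, `child_state`, `stage`.
#' @export
default_lineage_edges <- function() {
  rbind(
    data.frame(parent_state = c("A", "A", "B", "B"),
               child_state = c("A1", "A2", "B1", "B2"),
               stage = "112-cell", stringsAsFactors = FALSE),
    data.frame(parent_state = rep(c("A1", "A2", "B1", "B2"), each = 2),
               child_state = c("A1a", "A1b", "A2a", "A2b",
                               "B1a", "B1b", "B2a", "B2b"),
               stage = "mid-gastrula", stringsAsFactors = FALSE))
}

sim_stages <- c("64-cell", "112-cell", "mid-gastrula")

# planted (daughter1, daughter2) log2 deltas vs parent for each category;
# daughter1 is the higher-expressing sibling
category_deltas <- function(category, effect) {
  switch(category,
         `1` = c(effect, 0),
         `2` = c(effect, effect / 2),
         `3` = c(effect, -effect),
         `4` = c(0, -effect),
         `5` = c(-effect / 2, -effect))
}

#' Simulation specification
#'
#' The stated world of the synthetic generator: a bifurcating lineage with
#' negative-binomial UMI counts, per-mother batch offsets, planted
#' differentially expressed TFs of known mechanism category, a known
#' induced sibling per bifurcation, and treatment-dependent lineage
#' ablations.
#'
#' @param n_mothers number of adults pooled (default 3).
#' @param cells_per_state cells per state per treatment (default 60).
#' @param lineage edge list as in [default_lineage_edges()].
#' @param stages ordered stage labels.
#' @param n_genes total genes (default 400).
#' @param n_tfs number of TF-flagged genes, the first `n_tfs` (default 80).
#' @param nb_dispersion NB size parameter theta (variance
#'   `mu + mu^2/theta`); `Inf` gives Poisson counts. Default 10.
#' @param maternal_offset_sd sd of per-gene per-mother log2 offsets
#'   (default 0.15).
#' @param depth_sd sd of per-cell log depth factors, log-normal(0, 0.3).
#' @param planted_de data.frame (`parent`, `tf`, `category`, `effect`,
#'   `daughter1`) of planted TFs; `NULL` plants the default 10 TFs per
#'   bifurcation in proportions 50/20/10/10/10 over the five categories,
#'   with daughter 1 being the induced sibling for 8 of 10.
#' @param ablated_states states (with their whole subtrees) absent from
#'   the treated condition. Defaults ablate induced siblings (`A1` and
#'   `B1a`): the signal-dependent state is the one lost under treatment.
#' @param induced_sibling named character vector (bifurcation parent ->
#'   induced child); default: the first child.
#' @param program_genes_per_state non-TF genes upregulated (by
#'   `program_effect` log2 units) in each non-root state, inherited by
#'   descendants.
#' @param program_effect log2 effect of program genes (default 1).
#' @param base_mean_log2_mean,base_mean_log2_sd distribution of per-gene
#'   baseline log2 means (default N(3.5, 1) -> median ~11 counts/cell, so
#'   the planted TFs are a small fraction of each cell's library and
#'   depth-normalization composition artifacts stay negligible, as they
#'   are in a genome-scale transcriptome).
#' @param seed integer RNG seed.
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(n_mothers = 3, cells_per_state = 60,
                     lineage = default_lineage_edges(),
                     stages = sim_stages, n_genes = 400, n_tfs = 80,
                     nb_dispersion = 10, maternal_offset_sd = 0.15,
                     depth_sd = 0.3, planted_de = NULL,
                     ablated_states = c("A1", "B1a"),
                     induced_sibling = NULL,
                     program_genes_per_state = 12, program_effect = 1,
                     base_mean_log2_mean = 3.5, base_mean_log2_sd = 1,
                     seed = 1) {
  tree <- build_lineage(lineage, stages = stages)
  genes <- sprintf("g%04d", seq_len(n_genes))
  tfs <- genes[seq_len(n_tfs)]

  if (is.null(induced_sibling)) {
    induced_sibling <- setNames(tree$bifurcations$sib1,
                                tree$bifurcations$parent)
  }
  proxy_tf <- tfs[1]
  if (is.null(planted_de)) {
    # tfs[1] plays the globally signal-coupled proxy TF (Elk-like):
    # upregulated in the induced sibling of every bifurcation
    cats <- c(1, 1, 1, 1, 1, 2, 2, 3, 4, 5)
    rows <- list(); tf_i <- 1
    for (b in seq_len(nrow(tree$bifurcations))) {
      p <- tree$bifurcations$parent[b]
      sibs <- c(tree$bifurcations$sib1[b], tree$bifurcations$sib2[b])
      ind <- induced_sibling[[p]]
      oth <- setdiff(sibs, ind)
      rows[[length(rows) + 1]] <- data.frame(
        parent = p, tf = proxy_tf, category = 2, effect = 1,
        daughter1 = ind, stringsAsFactors = FALSE)
      for (j in seq_along(cats)) {
        tf_i <- tf_i + 1
        if (tf_i > length(tfs))
          stopf("not enough TF genes for the default planting")
        rows[[length(rows) + 1]] <- data.frame(
          parent = p, tf = tfs[tf_i], category = cats[j], effect = 1,
          daughter1 = if (j <= 8) ind else oth,
          stringsAsFactors = FALSE)
      }
    }
    planted_de <- do.call(rbind, rows)
  }

  # validate planted specification
  thr <- trio_config()$up_threshold
  for (i in seq_len(nrow(planted_de))) {
    pd <- planted_de[i, ]
    if (!pd$category %in% 1:5)
      stopf("planted TF %s: category %s is not in 1..5", pd$tf, pd$category)
    if (!pd$tf %in% tfs)
      stopf("planted TF %s is not in the TF annotation list", pd$tf)
    if (!pd$parent %in% tree$bifurcations$parent)
      stopf("planted TF %s: '%s' is not a bifurcation parent",
            pd$tf, pd$parent)
    need <- if (pd$category %in% c(2, 5)) 2 * thr else thr
    if (pd$effect <= need)
      stopf(paste0("planted TF %s: effect %.3f too small for category %d ",
                   "(needs > %.3f to respect the category definition)"),
            pd$tf, pd$effect, pd$category, need)
    b <- tree$bifurcations[tree$bifurcations$parent == pd$parent, ]
    if (!pd$daughter1 %in% c(b$sib1, b$sib2))
      stopf("planted TF %s: daughter1 '%s' is not a child of '%s'",
            pd$tf, pd$daughter1, pd$parent)
  }
  bad <- setdiff(ablated_states, tree$nodes$state)
  if (length(bad))
    stopf("ablated state '%s' is not a lineage node", bad[1])

  structure(list(
    n_mothers = n_mothers, cells_per_state = cells_per_state,
    lineage = lineage, stages = stages, tree = tree, genes = genes,
    tfs = tfs, n_genes = n_genes, n_tfs = n_tfs,
    nb_dispersion = nb_dispersion,
    maternal_offset_sd = maternal_offset_sd, depth_sd = depth_sd,
    planted_de = planted_de, ablated_states = ablated_states,
    induced_sibling = induced_sibling, proxy_tf = proxy_tf,
    program_genes_per_state = program_genes_per_state,
    program_effect = program_effect,
    base_mean_log2_mean = base_mean_log2_mean,
    base_mean_log2_sd = base_mean_log2_sd, seed = seed),
    class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf(
    "sim_spec: %d genes (%d TFs), %d states, %d mothers, %d cells/state, seed %d\n",
    x$n_genes, x$n_tfs, nrow(x$tree$nodes), x$n_mothers,
    x$cells_per_state, x$seed))
  invisible(x)
}

# per-state log2 mean matrix with planted effects and state programs
state_means <- function(spec) {
  tree <- spec$tree
  base <- rnorm(spec$n_genes, spec$base_mean_log2_mean,
                spec$base_mean_log2_sd)
  # planted TFs get a solid baseline (~32 counts/cell) so count-space fold
  # changes are not compressed by the pseudocount in the log2FC formula
  planted_tfs <- unique(spec$planted_de$tf)
  base[match(planted_tfs, spec$genes)] <-
    pmax(base[match(planted_tfs, spec$genes)], 5)
  m <- matrix(rep(base, nrow(tree$nodes)), ncol = nrow(tree$nodes),
              dimnames = list(spec$genes, tree$nodes$state))

  # assign program genes (unique, non-TF) to each non-root state
  non_tf <- setdiff(spec$genes, spec$tfs)
  # every state (roots included: founder lineages are transcriptionally
  # distinct in the embryo) gets its own upregulated gene program,
  # inherited by its descendants
  prog_states <- tree$nodes$state
  need <- length(prog_states) * spec$program_genes_per_state
  if (need > length(non_tf))
    stopf("not enough non-TF genes for %d program genes per state",
          spec$program_genes_per_state)
  pool <- sample(non_tf, need)
  programs <- split(pool, rep(prog_states, each = spec$program_genes_per_state))

  # walk the tree in stage order, child inherits parent then adds effects
  ord <- order(tree$nodes$stage_idx)
  for (s in tree$nodes$state[ord]) {
    p <- if (s %in% names(tree$parent)) tree$parent[[s]] else NA_character_
    if (!is.na(p)) m[, s] <- m[, p]
    m[programs[[s]], s] <- m[programs[[s]], s] + spec$program_effect
    if (is.na(p)) next
    pd <- spec$planted_de[spec$planted_de$parent == p, , drop = FALSE]
    for (i in seq_len(nrow(pd))) {
      d <- category_deltas(as.character(pd$category[i]), pd$effect[i])
      delta <- if (s == pd$daughter1[i]) d[1] else d[2]
      m[pd$tf[i], s] <- m[pd$tf[i], s] + delta
    }
  }
  list(means_log2 = m, programs = programs)
}

#' Simulate lineage-structured UMI counts with planted truth
#'
#' Counts are negative binomial with mean
#' `state mean x 2^(mother offset) x cell depth factor` and dispersion
#' `theta` (`Inf` = Poisson). The treated condition omits all cells of the
#' ablated states and their descendant subtrees. Identical spec + seed
#' give bit-identical output.
#'
#' @param spec a [sim_spec()].
#' @return list with `counts` (an [sc_counts] with stage, treatment,
#'   state, and mother in the cell metadata) and `truth` (planted DE
#'   table, induced siblings, per-state program genes, expanded ablated
#'   set, and the per-state log2 mean matrix).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  sm <- state_means(spec)
  tree <- spec$tree
  ablated_all <- unique(unlist(lapply(spec$ablated_states, function(s)
    lineage_descendants(tree, s))))

  cell_rows <- list()
  for (trt in c("control", "treated")) {
    states <- tree$nodes$state
    if (trt == "treated") states <- setdiff(states, ablated_all)
    for (s in states) {
      cell_rows[[length(cell_rows) + 1]] <- data.frame(
        state = s,
        stage = tree$nodes$stage[match(s, tree$nodes$state)],
        treatment = trt,
        mother = paste0("m", sample.int(spec$n_mothers,
                                        spec$cells_per_state,
                                        replace = TRUE)),
        stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, cell_rows)
  n_cells <- nrow(meta)
  meta$barcode <- sprintf("cell%05d", seq_len(n_cells))

  offsets <- matrix(rnorm(spec$n_genes * spec$n_mothers, 0,
                          spec$maternal_offset_sd),
                    nrow = spec$n_genes,
                    dimnames = list(spec$genes,
                                    paste0("m", seq_len(spec$n_mothers))))
  depth <- rlnorm(n_cells, 0, spec$depth_sd)
  mu <- 2^(sm$means_log2[, meta$state, drop = FALSE] +
             offsets[, meta$mother, drop = FALSE])
  mu <- sweep(mu, 2, depth, "*")
  counts <- if (is.infinite(spec$nb_dispersion)) {
    matrix(rpois(length(mu), lambda = mu), nrow = nrow(mu))
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = spec$nb_dispersion),
           nrow = nrow(mu))
  }
  dimnames(counts) <- list(spec$genes, meta$barcode)
  gene_meta <- data.frame(gene = spec$genes,
                          is_tf = spec$genes %in% spec$tfs,
                          stringsAsFactors = FALSE)
  x <- sc_counts(counts, meta[, c("stage", "treatment", "mother", "state")],
                 gene_meta)
  truth <- list(cell_mother = setNames(meta$mother, meta$barcode),
                cell_state = setNames(meta$state, meta$barcode),
                planted_de = spec$planted_de,
                induced_sibling = spec$induced_sibling,
                state_programs = sm$programs,
                ablated_states = ablated_all,
                means_log2 = sm$means_log2)
  list(counts = x, truth = truth)
}

#' Simulate per-cell SNP genotype dosages with dropout and errors
#'
#' Per-SNP alternate-allele frequencies are Beta(2, 2); each mother draws
#' a diploid dosage per SNP; every cell inherits its mother's dosage
#' vector, after which entries are set missing at `dropout_rate` and, of
#' the remainder, flipped to one of the other two dosage values at
#' `error_rate` (symmetric dosage flip).
#'
#' @param n_mothers number of mothers (>= 2).
#' @param n_snps number of SNPs (>= 1).
#' @param dropout_rate,error_rate per-entry probabilities in \[0, 1\].
#' @param cells_per_mother cells per mother; ignored when `cell_mothers`
#'   is given.
#' @param cell_mothers optional named vector barcode -> mother label
#'   (`"m1"`, ...) to genotype an existing cell set.
#' @param seed integer RNG seed.
#' @return list with `dosages` (cells x SNPs, NA = missing) and `truth`
#'   (`cell_mother`, `mother_genotypes`, `allele_freq`).
#' @export
simulate_genotypes <- function(n_mothers, n_snps, dropout_rate = 0,
                               error_rate = 0, cells_per_mother = 50,
                               cell_mothers = NULL, seed = 1) {
  if (n_mothers < 2) stopf("n_mothers must be at least 2 (demux undefined)")
  if (n_snps < 1) stopf("n_snps must be positive (no information)")
  stopifnot(dropout_rate >= 0, dropout_rate <= 1,
            error_rate >= 0, error_rate <= 1)
  set.seed(seed)
  mothers <- paste0("m", seq_len(n_mothers))
  p <- rbeta(n_snps, 2, 2)
  geno <- vapply(mothers, function(m) rbinom(n_snps, 2, p),
                 numeric(n_snps))
  rownames(geno) <- sprintf("snp%05d", seq_len(n_snps))

  if (is.null(cell_mothers)) {
    cell_mothers <- setNames(rep(mothers, each = cells_per_mother),
                             paste0(rep(mothers, each = cells_per_mother),
                                    "_c", rep(seq_len(cells_per_mother),
                                              n_mothers)))
  }
  g <- t(geno[, cell_mothers, drop = FALSE])
  rownames(g) <- names(cell_mothers)
  n <- length(g)
  err <- matrix(runif(n) < error_rate, nrow = nrow(g))
  if (any(err)) {
    shift <- matrix(sample(1:2, n, replace = TRUE), nrow = nrow(g))
    g[err] <- (g[err] + shift[err]) %% 3
  }
  drop <- matrix(runif(n) < dropout_rate, nrow = nrow(g))
  g[drop] <- NA_integer_
  storage.mode(g) <- "integer"
  colnames(g) <- rownames(geno)
  list(dosages = g,
       truth = list(cell_mother = cell_mothers, mother_genotypes = t(geno),
                    allele_freq = p))
}

#' Simulate planted trio fold-change pairs with bounded observation noise
#'
#' Plants mechanism categories directly at the fold-change level: each TF
#' gets true (daughter1, daughter2) log2 deltas from [category_deltas()]
#' plus independent uniform noise on `[-noise, noise]`. With
#' `effect >= 0.5` and `noise <= 0.1` every planted delta stays on the
#' correct side of the 0.3475 threshold, so category recovery by
#' [classify_mechanism()] is exact. Category counts follow `proportions`
#' exactly (largest-remainder rounding).
#'
#' @param n_tfs total planted TFs.
#' @param n_trios number of trios they are spread over (round-robin).
#' @param proportions length-5 category proportions (sum to 1).
#' @param effect planted primary effect size in log2 units.
#' @param noise half-width of the uniform observation noise.
#' @param seed integer RNG seed.
#' @return data.frame: `trio`, `tf`, `category` (planted), `d1`, `d2`
#'   (noisy observed deltas), `sib_log2FC` (`d1 - d2`).
#' @export
simulate_trio_effects <- function(n_tfs = 400, n_trios = 20,
                                  proportions = c(50, 20, 10, 15, 5) / 100,
                                  effect = 1, noise = 0.1, seed = 1) {
  stopifnot(length(proportions) == 5,
            abs(sum(proportions) - 1) < 1e-8, noise >= 0)
  set.seed(seed)
  # largest-remainder apportionment: planted proportions hold exactly
  raw <- proportions * n_tfs
  n_cat <- floor(raw)
  rem <- n_tfs - sum(n_cat)
  if (rem > 0) {
    extra <- order(raw - n_cat, decreasing = TRUE)[seq_len(rem)]
    n_cat[extra] <- n_cat[extra] + 1
  }
  category <- sample(rep(1:5, n_cat))
  true_d <- t(vapply(category, function(k)
    category_deltas(as.character(k), effect), numeric(2)))
  d1 <- true_d[, 1] + runif(n_tfs, -noise, noise)
  d2 <- true_d[, 2] + runif(n_tfs, -noise, noise)
  data.frame(trio = rep_len(paste0("trio", seq_len(n_trios)), n_tfs),
             tf = sprintf("tf%04d", seq_len(n_tfs)),
             category = category, d1 = d1, d2 = d2,
             sib_log2FC = d1 - d2, stringsAsFactors = FALSE)
}

#' Built-in example motifs
#'
#' Two 8-bp count matrices: an Ets-core-like motif (consensus CCGGAAGT)
#' used for planting, and an unrelated control motif (consensus TGCATGCA).
#' Counts put 17/20 on the consensus base per position.
#'
#' @return Named list of [pwm_build()] objects.
#' @export
example_pwms <- function() {
  make_counts <- function(consensus) {
    b <- match(strsplit(consensus, "")[[1]], DNA)
    counts <- matrix(1, nrow = 4, ncol = length(b), dimnames = list(DNA))
    counts[cbind(b, seq_along(b))] <- 17
    counts
  }
  list(ets = pwm_build(make_counts("CCGGAAGT"), name = "ets"),
       ctrl = pwm_build(make_counts("TGCATGCA"), name = "ctrl"))
}

#' Simulate promoter sequences with planted consensus sites
#'
#' Background sequences are i.i.d. draws from `background`; each sequence
#' receives `Poisson(density x length / 1000)` non-overlapping insertions
#' of the PWM consensus, recorded in the truth. An error is raised when
#' the expected site count exceeds the non-overlap capacity of the
#' sequence, or when a draw cannot be placed.
#'
#' @param set_sizes named integer vector: sequences per set.
#' @param densities named numeric vector (same names): planted consensus
#'   sites per kb.
#' @param pwm a [pwm_build()] object (consensus is planted).
#' @param seq_length sequence length in bp (default 1000).
#' @param background base composition (A,C,G,T).
#' @param share_background when TRUE (requires equal set sizes), the i-th
#'   sequence of every set is built on the same background draw, and only
#'   the planted insertions differ: a matched-control design in which
#'   between-set differences reflect the planted sites alone rather than
#'   background sampling noise. Default FALSE (fully independent
#'   sequences).
#' @param seed integer RNG seed.
#' @return list with `sequences` (named character, names `set_i`) and
#'   `truth` (`set`, per-sequence planted 0-based start positions).
#' @export
simulate_promoters <- function(set_sizes, densities,
                               pwm = example_pwms()$ets,
                               seq_length = 1000,
                               background = rep(0.25, 4),
                               share_background = FALSE, seed = 1) {
  stopifnot(all(names(set_sizes) %in% names(densities)))
  if (any(densities < 0)) stopf("densities must be non-negative")
  if (abs(sum(background) - 1) > 1e-8)
    stopf("background frequencies must sum to 1")
  m <- pwm$length
  capacity <- floor(seq_length / m)
  lambda <- densities * seq_length / 1000
  over <- names(densities)[lambda > capacity]
  if (length(over))
    stopf("set '%s': expected %.1f sites exceeds capacity %d",
          over[1], lambda[over[1]], capacity)
  if (share_background && length(unique(set_sizes)) != 1)
    stopf("share_background requires equal set sizes")
  set.seed(seed)
  cons <- strsplit(pwm$consensus, "")[[1]]
  seqs <- character(); sets <- character(); planted <- list()
  one_seq <- function(bg_chars, nm) {
    s <- bg_chars
    n_sites <- rpois(1, lambda[[nm]])
    starts <- integer()
    if (n_sites > 0) {
      cand <- sample(seq_len(seq_length - m + 1))
      for (pos in cand) {
        if (length(starts) == n_sites) break
        if (!any(abs(pos - starts) < m)) starts <- c(starts, pos)
      }
      if (length(starts) < n_sites)
        stopf("could not place %d non-overlapping sites in %d bp",
              n_sites, seq_length)
      for (pos in starts) s[pos:(pos + m - 1)] <- cons
    }
    list(s = s, starts = starts)
  }
  if (share_background) {
    for (i in seq_len(set_sizes[[1]])) {
      bg_chars <- sample(DNA, seq_length, replace = TRUE, prob = background)
      for (nm in names(set_sizes)) {
        r <- one_seq(bg_chars, nm)
        id <- sprintf("%s_%03d", nm, i)
        seqs[id] <- paste(r$s, collapse = "")
        sets[id] <- nm
        planted[[id]] <- sort(r$starts) - 1L
      }
    }
  } else {
    for (nm in names(set_sizes)) {
      for (i in seq_len(set_sizes[[nm]])) {
        bg_chars <- sample(DNA, seq_length, replace = TRUE,
                           prob = background)
        r <- one_seq(bg_chars, nm)
        id <- sprintf("%s_%03d", nm, i)
        seqs[id] <- paste(r$s, collapse = "")
        sets[id] <- nm
        planted[[id]] <- sort(r$starts) - 1L  # 0-based
      }
    }
  }
  list(sequences = seqs,
       truth = list(set = sets, planted_starts = planted))
}
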