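# generate one promoter sequence with Poisson-planted consensus sites
plant_promoter <- function(len, density, pwm, background = rep(0.25, 4)) {
  m <- pwm$length
  s <- sample(DNA, len, replace = TRUE, prob = background)
  n_sites <- rpois(1, density * len / 1000)
  starts <- integer()
  if (n_sites > 0) {
    if (n_sites * m > len)
      stopf("cannot place %d non-overlapping sites in %d bp", n_sites, len)
    cand <- sample(seq_len(len - m + 1))
    for (pos in cand) {
      if (length(starts) == n_sites) break
      if (!any(abs(pos - starts) < m)) starts <- c(starts, pos)
    }
    if (length(starts) < n_sites)
      stopf("could not place %d non-overlapping sites in %d bp",
            n_sites, len)
    for (pos in starts)
      s[pos:(pos + m - 1)] <- strsplit(pwm$consensus, "")[[1]]
  }
  list(seq = paste(s, collapse = ""), starts = sort(starts) - 1L)
}

revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Write a complete synthetic fixture bundle to disk
#'
#' Simulates counts, genotypes, and a per-gene synthetic genome with
#' planted promoter motifs, and writes every file the pipeline consumes:
#' an MTX count bundle (`counts/`), `dosages.tsv`, `lineage.tsv`,
#' `genome.fa`, `models.gff3` (one gene per 3.2 kb contig, alternating
#' strands), `peaks.bed` (one 800 bp peak inside each upstream window),
#' `motifs.pfm`, and `truth.json`. Promoters of the induced siblings'
#' program genes carry the planting motif at `density_target` sites/kb;
#' all other genes at `density_control`.
#'
#' @param spec a [sim_spec()].
#' @param outdir output directory.
#' @param n_snps,dropout_rate,error_rate genotype simulation parameters.
#' @param density_target,density_control planted consensus sites per kb.
#' @param upstream_len promoter window length (bp).
#' @return Invisibly, a list with every in-memory object written
#'   (`counts`, `truth`, `dosages`, `genome`, `gene_models`, `peaks`,
#'   `pfms`, `motif_truth`).
#' @export
write_fixture_bundle <- function(spec, outdir, n_snps = 1000,
                                 dropout_rate = 0.5, error_rate = 0.01,
                                 density_target = 5, density_control = 0.5,
                                 upstream_len = 1500) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_counts(spec)
  geno <- simulate_genotypes(spec$n_mothers, n_snps,
                             dropout_rate = dropout_rate,
                             error_rate = error_rate,
                             cell_mothers = sim$truth$cell_mother,
                             seed = derive_seed(spec$seed, 1))

  induced <- unname(spec$induced_sibling)
  target_genes <- unique(unlist(sim$truth$state_programs[induced]))
  pwms <- example_pwms()
  plant_pwm <- pwms$ets

  set.seed(derive_seed(spec$seed, 2))
  contig_len <- 3200L
  genome <- character(length(spec$genes))
  gm <- data.frame(gene = spec$genes,
                   seqnames = paste0("contig_", spec$genes),
                   start = NA_integer_, end = NA_integer_,
                   strand = rep_len(c("+", "-"), length(spec$genes)),
                   stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = gm$seqnames, start = NA_integer_,
                      end = NA_integer_,
                      name = paste0("peak_", spec$genes),
                      stringsAsFactors = FALSE)
  planted_sites <- list()
  for (i in seq_along(spec$genes)) {
    g <- spec$genes[i]
    dens <- if (g %in% target_genes) density_target else density_control
    pr <- plant_promoter(upstream_len, dens, plant_pwm)
    bg <- sample(DNA, contig_len, replace = TRUE)
    if (gm$strand[i] == "+") {
      gm$start[i] <- 200L + upstream_len + 1L   # body after upstream
      gm$end[i] <- gm$start[i] + 999L
      up_lo <- 201L
      substr_vec <- strsplit(pr$seq, "")[[1]]
      bg[up_lo:(up_lo + upstream_len - 1L)] <- substr_vec
      peaks$start[i] <- 500L; peaks$end[i] <- 1300L   # 0-based half-open
    } else {
      gm$start[i] <- 501L; gm$end[i] <- 1500L
      up_lo <- 1501L
      substr_vec <- strsplit(revcomp_chr(pr$seq), "")[[1]]
      bg[up_lo:(up_lo + upstream_len - 1L)] <- substr_vec
      peaks$start[i] <- 1900L; peaks$end[i] <- 2700L
    }
    genome[i] <- paste(bg, collapse = "")
    planted_sites[[g]] <- pr$starts
  }
  genome <- Biostrings::DNAStringSet(setNames(genome, gm$seqnames))

  # emit everything
  write_counts_mtx(sim$counts, file.path(outdir, "counts"))
  write_dosage_tsv(geno$dosages, file.path(outdir, "dosages.tsv"))
  write_lineage_tsv(spec$lineage, file.path(outdir, "lineage.tsv"))
  Biostrings::writeXStringSet(genome, file.path(outdir, "genome.fa"))
  gff <- c("##gff-version 3",
           sprintf("%s\tsibflow\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   gm$seqnames, gm$start, gm$end, gm$strand, gm$gene))
  writeLines(gff, file.path(outdir, "models.gff3"))
  write.table(peaks, file.path(outdir, "peaks.bed"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_jaspar_pfm(example_pwm_counts(), file.path(outdir, "motifs.pfm"))
  motif_truth <- list(target_genes = target_genes,
                      density_target = density_target,
                      density_control = density_control,
                      planted_sites = planted_sites)
  truth <- c(sim$truth[c("planted_de", "induced_sibling", "state_programs",
                         "ablated_states")],
             list(cell_mother = as.list(sim$truth$cell_mother),
                  motif = motif_truth[c("target_genes", "density_target",
                                        "density_control")]))
  write_truth_json(truth, file.path(outdir, "truth.json"))

  invisible(list(counts = sim$counts, truth = sim$truth,
                 dosages = geno$dosages, genotype_truth = geno$truth,
                 genome = genome, gene_models = gm, peaks = peaks,
                 pfms = pwms, motif_truth = motif_truth))
}

#' Raw count matrices of the built-in example motifs
#'
#' @return Named list of 4 x 8 count matrices.
#' @export
example_pwm_counts <- function() {
  make_counts <- function(consensus) {
    b <- match(strsplit(consensus, "")[[1]], DNA)
    counts <- matrix(1, nrow = 4, ncol = length(b), dimnames = list(DNA))
    counts[cbind(b, seq_along(b))] <- 17
    counts
  }
  list(ets = make_counts("CCGGAAGT"), ctrl = make_counts("TGCATGCA"))
}

subset_expr <- function(expr, keep) {
  sc_expr(expr$expr[, keep, drop = FALSE],
          expr$cell_meta[keep, , drop = FALSE], expr$gene_meta,
          expr$batch_corrected)
}

#' Run the full analysis pipeline on a fixture bundle
#'
#' Reads the files written by [write_fixture_bundle()] and executes
#' demultiplex -> normalize -> bifurcation analytics -> motif enrichment
#' -> waves end to end. Cluster (state) labels are taken from the
#' supplied metadata, as in studies where states are assigned upstream.
#'
#' @param dir fixture bundle directory.
#' @param k_mothers number of adults for demultiplexing.
#' @param root_stage stage of the lineage roots.
#' @param k_waves number of temporal waves to cut.
#' @param focal_root root state of the focal (wave-analysed) lineage; the
#'   induced child is followed at each stage.
#' @param proxy_tf gene id of the signal-coupled proxy TF for the
#'   signature matrix; default: first TF gene.
#' @param alpha,min_lfc DE cutoffs for target/control gene sets.
#' @return list with components `counts`, `expr`, `demux`, `tree`, `fgf`,
#'   `trios`, `category_summary`, `induction`, `tfbs`, `signature`,
#'   `waves`, `transfer`.
#' @export
run_pipeline <- function(dir, k_mothers, root_stage = "64-cell",
                         k_waves = 3, focal_root = "A", proxy_tf = NULL,
                         alpha = 0.05, min_lfc = 0.3) {
  counts <- read_counts_mtx(file.path(dir, "counts"))
  dosages <- read_dosage_tsv(file.path(dir, "dosages.tsv"))
  edges <- read_lineage_tsv(file.path(dir, "lineage.tsv"))
  tree <- build_lineage(edges, root_stage = root_stage)

  dmx <- demux_mothers(dosages, k_mothers)
  ar <- attach_and_regress(counts, dmx$assignments)
  counts <- ar$counts; expr <- ar$expr
  if (is.null(proxy_tf)) proxy_tf <- expr$gene_meta$gene[expr$gene_meta$is_tf][1]

  fgf <- fgf_sensitivity(tree, counts$cell_meta, alpha = alpha)

  ctrl <- expr$cell_meta$treatment == "control"
  expr_c <- subset_expr(expr, ctrl)
  states_c <- expr_c$cell_meta$state
  stage_c <- expr_c$cell_meta$stage

  # trios + induction per bifurcation (control cells)
  trios <- list(); induction <- list()
  for (i in seq_len(nrow(tree$bifurcations))) {
    b <- tree$bifurcations[i, ]
    cl <- classify_trio_tfs(expr_c, b$parent, b$sib1, b$sib2)
    trios[[b$parent]] <- cl
    if (nrow(cl)) {
      im <- induction_metric(data.frame(log2FC = cl$sib_log2FC),
                             sib1 = b$sib1, sib2 = b$sib2)
      induction[[b$parent]] <- data.frame(
        parent = b$parent, sib1 = b$sib1, sib2 = b$sib2,
        U1 = im$U1, U2 = im$U2, share1 = im$share1,
        predicted = im$predicted %||% NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  category_summary <- category_proportions(do.call(rbind, trios))
  induction <- do.call(rbind, induction)

  # motif stack
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  gff <- rtracklayer::import(file.path(dir, "models.gff3"))
  peaks <- rtracklayer::import(file.path(dir, "peaks.bed"))
  regions <- extract_regions(gff, genome, peaks)
  pfms <- read_jaspar_pfm(file.path(dir, "motifs.pfm"))
  pwms <- lapply(names(pfms), function(n) pwm_build(pfms[[n]], name = n))
  names(pwms) <- names(pfms)

  de_vs_others <- function(state) {
    a <- which(states_c == state)
    b2 <- which(states_c != state &
                  stage_c == stage_c[a[1]])
    wilcoxon_de(expr_c, a, b2)
  }
  tfbs <- list(); sig_rows <- list()
  for (i in seq_len(nrow(tree$bifurcations))) {
    b <- tree$bifurcations[i, ]
    de_sibs <- wilcoxon_de(expr_c, which(states_c == b$sib1),
                           which(states_c == b$sib2))
    up1 <- de_sibs$gene[de_sibs$p_value < alpha & de_sibs$log2FC >= min_lfc]
    up2 <- de_sibs$gene[de_sibs$p_value < alpha & de_sibs$log2FC <= -min_lfc]
    e1 <- de_vs_others(b$sib1); e2 <- de_vs_others(b$sib2)
    pick <- function(de, sign) de$gene[de$p_value < alpha &
                                         sign * de$log2FC >= min_lfc]
    tz <- bifurcation_tfbs(regions, pwms$ets, up1, up2,
                           pick(e1, 1), pick(e1, -1),
                           pick(e2, 1), pick(e2, -1))
    tfbs[[b$parent]] <- tz
    sig_rows[[b$parent]] <- data.frame(
      bifurcation = b$parent,
      z_by_sibs = tz$by_sibs$z,
      z_enr_sib1 = tz$enriched_sib1$z,
      z_enr_sib2 = tz$enriched_sib2$z,
      proxy_lfc = de_sibs$log2FC[match(proxy_tf, de_sibs$gene)],
      fgf_score = fgf$score[fgf$parent == b$parent],
      stringsAsFactors = FALSE)
  }
  signature <- ets_signature(do.call(rbind, sig_rows))

  # temporal waves along the focal (induced) lineage
  chain <- focal_root
  repeat {
    s <- chain[length(chain)]
    kids <- tree$children[[s]]
    if (is.null(kids)) break
    ind <- tree$bifurcations$sib1[tree$bifurcations$parent == s]
    chain <- c(chain, if (length(ind)) ind[1] else kids[1])
  }
  de_by_stage <- lapply(chain, de_vs_others)
  names(de_by_stage) <- chain
  union_genes <- enriched_union(de_by_stage, alpha = alpha,
                                min_lfc = min_lfc)
  pb <- pseudobulk(expr_c, states_c)
  profiles <- t(pb[chain, union_genes, drop = FALSE])
  colnames(profiles) <- tree$nodes$stage[match(chain, tree$nodes$state)]
  waves <- if (length(union_genes) >= max(2, k_waves))
    wave_cluster(profiles, k = k_waves) else NULL

  # label transfer onto treated cells, per stage (reference and query
  # states are only comparable within a stage)
  treated <- !ctrl
  transfer <- if (any(treated)) {
    parts <- lapply(unique(expr$cell_meta$stage), function(sg) {
      r <- ctrl & expr$cell_meta$stage == sg
      q <- treated & expr$cell_meta$stage == sg
      if (!any(q)) return(NULL)
      transfer_labels(subset_expr(expr, r), expr$cell_meta$state[r],
                      subset_expr(expr, q))
    })
    do.call(rbind, parts)
  } else NULL

  list(counts = counts, expr = expr, demux = dmx, tree = tree, fgf = fgf,
       trios = trios, category_summary = category_summary,
       induction = induction, tfbs = tfbs, signature = signature,
       waves = waves, wave_genes = union_genes, wave_chain = chain,
       transfer = transfer)
}
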