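# coerce gene models to GRanges with a gene_id column (input 1-based)
as_gene_granges <- function(gene_models) {
  if (is(gene_models, "GRanges")) {
    gr <- gene_models
    if (is.null(gr$gene_id)) {
      id <- gr$ID %||% gr$Name %||% names(gr)
      if (is.null(id)) stopf("gene models need a gene_id")
      gr$gene_id <- id
    }
    return(gr)
  }
  df <- as.data.frame(gene_models)
  chr_col <- intersect(c("seqnames", "seqname", "chrom"), names(df))[1]
  GenomicRanges::GRanges(
    seqnames = df[[chr_col]],
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand %||% "+",
    gene_id = df$gene %||% df$gene_id)
}

# coerce peaks (GRanges, or BED-style 0-based half-open data.frame) to
# GRanges with a name column
as_peak_granges <- function(peaks) {
  if (is(peaks, "GRanges")) {
    gr <- peaks
    if (is.null(gr$name))
      gr$name <- names(gr) %||% paste0("peak", seq_along(gr))
    return(gr)
  }
  df <- as.data.frame(peaks)
  chr_col <- intersect(c("chrom", "seqnames", "seqname"), names(df))[1]
  GenomicRanges::GRanges(
    seqnames = df[[chr_col]],
    ranges = IRanges::IRanges(df$start + 1L, df$end),
    name = df$name %||% paste0("peak", seq_len(nrow(df))))
}

granges_seq <- function(genome, gr, revcomp_minus = FALSE) {
  out <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
    chr <- as.character(GenomicRanges::seqnames(gr)[i])
    s <- Biostrings::subseq(genome[[chr]], GenomicRanges::start(gr)[i],
                            GenomicRanges::end(gr)[i])
    if (revcomp_minus &&
        as.character(GenomicRanges::strand(gr)[i]) == "-")
      s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1)))
  out
}

#' Extract upstream promoter regions and overlapping open-chromatin peaks
#'
#' For each gene, the `upstream` bp immediately 5' of the transcription
#' start site are extracted strand-aware (reverse-complemented for minus
#' strand genes) and clamped at contig edges. When peaks are supplied, any
#' peak overlapping a gene's upstream window is kept in full and labeled
#' by that gene -- the open-chromatin representation of the same
#' regulatory space.
#'
#' @param gene_models GRanges (or 1-based data.frame with `gene`,
#'   `seqnames`/`chrom`, `start`, `end`, `strand`) of gene bodies.
#' @param genome named [Biostrings::DNAStringSet] of contigs, or a FASTA
#'   path.
#' @param peaks optional peaks as GRanges or BED-style 0-based data.frame.
#' @param upstream window length in bp (default 1500).
#' @return list with `upstream` (DNAStringSet named by gene),
#'   `upstream_ranges` (GRanges, 1-based), `atac` (DNAStringSet named
#'   `gene|peak`), `atac_ranges`, `skipped` (genes not resolvable),
#'   `clamped` (data.frame of genes whose window hit a contig edge).
#' @export
extract_regions <- function(gene_models, genome, peaks = NULL,
                            upstream = 1500) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genes <- as_gene_granges(gene_models)
  seqlen <- setNames(Biostrings::width(genome), names(genome))

  skipped <- character()
  ok <- as.character(GenomicRanges::seqnames(genes)) %in% names(genome)
  if (any(!ok)) {
    skipped <- genes$gene_id[!ok]
    genes <- genes[ok]
  }
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  tss <- ifelse(minus, GenomicRanges::end(genes),
                GenomicRanges::start(genes))
  up_start <- ifelse(minus, tss + 1L, tss - upstream)
  up_end <- ifelse(minus, tss + upstream, tss - 1L)
  lim <- seqlen[as.character(GenomicRanges::seqnames(genes))]
  clamp_lo <- pmax(up_start, 1L)
  clamp_hi <- pmin(up_end, lim)
  clamped_flag <- clamp_lo != up_start | clamp_hi != up_end
  empty <- clamp_hi < clamp_lo
  if (any(empty)) skipped <- c(skipped, genes$gene_id[empty])

  keep <- !empty
  upr <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(genes)[keep],
    ranges = IRanges::IRanges(clamp_lo[keep], clamp_hi[keep]),
    strand = GenomicRanges::strand(genes)[keep],
    gene_id = genes$gene_id[keep])
  up_seq <- granges_seq(genome, upr, revcomp_minus = TRUE)
  names(up_seq) <- upr$gene_id
  clamped <- data.frame(gene = genes$gene_id[keep & clamped_flag],
                        length = (clamp_hi - clamp_lo + 1L)[keep &
                                                              clamped_flag],
                        stringsAsFactors = FALSE)

  atac_seq <- Biostrings::DNAStringSet()
  atac_ranges <- GenomicRanges::GRanges()
  if (!is.null(peaks)) {
    pk <- as_peak_granges(peaks)
    hits <- GenomicRanges::findOverlaps(pk, upr, ignore.strand = TRUE)
    if (length(hits)) {
      pk_hit <- pk[S4Vectors::queryHits(hits)]
      pk_hit$gene_id <- upr$gene_id[S4Vectors::subjectHits(hits)]
      atac_seq <- granges_seq(genome, pk_hit)
      names(atac_seq) <- paste0(pk_hit$gene_id, "|", pk_hit$name)
      atac_ranges <- pk_hit
    }
  }
  list(upstream = up_seq, upstream_ranges = upr,
       atac = atac_seq, atac_ranges = atac_ranges,
       skipped = skipped, clamped = clamped)
}

# pull the sequences of a gene set from an extract_regions() result
region_seqs <- function(regions, genes) {
  up <- regions$upstream[names(regions$upstream) %in% genes]
  at <- regions$atac[sub("\\|.*$", "", names(regions$atac)) %in% genes]
  list(upstream = up, atac = at)
}

#' Dual-representation motif enrichment for two gene sets
#'
#' Computes the over-representation z-score of a motif in the target
#' genes' regions versus the control genes' regions, separately on the
#' upstream-window representation and the open-chromatin representation,
#' then averages via [combined_zscore()].
#'
#' @param regions an [extract_regions()] result.
#' @param pwm a [pwm_build()] object.
#' @param target_genes,control_genes gene id vectors.
#' @inheritParams enrichment_zscore
#' @return list with `z` (combined), `z_upstream`, `z_atac` (enrichment
#'   objects or NULL when a representation is unavailable),
#'   `single_source`, `undefined`.
#' @export
tfbs_enrichment <- function(regions, pwm, target_genes, control_genes,
                            min_rel = 0.85, p_value = NULL,
                            continuity = FALSE) {
  one <- function(getter) {
    tg <- getter(region_seqs(regions, target_genes))
    cg <- getter(region_seqs(regions, control_genes))
    if (length(tg) == 0 || length(cg) == 0) return(NULL)
    enrichment_zscore(tg, cg, pwm, min_rel = min_rel, p_value = p_value,
                      continuity = continuity)
  }
  e_up <- one(function(x) x$upstream)
  e_at <- one(function(x) x$atac)
  comb <- combined_zscore(if (is.null(e_up)) NA_real_ else e_up$z,
                          if (is.null(e_at)) NA_real_ else e_at$z)
  list(z = comb$z, z_upstream = e_up, z_atac = e_at,
       single_source = comb$single_source, undefined = comb$undefined)
}

#' Per-bifurcation TF-binding-site enrichment triplet
#'
#' Three combined z-scores for one bifurcation: "by sibs" (genes up in
#' sibling 1 vs genes up in sibling 2) and "by enriched" for each sibling
#' (genes up vs genes down in that sibling's comparison against all other
#' states). Empty gene sets flag the corresponding z as unavailable (NA).
#'
#' @param regions an [extract_regions()] result.
#' @param pwm a [pwm_build()] object.
#' @param up_sib1,up_sib2 genes upregulated in each sibling
#'   (sibling-vs-sibling comparison, log2FC cutoff 0.3 upstream of this
#'   call).
#' @param enr_sib1_up,enr_sib1_down,enr_sib2_up,enr_sib2_down genes
#'   up/down in each sibling versus all other states.
#' @inheritParams tfbs_enrichment
#' @return list with `by_sibs`, `enriched_sib1`, `enriched_sib2`, each a
#'   [tfbs_enrichment()] result (or `z = NA` when a set was empty).
#' @export
bifurcation_tfbs <- function(regions, pwm, up_sib1, up_sib2,
                             enr_sib1_up = NULL, enr_sib1_down = NULL,
                             enr_sib2_up = NULL, enr_sib2_down = NULL,
                             min_rel = 0.85, p_value = NULL) {
  run <- function(tg, cg) {
    if (is.null(tg) || is.null(cg) || !length(tg) || !length(cg))
      return(list(z = NA_real_, z_upstream = NULL, z_atac = NULL,
                  single_source = FALSE, undefined = TRUE))
    tfbs_enrichment(regions, pwm, tg, cg, min_rel = min_rel,
                    p_value = p_value)
  }
  list(by_sibs = run(up_sib1, up_sib2),
       enriched_sib1 = run(enr_sib1_up, enr_sib1_down),
       enriched_sib2 = run(enr_sib2_up, enr_sib2_down))
}

#' Four-variable direct-vs-relay signature matrix with cluster order
#'
#' Assembles, per bifurcation, the by-sibs motif z, the two per-sibling
#' enriched-vs-depleted motif z's, and the proxy-TF (e.g. Elk-family)
#' log2 fold-change between siblings, and orders the rows by
#' average-linkage hierarchical clustering on Euclidean distance.
#' Bifurcations directly driven by the signal separate (high z, high proxy
#' fold-change) from relay/indirect ones. An optional ablation
#' (`fgf_score`) column is appended for display but excluded from
#' clustering; rows with missing variables are retained in the output but
#' excluded from clustering and listed.
#'
#' @param sig data.frame with columns `bifurcation`, `z_by_sibs`,
#'   `z_enr_sib1`, `z_enr_sib2`, `proxy_lfc`, and optionally `fgf_score`.
#' @return list with `matrix` (rows in cluster order, excluded rows last),
#'   `hclust`, `excluded` (bifurcation ids).
#' @export
ets_signature <- function(sig) {
  vars <- c("z_by_sibs", "z_enr_sib1", "z_enr_sib2", "proxy_lfc")
  stopifnot(all(c("bifurcation", vars) %in% names(sig)))
  m <- as.matrix(sig[, vars])
  rownames(m) <- sig$bifurcation
  complete <- stats::complete.cases(m)
  h <- NULL
  ord <- which(complete)
  if (sum(complete) >= 3) {
    h <- hclust(dist(m[complete, , drop = FALSE]), method = "average")
    ord <- which(complete)[h$order]
  }
  ord <- c(ord, which(!complete))
  out <- m[ord, , drop = FALSE]
  if (!is.null(sig$fgf_score))
    out <- cbind(out, fgf_score = sig$fgf_score[ord])
  list(matrix = out, hclust = h,
       excluded = sig$bifurcation[!complete])
}

#' Associate peaks with their nearest gene and tally per-gene open
#' chromatin and motif sites
#'
#' Each peak is assigned to the gene model at minimal genomic distance
#' (overlap counts as distance 0); equidistant candidates break ties
#' towards the lexicographically smaller gene id. Per gene, the total
#' assigned peak length and the number of (de-duplicated) motif hits in
#' those peaks are reported -- the genome-wide view in which genes under
#' unusually extensive, site-dense open chromatin stand out.
#'
#' @param peaks GRanges (or BED-style 0-based data.frame) with peak names
#'   matching the `seq` column of `hits`.
#' @param gene_models GRanges or 1-based data.frame of gene bodies.
#' @param hits motif hit data.frame (after [dedup_hits()]) whose `seq`
#'   values are peak names; may be NULL to tally lengths only.
#' @return data.frame: `gene`, `open_chromatin_bp`, `n_peaks`, `n_sites`.
#' @export
peak_gene_tally <- function(peaks, gene_models, hits = NULL) {
  pk <- as_peak_granges(peaks)
  genes <- as_gene_granges(gene_models)
  # explicit per-peak distances so exact ties are visible
  # (distanceToNearest(select = "all") does not reliably report them)
  assigned <- vapply(seq_along(pk), function(i) {
    same <- as.character(GenomicRanges::seqnames(genes)) ==
      as.character(GenomicRanges::seqnames(pk)[i])
    if (!any(same)) return(NA_character_)
    d <- GenomicRanges::distance(pk[i], genes[same],
                                 ignore.strand = TRUE)
    cand <- sort(genes$gene_id[same][d == min(d)])
    if (length(cand) > 1)
      message(sprintf("peak %s equidistant from %d genes; assigned to %s",
                      pk$name[i], length(cand), cand[1]))
    cand[1]
  }, character(1))

  site_count <- if (is.null(hits)) setNames(integer(0), character(0))
                else table(hits$seq)
  df <- data.frame(gene = assigned,
                   len = GenomicRanges::width(pk),
                   sites = as.integer(site_count[pk$name]),
                   stringsAsFactors = FALSE)
  df$sites[is.na(df$sites)] <- 0L
  df <- df[!is.na(df$gene), , drop = FALSE]
  agg <- aggregate(cbind(open_chromatin_bp = len, n_sites = sites,
                         n_peaks = rep(1L, nrow(df))) ~ gene, data = df,
                   FUN = sum)
  agg[order(agg$gene), , drop = FALSE]
}
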