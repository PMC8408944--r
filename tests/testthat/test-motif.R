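BASES <- c("A", "C", "G", "T")

# independent exhaustive window-scoring oracle (forward + reverse)
oracle_scan <- function(seq, pwm, thr) {
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]),
                                      collapse = ""))
  m <- pwm$length
  codes <- function(s) match(strsplit(s, "")[[1]], BASES)
  out <- list()
  for (i in seq_len(nchar(seq) - m + 1)) {
    win <- substr(seq, i, i + m - 1)
    for (strand in c("+", "-")) {
      w <- if (strand == "+") win else revcomp(win)
      cs <- codes(w)
      if (anyNA(cs)) next
      sc <- sum(pwm$weights[cbind(cs, seq_len(m))])
      if (sc >= thr - 1e-12)
        out[[length(out) + 1]] <- data.frame(start = i - 1L,
                                             strand = strand, score = sc)
    }
  }
  do.call(rbind, out)
}

test_that("JASPAR parsing and round trip", {
  path <- system.file("extdata", "example_motifs.pfm", package = "sibflow")
  pfms <- read_jaspar_pfm(path)
  expect_length(pfms, 2)
  expect_equal(dim(pfms[[1]]), c(4L, 8L))
  expect_equal(unname(colSums(pfms[[1]])), rep(20, 8))

  tmp <- tempfile(fileext = ".pfm")
  write_jaspar_pfm(pfms, tmp)
  again <- read_jaspar_pfm(tmp)
  expect_equal(pfms, again)
})

test_that("pwm_build gives consensus relative score exactly 1", {
  pw <- toy_pwm("ACGTAC")
  expect_identical(pw$consensus, "ACGTAC")
  expect_true(all(is.finite(pw$weights)))
  h <- scan_pwm(c(s = pw$consensus), pw, min_rel = 0.999)
  expect_equal(nrow(h), 1)
  expect_equal(h$rel_score, 1)
  expect_identical(h$strand, "+")
})

test_that("exact p-value DP equals exhaustive enumeration (<= 6 bp)", {
  backgrounds <- list(uniform = rep(0.25, 4),
                      skewed = c(0.4, 0.1, 0.1, 0.4))
  set.seed(77)
  for (len in c(2, 4, 6)) {
    counts <- matrix(rpois(4 * len, 5) + 1, nrow = 4,
                     dimnames = list(BASES))
    for (bg in backgrounds)
      expect_dp_matches_enumeration(pwm_build(counts, background = bg),
                                    background = bg)
  }
})

test_that("p-value thresholds are monotone; degenerate PWM behaves", {
  pw <- toy_pwm("ACGTAC")
  ps <- c(1, 0.5, 0.1, 0.01, 0.001)
  thr <- vapply(ps, function(p) pwm_score_threshold(pw, p), numeric(1))
  expect_true(all(diff(thr) >= 0))

  # all-equal columns: a single attainable score
  flat <- pwm_build(matrix(5, 4, 2, dimnames = list(BASES)))
  expect_equal(pwm_score_threshold(flat, 1), flat$max_score)
  expect_identical(pwm_score_threshold(flat, 0.5), Inf)
  h <- scan_pwm(c(s = "ACGT"), flat, p_value = 1)
  expect_equal(nrow(h), 6)  # every window, both strands
  expect_equal(nrow(scan_pwm(c(s = "ACGT"), flat, p_value = 0.5)), 0)
})

test_that("scanner equals the exhaustive oracle and respects strands", {
  set.seed(21)
  pw <- toy_pwm("GGAATG")
  thr <- pw$min_score + 0.8 * (pw$max_score - pw$min_score)
  for (i in 1:5) {
    s <- paste(sample(BASES, 60, replace = TRUE), collapse = "")
    s <- paste0(substr(s, 1, 20), "GGAATG", substr(s, 27, 54), "CATTCC")
    ours <- scan_pwm(c(x = s), pw, min_rel = 0.8)
    oracle <- oracle_scan(s, pw, thr)
    expect_equal(nrow(ours), nrow(oracle))
    expect_equal(ours$start, oracle$start[order(oracle$start,
                                                oracle$strand)])
    expect_equal(sort(ours$score), sort(oracle$score), tolerance = 1e-9)
  }

  # reverse complement of consensus: one reverse-strand hit, same score
  rc <- "CATTCC"
  h <- scan_pwm(c(x = rc), pw, min_rel = 0.999)
  expect_equal(nrow(h), 1)
  expect_identical(h$strand, "-")
  expect_equal(h$rel_score, 1)

  # N-containing windows are skipped; short sequences yield no hits
  expect_equal(nrow(scan_pwm(c(x = "GGANTG"), pw, min_rel = 0)), 0)
  expect_equal(nrow(scan_pwm(c(x = "GGA"), pw)), 0)
})

test_that("strand invariance: reverse-complementing sequences preserves hits", {
  set.seed(22)
  pw <- toy_pwm("GGAATG")
  seqs <- vapply(1:10, function(i)
    paste(sample(BASES, 300, replace = TRUE), collapse = ""), "")
  names(seqs) <- paste0("s", 1:10)
  rc <- vapply(seqs, function(s)
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                 collapse = "")), "")
  h1 <- scan_pwm(seqs, pw, min_rel = 0.8)
  h2 <- scan_pwm(rc, pw, min_rel = 0.8)
  expect_equal(nrow(h1), nrow(h2))
  expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-9)
})

test_that("dedup keeps the best hit within the center window, idempotently", {
  hits <- data.frame(seq = "x", start = c(10L, 11L), strand = "+",
                     score = c(5, 7), rel_score = c(.5, .7),
                     center = c(12.5, 13.5), pwm = c("a", "b"),
                     stringsAsFactors = FALSE)
  d <- dedup_hits(hits, window = 3)
  expect_equal(nrow(d), 1)
  expect_equal(d$score, 7)

  far <- hits; far$center <- c(10, 15.5); far$start <- c(8L, 13L)
  expect_equal(nrow(dedup_hits(far, window = 3)), 2)

  set.seed(23)
  pw <- toy_pwm("GGAATG")
  s <- paste(sample(BASES, 500, replace = TRUE), collapse = "")
  h <- scan_pwm(c(x = s), pw, min_rel = 0.6)
  once <- dedup_hits(h)
  expect_identical(dedup_hits(once), once)
})

test_that("opossum z-score evaluates the binomial formula exactly", {
  e <- opossum_zscore(20, 10000, 50, 100000)
  expect_equal(e$rate, 5e-4)
  expect_equal(e$mu, 5)
  expect_equal(e$sigma, sqrt(10000 * 5e-4 * 0.9995))
  expect_equal(e$z, (20 - 5) / sqrt(10000 * 5e-4 * 0.9995))

  ec <- opossum_zscore(20, 10000, 50, 100000, continuity = TRUE)
  expect_equal(ec$z, (20 - 5 - 0.5) / sqrt(10000 * 5e-4 * 0.9995))

  flagged <- opossum_zscore(5, 100, 0, 1000)
  expect_true(flagged$flagged)
  expect_true(is.na(flagged$z))
})

test_that("identical target and control sets give z = 0", {
  set.seed(24)
  pw <- toy_pwm("GGAATG")
  seqs <- vapply(1:20, function(i)
    paste(sample(BASES, 200, replace = TRUE), collapse = ""), "")
  names(seqs) <- paste0("s", 1:20)
  e <- enrichment_zscore(seqs, seqs, pw, min_rel = 0.75)
  expect_true(e$z == 0 || e$flagged)  # t == mu exactly
})

test_that("combined z-score averages finite inputs and flags singles", {
  expect_equal(combined_zscore(2, 4)$z, 3)
  expect_equal(combined_zscore(4, 2)$z, 3)
  one <- combined_zscore(2.5, NA)
  expect_equal(one$z, 2.5)
  expect_true(one$single_source)
  none <- combined_zscore(NA, NA)
  expect_true(none$undefined)
})

test_that("extract_regions follows the coordinate conventions", {
  # contig of 3000 bp; trackable sequence
  set.seed(25)
  contig <- paste(sample(BASES, 3000, replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = contig))

  # minus-strand gene ending at 1-based 1000: upstream = [1001, 2500],
  # i.e. 0-based [1000, 2500), reverse-complemented
  gm <- data.frame(gene = "gM", seqnames = "chr1", start = 500, end = 1000,
                   strand = "-", stringsAsFactors = FALSE)
  r <- extract_regions(gm, genome)
  expect_equal(GenomicRanges::start(r$upstream_ranges), 1001)
  expect_equal(GenomicRanges::end(r$upstream_ranges), 2500)
  expected <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(contig, 1001, 2500))))
  expect_identical(as.character(r$upstream[["gM"]]), expected)

  # plus-strand gene with TSS close to the contig start: clamped + logged
  gm2 <- data.frame(gene = "gP", seqnames = "chr1", start = 301, end = 800,
                    strand = "+", stringsAsFactors = FALSE)
  r2 <- extract_regions(gm2, genome)
  expect_equal(GenomicRanges::start(r2$upstream_ranges), 1)
  expect_equal(GenomicRanges::end(r2$upstream_ranges), 300)
  expect_identical(r2$clamped$gene, "gP")
  expect_equal(r2$clamped$length, 300)

  # overlapping peak is kept whole and labeled by gene
  peaks <- data.frame(chrom = "chr1", start = 100, end = 200,
                      name = "pk1", stringsAsFactors = FALSE)
  r3 <- extract_regions(gm2, genome, peaks)
  expect_identical(names(r3$atac), "gP|pk1")
  expect_identical(as.character(r3$atac[[1]]), substr(contig, 101, 200))

  # unknown contig: reported in skipped
  gm3 <- rbind(gm2, data.frame(gene = "gX", seqnames = "chrZ", start = 10,
                               end = 20, strand = "+"))
  r4 <- extract_regions(gm3, genome)
  expect_identical(r4$skipped, "gX")
})

test_that("bifurcation_tfbs has the role-swap and identity contracts", {
  set.seed(26)
  pw <- example_pwms()$ets
  pr <- simulate_promoters(c(t = 30, c = 30), c(t = 4, c = 0.5),
                           pwm = pw, seq_length = 600, seed = 26)
  genes <- names(pr$sequences)
  regions <- list(upstream = Biostrings::DNAStringSet(pr$sequences),
                  atac = Biostrings::DNAStringSet(
                    setNames(substr(pr$sequences, 100, 400),
                             paste0(genes, "|pk"))))
  tset <- genes[pr$truth$set == "t"]; cset <- genes[pr$truth$set == "c"]

  fwd <- bifurcation_tfbs(regions, pw, tset, cset)
  expect_gte(fwd$by_sibs$z, 3)
  rev_ <- bifurcation_tfbs(regions, pw, cset, tset)
  expect_lt(rev_$by_sibs$z, 0)

  same <- bifurcation_tfbs(regions, pw, tset, tset)
  expect_equal(same$by_sibs$z, 0)

  none <- bifurcation_tfbs(regions, pw, character(), cset)
  expect_true(none$by_sibs$undefined)
})

test_that("ets_signature clusters by average linkage with display column", {
  sig <- data.frame(bifurcation = paste0("b", 1:4),
                    z_by_sibs = c(5, 5, 0.1, 0.2),
                    z_enr_sib1 = c(4, 4, 0, 0.1),
                    z_enr_sib2 = c(1, 1, 0, 0),
                    proxy_lfc = c(1, 1, 0.05, 0),
                    fgf_score = c(9, 8, 1, NA))
  out <- ets_signature(sig)
  # identical rows b1/b2 are adjacent at merge height 0
  ord <- rownames(out$matrix)
  expect_equal(abs(which(ord == "b1") - which(ord == "b2")), 1)
  expect_equal(min(out$hclust$height), 0)
  expect_true("fgf_score" %in% colnames(out$matrix))
  # direct-like rows separate from relay-like rows at the top split
  top2 <- cutree(out$hclust, 2)
  expect_equal(length(unique(top2[c("b1", "b2")])), 1)
  expect_false(top2[["b1"]] == top2[["b3"]])

  # brute-force average-linkage oracle on the merge heights
  m <- as.matrix(sig[, 2:5]); rownames(m) <- sig$bifurcation
  expect_equal(sort(out$hclust$height),
               sort(hclust(dist(m), method = "average")$height))

  # missing variable: excluded from clustering but kept in output
  sig2 <- sig; sig2$proxy_lfc[2] <- NA
  out2 <- ets_signature(sig2)
  expect_identical(out2$excluded, "b2")
  expect_true("b2" %in% rownames(out2$matrix))
})

test_that("peak_gene_tally assigns nearest genes with lexicographic ties", {
  genes <- data.frame(gene = c("gA", "gB", "gC"),
                      seqnames = "chr1",
                      start = c(1000, 3000, 6000),
                      end = c(1500, 3500, 6500),
                      strand = "+", stringsAsFactors = FALSE)
  # BED-style 0-based peaks
  peaks <- data.frame(chrom = "chr1",
                      start = c(1550, 2000, 3600, 5000, 6100, 250),
                      end = c(1650, 2100, 3700, 5100, 6200, 350),
                      name = paste0("p", 1:6), stringsAsFactors = FALSE)
  hits <- data.frame(seq = c("p1", "p1", "p5", "p6"), start = 0L,
                     strand = "+", score = 1, rel_score = 1,
                     center = 3, pwm = "ets", stringsAsFactors = FALSE)
  tally <- peak_gene_tally(peaks, genes, hits)
  # hand-computed oracle:
  # p1 [1551,1650] -> gA (d=50 vs gB d=1349); p2 [2001,2100] -> gA (d=500
  # vs gB d=899); p3 -> gB (d=100); p4 [5001,5100] -> gC (d=899 vs gB
  # d=1500); p5 overlaps gC (d=0); p6 -> gA
  expect_equal(tally$open_chromatin_bp[tally$gene == "gA"], 300)
  expect_equal(tally$n_peaks[tally$gene == "gA"], 3)
  expect_equal(tally$n_sites[tally$gene == "gA"], 3)
  expect_equal(tally$n_peaks[tally$gene == "gB"], 1)
  expect_equal(tally$n_sites[tally$gene == "gC"], 1)

  # exact tie: equidistant between gA and gB -> lexicographically smaller
  tie <- data.frame(chrom = "chr1", start = 2199, end = 2300,
                    name = "ptie", stringsAsFactors = FALSE)
  # 1-based peak [2200, 2300]: gap to gA end 1500 = 699, gap to gB start
  # 3000 = 699 -> exact tie
  suppressMessages(t2 <- peak_gene_tally(tie, genes, NULL))
  expect_identical(t2$gene, "gA")
})
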