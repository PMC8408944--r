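# sibflow

Lineage-resolved analysis of cell fate bifurcations in single-cell RNA-seq.

## The problem

In embryos with stereotyped lineages, a parent cell state splits into two
sibling states ("bifurcation"); the parent plus both siblings form a
"trio". When such embryos are profiled by droplet scRNA-seq from pooled
gametes of several adults, two complications and several opportunities
arise, and `sibflow` covers both ends:

- **Mother-of-origin confounding.** Maternally deposited RNA differs
  between adults, so early-stage cells cluster by mother, not cell type.
  `sibflow` assigns each cell a mother from SNP dosages via the pairwise
  relatedness statistic

  *A<sub>jk</sub>* = (1/N<sub>jk</sub>) Σ<sub>i</sub>
  (g<sub>ij</sub> − 2p<sub>i</sub>)(g<sub>ik</sub> − 2p<sub>i</sub>) /
  (2p<sub>i</sub>(1 − p<sub>i</sub>)),

  clusters cells agglomeratively on the distance max(A) − A cut at the
  known number of adults, flags poorly attached cells, and regresses the
  maternal batch means out of the normalized expression.

- **Bifurcation analytics.** With states pinned to a lineage tree:
  - **Perturbation sensitivity**: per bifurcation, a Yates-corrected
    chi-square test on the 2×2 table of terminal-stage descendant cell
    counts by treatment (e.g. MEK inhibition), scored as −log10 *p*, with
    bifurcations below an eliminated state propagated to "untestable".
  - **Trio mechanism categories**: each sibling-DE transcription factor is
    classified by its log2 fold-changes versus the parent (threshold
    ±0.3475): 1 up/unchanged, 2 both up, 3 up/down, 4 unchanged/down,
    5 both down.
  - **Induction metric**: each sibling's share of the summed |log2FC| of
    upregulated DE TFs; the larger share predicts the signal-induced
    sibling.
  - **Motif stack**: JASPAR PFM parsing, log-odds PWM scanning on both
    strands with exact p-value calibration by dynamic programming, 3-bp
    best-hit de-duplication, and a binomial over-representation z-score
    *z* = (t − p̂T)/√(T p̂(1 − p̂)) computed on 1500-bp upstream regions
    and on overlapping ATAC peaks, then averaged ("combined z") — the
    basis of a 4-variable signature separating directly signal-driven
    bifurcations from relay-driven ones.
  - **Expression waves**: Ward clustering of per-stage pseudo-bulk
    profiles of tissue-enriched genes into temporal modules.

A synthetic-data generator (`sim_spec()`, `simulate_counts()`,
`simulate_genotypes()`, `simulate_promoters()`, `write_fixture_bundle()`)
emits negative-binomial counts on a bifurcating lineage with planted DE
TFs of known category, known induced siblings, treatment ablations,
per-mother genotypes, and promoters with planted motif densities — so the
entire pipeline is testable offline against machine-readable truth.

## Worked example

```r
library(sibflow)

## mother-of-origin demultiplexing on simulated genotypes
g <- simulate_genotypes(3, 1000, dropout_rate = 0.5, error_rate = 0.01,
                        cells_per_mother = 50, seed = 11)
dmx <- demux_mothers(g$dosages, k_mothers = 3)
head(dmx$assignments, 3)
#>   barcode mother mean_within_relatedness keep review
#> 1   m1_c1      1               0.6901304 TRUE  FALSE
#> 2   m1_c2      1               0.7072830 TRUE  FALSE
#> 3   m1_c3      1               0.7153571 TRUE  FALSE
adjusted_rand_index(dmx$assignments$mother, g$truth$cell_mother)
#> [1] 1

## full pipeline on a synthetic fixture bundle
spec <- sim_spec(seed = 42)          # 14 states, 6 bifurcations, 3 mothers
dir <- file.path(tempdir(), "demo")
write_fixture_bundle(spec, dir)
res <- run_pipeline(dir, k_mothers = 3)

res$fgf[, c("parent", "chisq", "p_value", "status", "eliminated_sibling")]
#>   parent chisq  p_value      status eliminated_sibling
#> 1      A  87.6 7.87e-21   sensitive                 A1
#> 2      B  10.5 1.17e-03   sensitive                 B1
#> 3     A1    NA       NA  untestable               <NA>
#> 4     A2   0.0 1.00e+00 insensitive               <NA>
#> 5     B1    NA       NA  untestable               <NA>
#> 6     B2   0.0 1.00e+00 insensitive               <NA>
```

The planted ablation of the induced sibling `A1` is detected
(chi-square 87.6, p ≈ 8e-21, score 20.1); ablating the deeper state `B1a`
depletes `B1`'s descendants, so `B` is sensitive and every bifurcation
inside an eliminated subtree (`A1`, `B1`) is correctly reported
untestable rather than tested on absent cells.

```r
res$induction[, c("parent", "share1", "predicted")]
#>    parent share1 predicted
#> A       A  0.735        A1
#> A1     A1  0.771       A1a
#> ...
```

Every bifurcation's induced sibling carries ~73–78% of the TF
upregulation mass and is correctly predicted. The trio classifier
recovers the planted category mix (planted 45/27/9/9/9 over categories
1–5; recovered 48.5/24.2/9.1/9.1/9.1), with TFs upregulated in at least
one sibling in 81.8% of instances and downregulated in 27.3%.

```r
round(res$signature$matrix, 2)
#>    z_by_sibs z_enr_sib1 z_enr_sib2 proxy_lfc fgf_score
#> A1     12.67       5.09       2.11      0.44        NA
#> B1     13.47       7.25       2.47      0.36      ...
```

The by-sibs motif enrichment z is strongly positive wherever the induced
program's promoters carry the planted motif, and the globally induced
proxy TF has a positive fold-change in every induced sibling — the
signature used to call a bifurcation directly signal-driven.

## Command line

```sh
Rscript inst/cli/sibflow simulate --seed 17 --outdir fixtures/
Rscript inst/cli/sibflow demux --genotypes fixtures/dosages.tsv --k 3 --out labels.tsv
Rscript inst/cli/sibflow de --counts fixtures/counts --group-a A1 --group-b A2 \
    --min-lfc 0.3 --alpha 0.05 --out de.tsv
Rscript inst/cli/sibflow bifurcate --tree fixtures/lineage.tsv \
    --counts fixtures/counts --out fgf.tsv
Rscript inst/cli/sibflow waves --profiles noto.tsv --k 5 --out waves.tsv
```

Genotypes are consumed as a cell × SNP dosage TSV (0/1/2, `NA` missing);
convert a VCF with e.g. `bcftools query` upstream.

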