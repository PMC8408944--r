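---
title: "sibflow: models, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sibflow: models, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `sibflow`, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the design decisions taken where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Mother-of-origin demultiplexing

**Model.** Cells from the same mother share a diploid genotype; observed
per-cell dosages are that genotype with missingness (allelic dropout in
sparse 3' data) and call errors. For cells $j,k$ the unadjusted
relatedness is

$$A_{jk} = \frac{1}{N_{jk}} \sum_{i}
  \frac{(g_{ij} - 2p_i)(g_{ik} - 2p_i)}{2 p_i (1-p_i)},$$

summed over SNPs called in both cells, with $p_i$ the in-sample
alternate-allele frequency. Same-mother pairs share the mother's
deviation from the population mean at every SNP, so their expected
$A_{jk}$ is elevated; unrelated pairs center at 0.

**Parameters.**

- `min_calls` (default 10) and `maf_range` (default [0.05, 0.95]):
  SNP usability filters. The statistic's denominator degenerates as
  $p_i \to \{0, 1\}$; published pipelines rarely state a filter, so
  conservative defaults avoid exploding single-SNP terms.
- Distance: `max(A) - A`, not `1 - A`. Unadjusted $A_{jk}$ is unbounded
  above (it exceeds 2 for same-mother pairs at extreme frequencies), so
  `1 - A` can go negative; `max(A) - A` is always a valid dissimilarity.
- Linkage: `average` (UPGMA). The statistic is block-structured by
  construction; average linkage is robust to the heavy-tailed
  within-block noise that single linkage chains on and complete linkage
  over-fragments. Configurable.
- Tree cut: exactly `k_mothers` clusters — the codified version of
  choosing a dendrogram cutoff that mirrors the number of adults. When
  one adult contributes no cells (as happens when a batch of eggs fails),
  cutting at the number of *contributing* mothers still yields clean
  clusters; the test suite reproduces this case.
- Outlier filter `min_quantile` (default 0.01): a cell is dropped when
  its mean within-cluster relatedness falls strictly below the cluster's
  1% quantile of that statistic. Taken literally this shaves the weakest
  ~1% of even a clean cluster — the cost of a nonparametric rule with no
  free scale parameter; a doublet-like cell (average of two genotypes)
  falls far below the quantile and is removed reliably. Clusters smaller
  than 3 cells are flagged for review rather than auto-dropped, since the
  within-cluster mean is meaningless there.

**Batch regression.** After labeling, per-gene within-mother means of the
normalized expression are equalized to the gene's global mean. This is an
additive location adjustment in log space — exactly what a per-gene
linear model with a mother factor would remove — and suffices because the
maternal effect is simulated (and, to first order, observed) as a
per-gene multiplicative offset.

## 2. Normalization stand-in

Regularized variance-stabilizing transforms are deliberately not
replicated. The downstream statistics (rank-sum tests, fold changes of
de-logged means, centroid distances) need only a depth-normalized log
space with maternal effects removed, so `normalize_counts()` scales each
cell to the median total count, applies `log1p`, and (optionally)
equalizes mother means. One consequence: "normalization idempotence"
holds for the depth-scaling step (`log1p = FALSE`), not through the log
transform, and is tested in that form.

Fold changes use the pseudocount-1 ratio of de-logged group means,
$\log_2((\bar{x}_A + 1)/(\bar{x}_B + 1))$ — the scale on which the
package's 0.3 (DE gene sets) and 0.3475 (trio categories) cutoffs are
defined. The pseudocount compresses fold changes of weakly expressed
genes; this is intentional fidelity to the convention, not a bug, and it
is why the simulator gives planted TFs a solid baseline (see §6).

## 3. Differential expression

Two-sided Wilcoxon rank-sum per gene. Both groups ≤ 8 cells: exact
enumeration of all $\binom{n}{n_A}$ assignments of the observed
(possibly tied) ranks, two-sided by symmetric deviation from the mean
rank sum. Larger groups: normal approximation with the tie-corrected
variance and a 0.5 continuity correction, matching the reference
implementation to ~1e-9 (tested against `wilcox.test` on both paths).
The n ≤ 8 bound keeps enumeration below ~13k subsets per gene.

Trio TF selection keeps all TFs at unadjusted p < 0.05 — no
multiple-testing correction, by design (selection feeds a descriptive
classification, not a discovery claim);
a Benjamini–Hochberg column is available (`adjust_bh = TRUE`) but off by
default.

## 4. Bifurcation analytics

**Ablation sensitivity.** Each sibling's count is the sum over its
terminal-stage descendant states (descendant summation makes early
bifurcations testable even when intermediate states are ambiguous). The
2×2 sibling × treatment table gets the Yates continuity-corrected
chi-square (the base-R default for 2×2), p floored at 1e-300 so the
−log10 score stays finite. When a bifurcation is sensitive, the sibling
with the lower treated/control ratio (+0.5 smoothing so zero counts
compare cleanly) is the eliminated state and its whole subtree becomes
untestable — in treated embryos those cell types are simply absent, and
testing them would produce degenerate tables, not evidence.

**Trio categories.** Daughter 1 is the sibling with the higher
sibling-vs-sibling log2FC; the (vs-parent) pair $(\Delta_1, \Delta_2)$ is
mapped to categories 1–5 with "up" = $\Delta > 0.3475$ and "down" =
$\Delta < -0.3475$ (strict inequalities; the boundary is "unchanged").
A sibling-DE TF with both daughters "unchanged" versus the parent is
*unclassified* and excluded from the category denominator, so the five
percentages sum to 100. "Up-in-either" counts TF × trio instances (not
unique TFs) with at least one "up" daughter — the instance-counting
reading of an ambiguous denominator; categories 1–3 contribute to it and
3–5 to "down-in-either".

**Induction metric.** The upregulation mass of a sibling is the summed
|log2FC| of the sibling-DE TFs upregulated in it; the larger share
predicts the induced sibling. Whether such a metric should sum fold
changes, count TFs, or weight by expression is genuinely open; the
summed-|log2FC| reading is implemented as the default
and a count-based variant sits behind `count_based = TRUE` with no
fidelity claim. The metric is scale-invariant and undefined (flagged) on
an exact tie or an empty DE set.

## 5. Motif stack

**PWM.** Counts plus a total pseudocount of 0.8 distributed by the
background composition, log2-odds against the background. The consensus
(per-column argmax) attains relative score exactly 1, which makes planted
truth unambiguous for scanner tests.

**Exact p-values.** The null score distribution under an i.i.d.
background is computed by dynamic programming over per-position score
sums. States are merged on a fixed grid (resolution
$\max(10^{-9}, \text{range} \times 10^{-12})$); if the state count would
exceed 2e5 the grid coarsens with a warning. The accumulated rounding is
at most $L \cdot \varepsilon / 2$ (~3e-9 for an 8-mer), which the
enumeration oracle tests account for by probing tails between
well-separated score levels. The threshold for a scan p-value $p$ is the
smallest score with tail ≤ p, `Inf` when no attainable score is that
rare (a degenerate all-equal-columns PWM at p < 1 admits nothing).

**Scanning and dedup.** Both strands, N-containing windows skipped,
deterministic (sequence, start, strand) ordering. De-duplication keeps
the best-scoring hit among all hits (across a configured matrix group
and both strands) whose centers lie within 3 bp, ties broken by lower
start, then forward strand, then matrix name; the greedy
highest-score-first sweep is idempotent.

**Enrichment.** With $t$ hits in $T$ target nucleotides and $b$ in $B$
control nucleotides, $\hat p = b/B$ and
$z = (t - \hat p T)/\sqrt{T \hat p (1 - \hat p)}$; an optional −0.5
continuity correction is off by default. The external tool this
re-implements has version-dependent defaults; fidelity to
its numeric output is not claimed — the acceptance surface is planted
truth. The upstream-region z and the ATAC-peak z are averaged into the
combined z; a single available representation passes through flagged.

**A statistical caveat, and why the acceptance test uses matched
backgrounds.** Under the null with *independently sampled* target and
control sets, $\mathrm{Var}(t - \hat p T) = T p (1 + T/B)$ while the
denominator estimates $T p$, so z has null standard deviation
$\sqrt{1 + T/B} \approx 1.41$ for equal-size sets. A per-seed bound of
|z| ≤ 1.5 over 20 seeds therefore fails by chance roughly a quarter of
the time per seed under the i.i.d. design — we verified this empirically.
The bound is a meaningful statement only about the *planted design*, so
`simulate_promoters(share_background = TRUE)` builds target and control
sequences on the same background draws (differing only in planted
insertions), and the acceptance criterion is implemented in that matched
mode. The default generator remains fully i.i.d.; sign-correctness of z
under the i.i.d. design is still tested, with the appropriate variance in
mind.

**Regions.** Upstream windows are the 1500 bp 5' of the TSS,
strand-aware (for a minus-strand gene ending at 1-based position $e$ the
window is $[e+1, e+1500]$, reverse-complemented), clamped at contig
edges with the clamped length logged. Peaks overlapping a window are
kept *whole* and labeled by gene. BED input is 0-based half-open, GFF3
1-based; everything is converted on read and held as 1-based ranges
internally. Peak-to-gene assignment is nearest-distance (overlap = 0)
with exact ties broken to the lexicographically smaller gene id, logged.

## 6. The synthetic world

`sim_spec()` states a world: two founder lineages bifurcating at each of
three stages (14 states, 6 bifurcations), 3 mothers, 60 cells per state
per treatment, 400 genes of which 80 are TFs.

- **Counts**: negative binomial, variance $\mu + \mu^2/\theta$,
  $\theta = 10$ (typical droplet-data overdispersion); per-cell depth
  factors log-normal(0, 0.3); per-gene per-mother log2 offsets
  N(0, 0.15).
- **State programs**: every state, roots included, upregulates 12 unique
  non-TF genes by 1 log2 unit, inherited by descendants. Roots get
  programs because real founder lineages are transcriptionally distinct —
  without them label transfer between identical root distributions would
  be a coin flip.
- **Planted TFs**: per bifurcation, one globally signal-coupled proxy TF
  (category 2, oriented to the induced sibling at every bifurcation — the
  Elk-like regulator) plus ten TFs in category mix 5/2/1/1/1
  (i.e. 50/20/10/10/10%), effect 1.0 log2 units, eight of ten oriented to
  the induced sibling. Category deltas: 1 = (e, 0), 2 = (e, e/2),
  3 = (e, −e), 4 = (0, −e), 5 = (−e/2, −e); the constructor rejects
  effects too small for a category's definition (e.g. e/2 must clear the
  0.3475 threshold for categories 2 and 5).
- **Ablations**: the treated condition omits the induced sibling `A1`
  (and subtree) and the terminal induced state `B1a` — the
  signal-dependent state is the one lost under pathway inhibition, which
  is what makes the fold-change matrix's proxy-TF row all-positive.
- **Baselines**: per-gene baseline log2 means are N(3.5, 1) and planted
  TFs are floored at 32 counts/cell. Two reasons: the pseudocount in the
  fold-change formula compresses effects at low expression, and with only
  400 genes a handful of strongly shifted TFs would otherwise move the
  library size enough to create systematic composition artifacts that a
  genome-scale transcriptome would not show. Both choices were made to
  keep the 400-gene world faithful to the statistics of a 15k-gene one,
  not to tune any test.
- **Genotypes**: Beta(2,2) allele frequencies, binomial diploid mother
  genotypes, per-entry dropout (NA) and symmetric dosage-flip errors.
- **Promoters/genome**: one 3.2-kb contig per gene, alternating strands,
  a 1500-bp upstream window carrying Poisson-planted consensus sites
  (5/kb for induced-program genes, 0.5/kb otherwise) and one 800-bp peak
  inside each window.

**What a green test does not establish.** The generator has no doublets,
no ambient RNA, no read-level noise, no pseudo-replication structure
between embryos of one mother, balanced state sizes, and planted effects
that are i.i.d. across genes. Recovery at 100% here bounds algorithmic
correctness, not real-data performance; the quantitative behavior on the
deposited full-scale data is out of scope.

## 7. Waves

Per-gene max-normalization (default) before Ward (`ward.D2`) clustering
of gene × stage pseudo-bulk profiles — max-normalization preserves
profile *shape* and gives invariance to uniform positive rescaling;
z-scoring is available as an alternative. The manual dendrogram cutoff
used in practice is codified as a k-cut (`k = 5` matches the module
count typically reported for a differentiating tissue; the synthetic
default lineage supports k = 3), with a height-cut mode for exploration;
cutting at k and at the height realizing k clusters give identical
partitions, and wave ids are relabeled by peak-stage order for stable
naming. `ward.D2` on Euclidean distances is exactly the greedy
minimization of the within-cluster sum-of-squares increase, which the
test suite verifies against a from-scratch oracle.

## 8. Label transfer stand-in

Anchor-based transfer is replaced by nearest-centroid classification in
the reference PCA space with softmax(−distance) confidences, ties broken
to the first label in sort order (with a 1e-9 tolerance so floating-point
noise cannot flip an exact tie). The pipeline transfers labels per stage:
states are only comparable within a stage, and pooling stages confuses
parent/child states whose expression programs are nested.

## 9. Numerical conventions

- PCA signs are fixed by making the largest-magnitude loading of each
  component positive; embeddings are bit-reproducible.
- p-value floor 1e-300 before −log10 display scores.
- All RNG flows from a single integer seed per simulation; derived seeds
  stay below 2^31.
- Exact Wilcoxon enumeration bound n ≤ 8; chi-square correction
  `min(0.5, |O − E|)` per cell (the base-R convention).

## 10. Known limitations

- The demux k-cut requires the number of adults; gap-based automatic
  cutting is not implemented.
- VCF parsing is not built in; genotypes enter as a dosage matrix.
- The enrichment z is the plain binomial form; GC-matched backgrounds and
  sequence-composition corrections are not attempted.
- The wave module consumes any pseudo-bulk time series but does not
  integrate across datasets or batch-align them.
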