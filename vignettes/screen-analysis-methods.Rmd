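---
title: "Methods: from sgRNA counts to fitness catalogues and dependency signatures"
author: "osccfitness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from sgRNA counts to fitness catalogues and dependency signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osccfitness)
```

## The analysis problem

A pooled genome-wide CRISPR-Cas9 knockout screen infects a cell line with a
library of single-guide RNAs (sgRNAs, typically ~5 per gene), grows the pool
for two to three weeks, and sequences the surviving guide cassettes. Guides
targeting *fitness genes* — genes the cells need to proliferate — drop out of
the pool, so their read counts fall relative to the plasmid library. Run over
a panel of cell lines, such screens map each line's genetic dependencies.
Two systematic problems stand between raw counts and a credible dependency
catalogue:

1. **Gene-independent depletion over amplified regions.** Cas9 cutting in a
   highly amplified locus is toxic regardless of the targeted gene's
   function, so genes in copy-number-amplified segments look spuriously
   essential. The fix is positional: sort genes along the genome, find
   segments whose fold-changes deviate en bloc, and subtract the segment
   effect.
2. **Genes essential everywhere.** Ribosome, proteasome and spliceosome
   genes deplete in every cell line of every lineage; they dominate raw hit
   lists but make poor therapeutic targets. They are removed with compiled
   core-fitness reference lists, leaving *context-specific* dependencies.

This package implements that chain, plus the downstream machinery for
relating dependency classes to tumor expression cohorts through
gene-expression signatures, and ships a synthetic-data generator so every
stage can be validated against planted ground truth.

## Count normalization and fold-changes

`median_ratio_normalize()` uses median-of-ratios size factors: a per-sgRNA
geometric-mean reference across all samples (sgRNAs with a zero anywhere are
excluded from the reference), then the per-sample median of count/reference.
We rescale the size factors to geometric mean 1; this changes nothing
relative (normalization is defined up to a global constant) and makes the
operation exactly idempotent, which is the natural fixed-point property for
a normalizer and the one our tests assert. The estimator is cross-checked in
the test suite against `DESeq2::estimateSizeFactorsForMatrix()`.

`compute_logfc()` removes sgRNAs with *raw* plasmid counts below 30 —
guides that were poorly represented in the library give unstable ratios —
then computes `log2((endpoint + c) / (plasmid + c))` and averages
replicates per cell line (averaging after the log, not before). The
pseudocount `c = 0.5` is the smallest symmetric stabilizer; at plasmid
counts ≥ 30 its influence is below 2.5% of the ratio.

## Copy-number bias correction

`correct_cn_bias()` works per cell line and chromosome on per-gene mean
logFCs ordered by genomic position. Recursive binary segmentation splits the
sequence where a Welch test between the two sides gives p < 0.01, subject to
a minimum of 3 distinct genes per side. When a chromosome is split, every
resulting segment's mean is subtracted from its member sgRNAs — the segment
structure itself is the evidence of a regional, gene-independent effect, and
flattening all segments mirrors the behavior of segmentation-based
correction tools for this problem. An *unsplit* chromosome is left
untouched: a lone full-chromosome "segment" carries no evidence of regional
bias, and subtracting its mean would destroy genuine genome-wide depletion
signal (and violate the identity-on-flat-data property we test).

Design notes:

* Segmentation needs only gene *order*, so the synthetic library places
  genes on 22 chromosomes at unit spacing; real annotations supply true
  positions but only their order matters.
* Boundary resolution is limited by the minimum segment width: a planted
  block can keep or lose up to `min_genes - 1` genes at each edge, so
  residual block means after correction are near zero but not exactly zero;
  blocks narrower than `min_genes` are deliberately not corrected.
* The conservation property tested: the genome-wide mean logFC moves by at
  most the summed corrected-segment mass.

`gene_level_scores()` then averages sgRNAs per gene; `quantile_normalize()`
(classic order-statistic averaging, delegated to
`limma::normalizeQuantiles`) makes columns comparable across lines, and
`batch_correct()` applies a parametric empirical-Bayes location/scale
adjustment per gene and batch: standardize per gene, estimate per-batch
gene effects, shrink them toward batch-wide priors (normal for locations,
inverse-gamma with moment-matched hyperparameters for scales), remove, and
restore the per-gene grand mean exactly. With a single batch the step is a
no-op; a one-column batch gets a location-only adjustment. The combined
output is the **CRISPR score** matrix (negative = depleted). Batch labels
come from the sample sheet/config; when none are given all columns form one
batch, since a batch structure should never be invented.

Quantile normalization is applied jointly across all columns (not per
batch); with no stated batch structure this is the only defensible default.

## Depletion significance

`rra_gene_test()` is a rank-aggregation test in the α-RRA family. sgRNAs
are ranked ascending by logFC (most depleted first) and ranks normalized to
(0, 1]. For a gene with *k* guides, order statistics above `alpha = 0.5`
are discarded; the statistic is

ρ = min over retained j of **P**(Beta(j, k − j + 1) ≤ r(j)),

i.e. the most surprising order statistic under the uniform null. The null
is generated by drawing *k* uniform ranks per permutation (10,000 by
default, shared across genes with equal *k*), and
p = (1 + #{ρ_null ≤ ρ_obs}) / (n_perm + 1), so p-values are never zero and
are bit-reproducible under a fixed seed. BH adjustment is per cell line and
hits are called at FDR ≤ 0.05, *inclusive*. `alpha = 0.5` is the rank-only
analogue of selecting the better half of a gene's guides; because only
ranks enter, the test is invariant under monotone transforms of the logFC.

This is a deliberate simplification of the mean-variance-modeling +
rank-aggregation tool used in large screen projects: it is self-contained
and validated by null calibration (uniform p on null screens) and by
planted-essential recovery (sensitivity ≥ 0.9 at a −2 log2 shift, empirical
FDR ≤ 0.1 — both recomputed by `scripts/acceptance.R`). For fidelity to
externally produced gene statistics, `import_external_gene_stats()` ingests
the common gene-summary dialect so the downstream cascade can run on
deposited outputs unchanged.

Screen QC: `replicate_correlation()` (pairwise Pearson within line) and
`precision_recall_qc()` (PR curve against reference essential /
non-essential sets; area is average precision, and we report recall at 95%
precision). Reference sets are inputs, not constants baked into the
package.

## The filtering cascade

Per line, hits pass three filters, each anti-extensive and mutually
commuting (tested):

1. `expression_filter()` — hits with FPKM < 0.5 (strict) in the same line
   are implausible and removed; genes without expression measurements are
   retained and logged, since absence of evidence is not low expression.
2. `remove_core_fitness()` — the union of all supplied core-fitness source
   lists is removed everywhere. Union semantics matches compiling one
   reference list from several published compendia.
3. `recurrence_partition()` — the union catalogue splits into genes unique
   to one line and recurrent genes (≥ 2 lines), with the full histogram.

`subgroup_contrast()` implements Venn semantics (unique to A = hit in ≥ 1 A
line and 0 B lines; no minimum recurrence), `tractability_groups()`
collapses drug-tractability buckets 1–10 into groups 1–3 (1–3 / 4–7 / 8–10,
configurable), `ora_hypergeometric()` is a self-contained
over-representation test (upper-tail hypergeometric, BH q, minimum overlap
2, p < 0.05, ranked by q), and `mutation_dependency_association()` is
Fisher's exact test with both tails reported and the enrichment-direction
tail as the headline value.

## Dependency signatures

Given cell lines with validated dependency classes, `derive_degs()` runs a
one-vs-rest moderated t-test per group on `log2(x + 1)` expression:
per-gene pooled variances are shrunk toward a scaled inverse-chi-square
prior whose parameters (d0, s0²) are fitted by moment matching on the log
variances (digamma/trigamma moments). Genes with p < 0.01 and |log2FC| > 2
are kept, split by sign, and a final exclusivity pass removes genes passing
in more than one group — the signatures must separate the groups, not
describe shared biology. The implementation is validated against
`limma::eBayes` (agreement of coefficients and p-value ranking) and by
planted-block recovery, not by coefficient-level equality, since the prior
fits differ in detail.

One-vs-rest designs leak: a gene strongly up in group 1 is mildly "down" in
the group-2 and group-3 contrasts (the rest includes group 1). At the |lfc|
> 2 gate this only bites genes with very large effects, which then fail the
exclusivity pass — the desired behavior, and one of the unit tests
constructs exactly this case.

Scoring a cohort: `zscore_genes()` standardizes each gene across the
cohort with the sample (n−1) SD — each cohort separately, because Z-scores
from cohorts measured in different units are not comparable; constant genes
get Z = 0. `signature_score()` is mean(Z over up genes) − mean(Z over down
genes), so any per-sample constant cancels. `classify_samples()` calls a
sample *core* when its maximum score strictly exceeds 0.5, assigns the
argmax class, and refuses exact ties (`unclassified`, flagged): the
threshold is absolute, not rank-based, so monotone rescalings only preserve
classifications when they preserve the 0.5 crossing. `cluster_samples()`
uses Euclidean distance with average linkage by default (the tool
originally used for such heatmaps does not document its defaults, so these
are configurable).

## Enrichment

`ssgsea_score()` ranks one profile descending and accumulates a weighted
KS running sum (hit increments ∝ rank-weight^tau with tau = 0.25, miss
decrements 1/(N−|S|)); the score is the *integral* (sum) of the running
sum. When a cohort is scored, `ssgsea_matrix()` divides each set's scores
by their cohort range, the normalization of the common implementation;
single profiles return the raw integral, since absolute single-sample
values are implementation-specific and only contrasts between sample
groups are interpreted. `gsea_preranked()` computes the classic weighted
(p = 1) maximum-deviation ES with a gene-set permutation null (only a
ranking is available, so phenotype permutation is out of reach), NES =
ES / mean |null ES| of the same sign, and BH q per sign.

## The synthetic-data generator

`simulate_screen()` draws log-normal sgRNA representation (sdlog 0.5),
plasmid and endpoint counts from a shared negative-binomial model
(dispersion 0.05, i.e. size 20), endpoint means scaled by 2^lfc where lfc
combines the planted essential shift (−2 by default, with per-guide
efficacy noise of SD 0.2 — guides vary in cutting efficiency) and planted
copy-number segment biases. Defaults mirror the screen design being
emulated: 5 sgRNAs/gene, triplicate endpoints, mean depth 500 reads/sgRNA.
`simulate_expression()` plants three sample groups (sizes by deterministic
largest-remainder rounding, then a seeded shuffle — exact reproducible
sizes), per-group up/down DEG blocks of ±3 log2 units over N(5, 1.5)
baselines with N(0, 0.5) noise, and a binary mutation label with 5-fold
odds enrichment in group 3 over a 20% base rate.

What the generator does *not* emulate: guide-level off-target effects,
growth-rate differences between lines, mean-variance trends in expression,
tumor purity/microenvironment mixtures, and correlated gene modules.
Passing the recovery tests therefore demonstrates the pipeline's
correctness under its stated noise model, not performance on any particular
real dataset.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` use 1,000-gene screens (5,000
sgRNAs, depth 500), 2,000 permutations for the depletion null, and
100-sample expression cohorts — sizes at which every planted-recovery and
calibration property is comfortably measurable while the full suite runs
in well under a minute per file. All stochastic stages are seeded; the
pipeline orchestrator (`run_pipeline()`) fans a single global seed into
per-stage seeds (`seed + 101 × stage index`) and writes a manifest with
md5 hashes of every output, so reruns are bit-identical.

## Known limitations

* Segmentation boundary resolution (± `min_genes − 1` genes) leaves small
  residuals at block edges; very short amplicons (< 3 genes) are not
  corrected at the default width.
* The depletion test models ranks only; it does not use replicate-level
  count variance (the permutation null subsumes it at the cost of some
  power at very low depth).
* The batch adjustment assumes roughly balanced gene-wise effects per
  batch and at least two columns per batch for scale estimation.
* One-vs-rest DEG derivation requires ≥ 2 samples per group and behaves
  best with balanced groups; with three groups, up-signals leak into other
  groups' down-lists at half strength (see above).
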