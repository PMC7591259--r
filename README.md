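# osccfitness

Analysis of genome-wide pooled CRISPR-Cas9 fitness screens in cancer
cell-line panels — from raw sgRNA counts to statistically called fitness
genes, a context-specific dependency catalogue, and gene-expression
dependency signatures that project cell-line dependency classes onto tumor
cohorts. The package is modelled on the analysis of oral squamous cell
carcinoma (OSCC) dependency screens, where segmentation-based correction of
copy-number bias and core-fitness filtering are essential to separate
targetable, context-specific dependencies (e.g. the Hippo-pathway effectors
*YAP1*/*WWTR1*) from artefacts and pan-lineage essentials.

It is written for computational biologists who have screen count tables (or
externally produced gene-level statistics) and want a tested, self-contained
pipeline, and for methodologists who want each stage individually testable:
a synthetic-data generator with planted ground truth backs every stage.

## The method in brief

1. **Normalization / fold-changes.** Median-of-ratios size factors
   (geometric-mean reference); sgRNAs with raw plasmid counts < 30 dropped;
   `log2((endpoint + 0.5)/(plasmid + 0.5))`, replicates averaged.
2. **Copy-number bias correction.** Per chromosome, per-gene mean logFCs in
   genomic order are recursively segmented (Welch-test splits, p < 0.01,
   ≥ 3 genes/side); on split chromosomes each segment's mean is subtracted
   from its sgRNAs.
3. **CRISPR scores.** Gene-level means, quantile normalization across
   lines, empirical-Bayes batch adjustment. Negative = depleted.
4. **Depletion test.** α-RRA-style statistic
   `ρ = min_j BetaCDF(r_(j); j, k−j+1)` over a gene's retained normalized
   sgRNA ranks (α = 0.5), permutation p-values with +1 smoothing, BH FDR,
   hits at FDR ≤ 0.05.
5. **Catalogue.** Expression-plausibility filter (FPKM < 0.5), removal of
   the union of core-fitness reference lists, recurrence partition,
   subgroup Venn contrasts, tractability groups, Fisher mutation
   associations, hypergeometric over-representation.
6. **Signatures.** One-vs-rest moderated-t DEGs (p < 0.01, |log2FC| > 2,
   non-overlapping across groups); per-sample score = mean Z(up) − mean
   Z(down); core samples at score > 0.5; hierarchical clustering;
   single-sample and pre-ranked GSEA.

See `vignettes/screen-analysis-methods.Rmd` for assumptions, parameter
rationale and limitations.

## Worked example

Simulate a 500-gene screen in two cell lines with 10% planted essential
genes and a 10-gene copy-number-biased segment, score it, and call hits:

```r
library(osccfitness)

cfg <- screen_sim_config(
  n_genes = 500, n_cell_lines = 2, frac_essential = 0.1,
  cn_segments = list(list(chromosome = 3, start_gene_index = 5,
                          n_genes = 10, lfc_bias = -1.5)),
  seed = 42)
sim <- simulate_screen(cfg)
sim$counts
#> count_table: 2500 sgRNAs x 7 samples (2 cell lines)

res <- compute_crispr_scores(sim$counts, sim$annotation)
round(res$scores[1:3, ], 3)
#>          CL01   CL02
#> G00001 -0.226 -0.165
#> G00002 -0.113 -0.096
#> G00003  0.108  0.004

head(res$segments[, c("cell_line", "chromosome", "n_genes", "mean_lfc")], 1)
#>   cell_line chromosome n_genes  mean_lfc
#> 1      CL01       chr3      14 -1.171905

stats <- rra_test_matrix(res$logfc, sim$annotation, n_perm = 2000, seed = 1)
head(subset(stats, hit), 2)
#>   cell_line   gene n_sgrna          rho            p         fdr  hit
#> 4      CL01 G00004       5 1.541495e-06 0.0004997501 0.005678979 TRUE
#> 5      CL01 G00005       5 8.869590e-07 0.0004997501 0.005678979 TRUE

table(stats$cell_line[stats$hit])
#> CL01 CL02
#>   46   47

ess <- sim$truth$essential_genes[["CL01"]]
mean(ess %in% stats$gene[stats$hit & stats$cell_line == "CL01"])
#> [1] 0.92
```

The score matrix holds corrected, normalized gene-level log2 fold-changes
(more negative = stronger depletion); the segment report shows the
recovered copy-number block on chromosome 3 (planted bias −1.5, estimated
segment mean −1.17 over a 14-gene segment including the block); 46–47 hits
per line at FDR ≤ 0.05 recover 92% of the planted essentials in CL01 with
the copy-number block suppressed.

Downstream, the same objects feed the catalogue and signature stages
(`expression_filter()`, `remove_core_fitness()`, `recurrence_partition()`,
`derive_degs()`, `signature_scores()`, `classify_samples()`), and
`run_pipeline()` orchestrates all stages with a reproducibility manifest.

As a reference point for the statistics: the exact one-sided Fisher test on
a 21-line panel where 5 of 6 paralog-non-dependent lines carry a hotspot
mutation and 0 of 15 dependent lines do gives

```r
mutation_dependency_association(
  status     = c(rep(TRUE, 5), FALSE, rep(FALSE, 15)),
  dependency = c(rep(TRUE, 6), rep(FALSE, 15)))$p_one_sided
#> [1] 0.0002948548
```

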