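# Gene-level depletion significance: a rank-aggregation test in the alpha-RRA
# family with a permutation null, BH FDR control, hit calling at FDR <= 0.05,
# and screen QC against reference essential/non-essential gene sets.

# rho for one gene: sgRNA normalized ranks r (unsorted), alpha cutoff.
# Retains order statistics r_(j) <= alpha and takes the minimum Beta(j, k-j+1)
# CDF over them; genes with nothing retained score 1 (no evidence).
rra_rho <- function(r, alpha) {
  k <- length(r)
  r <- sort(r)
  j <- seq_len(k)
  keep <- r <= alpha
  if (!any(keep)) return(1)
  min(stats::pbeta(r[keep], j[keep], k - j[keep] + 1))
}

# Null rho distribution for genes with k sgRNAs: each permutation draws k
# uniform normalized ranks. Returns a sorted vector of n_perm rho values.
rra_null <- function(k, alpha, n_perm) {
  u <- matrix(stats::runif(n_perm * k), n_perm, k)
  u <- t(apply(u, 1, sort))
  b <- stats::pbeta(u, matrix(1:k, n_perm, k, byrow = TRUE),
                    matrix(k:1, n_perm, k, byrow = TRUE))
  b[u > alpha] <- 1
  rho <- do.call(pmin, as.data.frame(b))
  sort(rho)
}

#' Rank-aggregation depletion test for one screen
#'
#' Ranks sgRNAs ascending by logFC (most depleted first) and converts ranks
#' to normalized ranks (`rank/N`). For a gene with k sgRNAs, order
#' statistics exceeding `alpha` are discarded and the aggregation statistic
#' `rho` is the minimum over retained order statistics j of
#' `BetaCDF(r_(j); j, k - j + 1)` -- small when a gene's guides sit
#' unusually high in the depletion ranking. Significance comes from a
#' permutation null drawing k uniform ranks, with +1 smoothing:
#' `p = (1 + #\{null rho <= observed\}) / (n_perm + 1)`. p-values are
#' BH-adjusted across genes and hits called at FDR <= 0.05 (inclusive).
#' Because only ranks enter, the test is invariant under strictly monotone
#' transforms of the logFCs.
#'
#' @param logfc Named numeric vector of sgRNA logFCs for one cell line.
#' @param annotation Library annotation mapping sgRNAs to genes.
#' @param alpha Fraction of the ranking considered evidence (default 0.5).
#' @param n_perm Permutations for the null (default 10000, minimum 1000).
#' @param seed Integer seed for the permutation draw.
#' @param fdr_cut Hit threshold on BH FDR (default 0.05, inclusive).
#' @return `data.frame` with `gene`, `n_sgrna`, `rho`, `p`, `fdr`, `hit`.
#' @export
rra_gene_test <- function(logfc, annotation, alpha = 0.5, n_perm = 10000L,
                          seed = 1L, fdr_cut = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    stop_config("alpha must lie in (0, 1]")
  if (n_perm < 1000) stop_config("n_perm must be >= 1000")
  ann <- annotation[match(names(logfc), annotation$sgrna_id), ]
  if (anyNA(ann$gene)) stop_format("sgRNAs missing from annotation")
  N <- length(logfc)
  r <- rank(logfc, ties.method = "average") / N
  by_gene <- split(r, ann$gene)
  k_of <- lengths(by_gene)
  rho <- vapply(by_gene, rra_rho, numeric(1), alpha = alpha)

  with_seed(seed, {
    nulls <- lapply(sort(unique(k_of)), function(k) rra_null(k, alpha, n_perm))
    names(nulls) <- as.character(sort(unique(k_of)))
    p <- vapply(seq_along(rho), function(i) {
      null <- nulls[[as.character(k_of[i])]]
      (1 + findInterval(rho[i], null)) / (n_perm + 1)
    }, numeric(1))
  })
  fdr <- bh_fdr(p)
  data.frame(gene = names(by_gene), n_sgrna = as.integer(k_of),
             rho = as.numeric(rho), p = p, fdr = fdr, hit = fdr <= fdr_cut,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Depletion test across all cell lines of a logFC matrix
#'
#' Applies [rra_gene_test()] to each column; BH adjustment is per cell line.
#'
#' @param logfc sgRNA x cell-line matrix (or `logfc_table`).
#' @inheritParams rra_gene_test
#' @return `data.frame` with an extra `cell_line` column.
#' @export
rra_test_matrix <- function(logfc, annotation, alpha = 0.5, n_perm = 10000L,
                            seed = 1L, fdr_cut = 0.05) {
  if (inherits(logfc, "logfc_table")) logfc <- logfc$logfc
  out <- lapply(colnames(logfc), function(cl) {
    res <- rra_gene_test(logfc[, cl], annotation, alpha = alpha,
                         n_perm = n_perm, seed = seed, fdr_cut = fdr_cut)
    cbind(cell_line = cl, res, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wraps [stats::p.adjust()] after validation).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop_format("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Precision-recall QC against reference essential/non-essential genes
#'
#' Sweeps a threshold over gene scores (most depleted first), treating
#' reference essential genes as the positive class, and reports the
#' precision-recall curve, its area (average precision) and the recall
#' achievable at 95% precision -- the standard screen-quality readout.
#'
#' @param scores Named numeric vector of gene scores for one cell line
#'   (lower = more depleted).
#' @param essential_ref,nonessential_ref Disjoint reference gene sets; each
#'   must intersect the scored genes in at least 10 genes.
#' @return List with `curve` (`data.frame` of `recall`, `precision`),
#'   `area`, and `recall_at_95_precision`.
#' @export
precision_recall_qc <- function(scores, essential_ref, nonessential_ref) {
  essential_ref <- clean_symbols(essential_ref)
  nonessential_ref <- clean_symbols(nonessential_ref)
  if (length(intersect(essential_ref, nonessential_ref)))
    stop_format("reference sets must be disjoint")
  genes <- intersect(names(scores), union(essential_ref, nonessential_ref))
  pos <- intersect(genes, essential_ref)
  neg <- intersect(genes, nonessential_ref)
  if (length(pos) < 10 || length(neg) < 10)
    stop_format("need >= 10 essential and >= 10 non-essential reference genes in the matrix")
  s <- scores[genes]
  ord <- order(s)  # most depleted first
  is_pos <- genes[ord] %in% pos
  tp <- cumsum(is_pos)
  precision <- tp / seq_along(tp)
  recall <- tp / length(pos)
  # average precision: sum of precision at each recall increment
  area <- sum(precision[is_pos]) / length(pos)
  r95 <- if (any(precision >= 0.95)) max(recall[precision >= 0.95]) else 0
  list(curve = data.frame(recall = recall, precision = precision),
       area = area, recall_at_95_precision = r95)
}

#' Import externally produced gene-level depletion statistics
#'
#' Maps a gene-summary table from an external screen-analysis tool (the
#' usual dialect has columns `gene` or `id` plus negative-selection
#' `neg.p.value`/`neg.fdr`, or plain `p`/`fdr` columns) into the package's
#' depletion-result format, so downstream cataloguing can run on deposited
#' screen outputs.
#'
#' @param path TSV path.
#' @param fdr_cut Hit threshold (default 0.05, inclusive).
#' @param cell_line Optional cell-line label attached to the rows.
#' @return `data.frame` with `gene`, `p`, `fdr`, `hit` (and `cell_line`
#'   if given).
#' @export
import_external_gene_stats <- function(path, fdr_cut = 0.05,
                                       cell_line = NULL) {
  df <- read_tsv_checked(path)
  gene_col <- intersect(c("gene", "id"), names(df))[1]
  p_col <- intersect(c("neg.p.value", "neg|p-value", "p"), names(df))[1]
  fdr_col <- intersect(c("neg.fdr", "neg|fdr", "fdr"), names(df))[1]
  if (is.na(gene_col) || is.na(p_col) || is.na(fdr_col))
    stop_format("need gene, depletion p and FDR columns; found: ",
                paste(names(df), collapse = ", "))
  p <- suppressWarnings(as.numeric(df[[p_col]]))
  fdr <- suppressWarnings(as.numeric(df[[fdr_col]]))
  if (any(is.na(p)) || any(is.na(fdr)))
    stop_format("malformed numeric in p/FDR columns")
  out <- data.frame(gene = clean_symbols(df[[gene_col]]), p = p, fdr = fdr,
                    hit = fdr <= fdr_cut, stringsAsFactors = FALSE)
  if (!is.null(cell_line)) out <- cbind(cell_line = cell_line, out,
                                        stringsAsFactors = FALSE)
  out
}
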