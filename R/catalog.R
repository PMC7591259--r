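# The filtering cascade from per-line depletion hits to a context-specific
# fitness catalogue, and the catalogue analytics: recurrence partition,
# subgroup contrasts, tractability grouping, mutation-dependency association
# and over-representation analysis.

#' Build a fitness catalogue from per-line hit sets
#'
#' @param hits Named list: one character vector of hit genes per cell line.
#' @return Object of class `fitness_catalog` with per-line `hits`, the
#'   `union` set, and `n_dependent` (genes -> number of dependent lines).
#' @export
fitness_catalog <- function(hits) {
  if (is.null(names(hits)) || any(!nzchar(names(hits))))
    stop_format("hits must be a named list (one entry per cell line)")
  hits <- lapply(hits, function(x) unique(clean_symbols(x)))
  all_genes <- sort(unique(unlist(hits)))
  n_dep <- vapply(all_genes, function(g)
    sum(vapply(hits, function(h) g %in% h, logical(1))), integer(1))
  structure(list(hits = hits, union = all_genes,
                 n_dependent = n_dep), class = "fitness_catalog")
}

#' Build a catalogue from a depletion-result table
#'
#' @param results `data.frame` with `cell_line`, `gene`, `hit` columns (see
#'   [rra_test_matrix()] / [import_external_gene_stats()]).
#' @return A [fitness_catalog()].
#' @export
catalog_from_results <- function(results) {
  stopifnot(all(c("cell_line", "gene", "hit") %in% names(results)))
  hits <- lapply(split(results, results$cell_line),
                 function(d) d$gene[d$hit])
  fitness_catalog(hits)
}

#' @export
print.fitness_catalog <- function(x, ...) {
  cat(sprintf("fitness_catalog: %d cell lines, %d genes in union\n",
              length(x$hits), length(x$union)))
  invisible(x)
}

#' Remove low-expression hits (expression plausibility filter)
#'
#' Depletion hits with negligible expression in the same cell line (FPKM
#' below `threshold`, strict) are likely false positives and are removed.
#' Genes absent from the expression matrix are treated as not measured:
#' retained, with a message.
#'
#' @param hits Named list of hit genes per cell line.
#' @param expr Expression matrix (genes x cell lines, FPKM-like).
#' @param threshold Strict lower cutoff (default 0.5).
#' @return Named list of filtered hit sets.
#' @export
expression_filter <- function(hits, expr, threshold = 0.5) {
  absent <- setdiff(names(hits), colnames(expr))
  if (length(absent))
    stop_format("cell lines absent from expression matrix: ",
                paste(absent, collapse = ", "))
  out <- lapply(names(hits), function(cl) {
    h <- unique(clean_symbols(hits[[cl]]))
    measured <- intersect(h, rownames(expr))
    unmeasured <- setdiff(h, measured)
    if (length(unmeasured))
      message(cl, ": ", length(unmeasured),
              " hits not in expression matrix; retained as not-measured")
    low <- measured[expr[measured, cl] < threshold]
    setdiff(h, low)
  })
  names(out) <- names(hits)
  out
}

#' Remove core-fitness genes from every line's hits
#'
#' Core-fitness genes -- essential across lineages in reference compendia --
#' are removed from each line's hit set using the union of all provided
#' source lists, leaving context-specific dependencies.
#'
#' @param hits Named list of hit genes per cell line.
#' @param core_sources List of character vectors (the core-fitness source
#'   lists), or a single character vector.
#' @return List with `catalog` (a [fitness_catalog()] of the filtered hits)
#'   and `removed`, a per-line `data.frame` of counts and fractions removed.
#' @export
remove_core_fitness <- function(hits, core_sources) {
  if (is.character(core_sources)) core_sources <- list(core_sources)
  core <- unique(clean_symbols(unlist(core_sources)))
  if (!length(core)) {
    warning("empty core-fitness union; returning hits unchanged")
    core <- character(0)
  }
  filtered <- lapply(hits, function(h) setdiff(unique(clean_symbols(h)), core))
  removed <- data.frame(
    cell_line = names(hits),
    n_hits = lengths(hits),
    n_removed = lengths(hits) - lengths(filtered),
    fraction_removed = ifelse(lengths(hits) > 0,
                              (lengths(hits) - lengths(filtered)) / lengths(hits), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  list(catalog = fitness_catalog(filtered), removed = removed)
}

#' Partition catalogue genes by recurrence
#'
#' Splits the catalogue union into genes essential in exactly one line
#' (`unique`) and in two or more (`recurrent`), with the full histogram of
#' dependent-line counts.
#'
#' @param catalog A [fitness_catalog()].
#' @return List with `unique`, `recurrent`, and `histogram` (named integer
#'   vector over 1..n_lines; sums to the union size).
#' @export
recurrence_partition <- function(catalog) {
  stopifnot(inherits(catalog, "fitness_catalog"))
  n_lines <- length(catalog$hits)
  hist <- vapply(seq_len(max(1L, n_lines)), function(k)
    sum(catalog$n_dependent == k), integer(1))
  names(hist) <- seq_along(hist)
  list(unique = names(catalog$n_dependent)[catalog$n_dependent == 1],
       recurrent = names(catalog$n_dependent)[catalog$n_dependent >= 2],
       histogram = hist)
}

#' Contrast fitness genes between two groups of cell lines
#'
#' A gene is unique to group A if it is a hit in at least one A line and in
#' no B line (Venn semantics); symmetric for B; hits in both groups are
#' shared.
#'
#' @param catalog A [fitness_catalog()].
#' @param group_a,group_b Disjoint character vectors of cell-line names.
#' @return List with `unique_a`, `unique_b`, `shared`.
#' @export
subgroup_contrast <- function(catalog, group_a, group_b) {
  stopifnot(inherits(catalog, "fitness_catalog"))
  if (length(intersect(group_a, group_b)))
    stop_format("groups must be disjoint")
  missing <- setdiff(c(group_a, group_b), names(catalog$hits))
  if (length(missing))
    stop_format("lines not in catalog: ", paste(missing, collapse = ", "))
  a_hits <- sort(unique(unlist(catalog$hits[group_a])))
  b_hits <- sort(unique(unlist(catalog$hits[group_b])))
  list(unique_a = setdiff(a_hits, b_hits),
       unique_b = setdiff(b_hits, a_hits),
       shared = intersect(a_hits, b_hits))
}

#' Map tractability buckets to coarse groups
#'
#' Buckets 1-3 (approved drugs or drugs in clinical/pre-clinical
#' development) map to group 1; 4-7 (evidence supporting tractability) to
#' group 2; 8-10 (little or no evidence) to group 3; genes absent from the
#' table are `unknown`.
#'
#' @param genes Character vector of genes to classify.
#' @param table Tractability `data.frame` (`gene`, `bucket`), see
#'   [read_tractability()].
#' @param mapping Named list group -> bucket vector (defaults above).
#' @return Named character vector gene -> group in
#'   `{"1", "2", "3", "unknown"}`.
#' @export
tractability_groups <- function(genes, table,
                                mapping = list(`1` = 1:3, `2` = 4:7,
                                               `3` = 8:10)) {
  genes <- clean_symbols(genes)
  if (any(!table$bucket %in% 1:10))
    stop_format("tractability buckets must be in 1..10")
  bucket_to_group <- rep(NA_character_, 10)
  for (g in names(mapping)) bucket_to_group[mapping[[g]]] <- g
  idx <- match(genes, table$gene)
  out <- ifelse(is.na(idx), "unknown", bucket_to_group[table$bucket[idx]])
  stats::setNames(out, genes)
}

#' Association between a mutation label and a dependency label
#'
#' Fisher's exact (hypergeometric) test on the 2x2 cross-tabulation of two
#' binary labels over cell lines, e.g. mutated vs dependency status. The
#' one-sided (enrichment-direction) p is the headline value; both tails and
#' the odds ratio are reported. A degenerate margin (all lines share a
#' label) gives p = 1 with a warning.
#'
#' @param status Logical vector (e.g. mutated) named by cell line.
#' @param dependency Logical vector over the same lines.
#' @return List with `table` (2x2), `odds_ratio`, `p_one_sided`,
#'   `p_two_sided`.
#' @export
mutation_dependency_association <- function(status, dependency) {
  if (!is.null(names(status)) && !is.null(names(dependency)))
    dependency <- dependency[names(status)]
  if (length(status) != length(dependency) || anyNA(status) || anyNA(dependency))
    stop_format("status and dependency must be equal-length complete logicals")
  tab <- table(factor(status, levels = c(TRUE, FALSE)),
               factor(dependency, levels = c(TRUE, FALSE)),
               dnn = c("status", "dependency"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin: association undefined, p = 1")
    return(list(table = tab, odds_ratio = NA_real_,
                p_one_sided = 1, p_two_sided = 1))
  }
  two <- stats::fisher.test(tab)
  greater <- stats::fisher.test(tab, alternative = "greater")$p.value
  less <- stats::fisher.test(tab, alternative = "less")$p.value
  list(table = tab, odds_ratio = unname(two$estimate),
       p_one_sided = min(greater, less), p_two_sided = two$p.value)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p per gene set for the overlap with a query
#' list, BH q across all tested sets, then filtering at `overlap >=
#' min_overlap` and `p < p_cut`, ranked by ascending q.
#'
#' @param query Character vector of query genes (must lie in `universe`).
#' @param gene_sets Named list of gene sets (intersected with the universe).
#' @param universe Character vector: all genes eligible for selection.
#' @param min_overlap Minimum overlap to report a set (default 2).
#' @param p_cut p-value cutoff (default 0.05, strict).
#' @return `data.frame` with `set`, `set_size`, `overlap`, `p`, `q`, sorted
#'   by `q`.
#' @export
ora_hypergeometric <- function(query, gene_sets, universe, min_overlap = 2L,
                               p_cut = 0.05) {
  universe <- unique(clean_symbols(universe))
  if (!length(universe)) stop_format("empty universe")
  query <- intersect(unique(clean_symbols(query)), universe)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(clean_symbols(gene_sets[[nm]]), universe)
    ov <- length(intersect(query, set))
    p <- stats::phyper(ov - 1, length(set), length(universe) - length(set),
                       length(query), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_fdr(res$p)
  res <- res[res$overlap >= min_overlap & res$p < p_cut, , drop = FALSE]
  res[order(res$q, res$p), , drop = FALSE]
}

#' CRISPR scores split by mutation status, with a Welch test
#'
#' Lists a gene's CRISPR scores across cell lines grouped by a binary
#' mutation/amplification status and, when both groups have at least two
#' lines, tests the group difference with Welch's t.
#'
#' @param scores Gene x cell-line CRISPR score matrix.
#' @param status Logical vector named by cell line (e.g. amplified or not).
#' @param gene Gene to examine.
#' @return List with `scores` (named list of the two groups) and `test`
#'   (`welch_t()` result, or `NULL` when a group has fewer than 2 lines).
#' @export
score_by_mutation <- function(scores, status, gene) {
  gene <- clean_symbols(gene)
  if (!gene %in% rownames(scores)) stop_format("gene not in score matrix: ", gene)
  lines <- intersect(colnames(scores), names(status))
  if (!length(lines)) stop_format("no overlapping cell lines")
  s <- scores[gene, lines]
  grp <- split(s, ifelse(status[lines], "mutated", "wild_type"))
  test <- if (length(grp) == 2 && all(lengths(grp) >= 2))
    welch_t(grp[["mutated"]], grp[["wild_type"]]) else NULL
  list(scores = grp, test = test)
}
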