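# Gene set enrichment: single-sample scores (rank-weighted running-sum
# integral) and pre-ranked GSEA with a gene-set permutation null.

# Running-sum increments for one profile/set; shared by both scorers.
# Genes are ordered descending by value; hits step up proportionally to
# rank_weight^tau (rank weight N..1), misses step down by 1/(N - |S|).
ssgsea_running_sum <- function(ord_genes, gene_set, tau) {
  N <- length(ord_genes)
  hit <- ord_genes %in% gene_set
  nh <- sum(hit)
  if (nh == 0) stop_format("gene set does not intersect the profile")
  w <- (N - seq_len(N) + 1)^tau
  incr <- numeric(N)
  incr[hit] <- w[hit] / sum(w[hit])
  if (nh == N) {
    warning("gene set covers the whole profile: miss decrement undefined, ",
            "returning the maximal positive running sum")
  } else {
    incr[!hit] <- -1 / (N - nh)
  }
  cumsum(incr)
}

#' Single-sample enrichment score for one expression profile
#'
#' Ranks the profile's genes descending by expression and walks the ranking
#' with a weighted Kolmogorov-Smirnov running sum: set members increment
#' proportionally to `rank_weight^tau`, non-members decrement uniformly.
#' The enrichment score is the sum over the running-sum values (the
#' integral form), positive when set members concentrate among the highest
#' expressed genes. Being rank-based, the score is invariant under strictly
#' increasing transforms of the profile.
#'
#' @param profile Named numeric vector: one sample's expression.
#' @param gene_set Character vector (needs >= 2 genes in the profile).
#' @param tau Rank-weight exponent (default 0.25).
#' @return Numeric enrichment score (raw integral, unnormalized).
#' @export
ssgsea_score <- function(profile, gene_set, tau = 0.25) {
  if (length(intersect(names(profile), gene_set)) < 2)
    stop_format("gene set must share >= 2 genes with the profile")
  ord <- names(profile)[order(profile, decreasing = TRUE)]
  sum(ssgsea_running_sum(ord, gene_set, tau))
}

#' Single-sample enrichment scores over a cohort
#'
#' Scores every sample against every gene set and, by default, normalizes
#' each set's scores by its range across the cohort (max - min), the usual
#' cohort-level normalization; raw integrals are returned when
#' `normalize = FALSE`.
#'
#' @param expr Expression matrix (genes x samples).
#' @param gene_sets Named list of gene sets.
#' @param tau Rank-weight exponent (default 0.25).
#' @param normalize Divide each set's scores by their cohort range.
#' @return Matrix (sets x samples) of enrichment scores.
#' @export
ssgsea_matrix <- function(expr, gene_sets, tau = 0.25, normalize = TRUE) {
  es <- vapply(colnames(expr), function(s) {
    profile <- expr[, s]
    names(profile) <- rownames(expr)
    vapply(gene_sets, function(gs) ssgsea_score(profile, gs, tau), numeric(1))
  }, numeric(length(gene_sets)))
  es <- matrix(es, nrow = length(gene_sets),
               dimnames = list(names(gene_sets), colnames(expr)))
  if (normalize && ncol(es) > 1) {
    rng <- apply(es, 1, function(v) diff(range(v)))
    rng[rng == 0] <- 1
    es <- es / rng
  }
  es
}

# Classic weighted (p = 1) KS enrichment score of a set in a ranking:
# maximum-deviation (signed) form.
gsea_es <- function(stats_sorted, hit) {
  N <- length(stats_sorted)
  nh <- sum(hit)
  if (nh < 2 || nh >= N) return(NA_real_)
  w <- abs(stats_sorted)
  incr <- numeric(N)
  if (sum(w[hit]) == 0) incr[hit] <- 1 / nh else incr[hit] <- w[hit] / sum(w[hit])
  incr[!hit] <- -1 / (N - nh)
  running <- cumsum(incr)
  running[which.max(abs(running))]
}

#' Pre-ranked gene set enrichment with a gene-set permutation null
#'
#' Computes the classic weighted (p = 1) Kolmogorov-Smirnov enrichment
#' score of each set in a ranked gene list, builds a null by drawing random
#' gene sets of the same size, and reports the normalized enrichment score
#' (ES divided by the mean |null ES| of the same sign), a permutation
#' p-value with +1 smoothing, and BH q-values computed separately per sign.
#' Sets with fewer than 2 genes after intersection are skipped with a
#' message.
#'
#' @param ranked Named numeric vector of gene-level scores (the ranking
#'   metric); ties are allowed, missing genes are not.
#' @param gene_sets Named list of gene sets.
#' @param n_perm Number of random sets per null (default 1000).
#' @param seed Integer seed.
#' @return `data.frame` with `set`, `size`, `es`, `nes`, `p`, `q`.
#' @export
gsea_preranked <- function(ranked, gene_sets, n_perm = 1000L, seed = 1L) {
  if (anyNA(ranked)) stop_format("ranking must not contain missing values")
  ord <- order(ranked, decreasing = TRUE)
  stats_sorted <- ranked[ord]
  genes_sorted <- names(ranked)[ord]
  rows <- list()
  with_seed(seed, {
    null_cache <- list()
    for (nm in names(gene_sets)) {
      set <- intersect(gene_sets[[nm]], genes_sorted)
      sz <- length(set)
      if (sz < 2) {
        message("set '", nm, "' has < 2 genes after intersection; skipped")
        next
      }
      es <- gsea_es(stats_sorted, genes_sorted %in% set)
      key <- as.character(sz)
      if (is.null(null_cache[[key]])) {
        null_cache[[key]] <- vapply(seq_len(n_perm), function(i) {
          hit <- logical(length(genes_sorted))
          hit[sample.int(length(genes_sorted), sz)] <- TRUE
          gsea_es(stats_sorted, hit)
        }, numeric(1))
      }
      null <- null_cache[[key]]
      same_sign <- null[sign(null) == sign(es)]
      nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
      p <- (1 + sum(abs(same_sign) >= abs(es))) / (length(same_sign) + 1)
      rows[[nm]] <- data.frame(set = nm, size = sz, es = es, nes = nes,
                               p = p, stringsAsFactors = FALSE)
    }
  })
  if (!length(rows))
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p = numeric(), q = numeric()))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$q <- NA_real_
  for (sgn in c(-1, 1)) {
    idx <- which(sign(res$es) == sgn)
    if (length(idx)) res$q[idx] <- bh_fdr(res$p[idx])
  }
  res
}
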