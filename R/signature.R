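# Dependency-signature machinery: derive group DEG signatures with a
# moderated one-vs-rest t-test, compute per-sample Z-score based signature
# scores, classify core samples, cluster score profiles, and the two
# elementary tests used throughout (Welch t, Pearson with p).

# Empirical-Bayes variance shrinkage: given per-gene sample variances s2 on
# d residual df, fit a scaled inverse-chi-square prior (d0, s0^2) by moment
# matching on log s2 (mean/variance of log variances against the theoretical
# digamma/trigamma moments), and return posterior variances
# (d0 s0^2 + d s2) / (d0 + d). d0 = Inf collapses every gene to s0^2.
squeeze_var <- function(s2, df) {
  s2 <- pmax(s2, 1e-12)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  ev <- stats::var(e)
  target <- ev - trigamma(df / 2)
  if (!is.finite(target) || target <= 1e-10) {
    d0 <- Inf
    s0 <- exp(mean(e))
  } else {
    f <- function(x) trigamma(x / 2) - target
    d0 <- stats::uniroot(f, c(0.02, 1e8), tol = 1e-8)$root
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  post <- if (is.infinite(d0)) rep(s0, length(s2)) else
    (d0 * s0 + df * s2) / (d0 + df)
  list(var_post = post, d0 = d0, s0 = s0)
}

# Moderated two-sample (one-vs-rest) t-test per gene on a log-scale matrix.
moderated_t <- function(logexpr, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group)
  if (n1 < 2 || n2 < 2) stop_config("each side needs >= 2 samples")
  m1 <- rowMeans(logexpr[, in_group, drop = FALSE])
  m2 <- rowMeans(logexpr[, !in_group, drop = FALSE])
  v1 <- rowVars(logexpr[, in_group, drop = FALSE])
  v2 <- rowVars(logexpr[, !in_group, drop = FALSE])
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  sq <- squeeze_var(s2, df)
  df_total <- if (is.infinite(sq$d0)) 1e6 else df + sq$d0
  t_stat <- (m1 - m2) / sqrt(sq$var_post * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(t_stat), df_total)
  data.frame(gene = rownames(logexpr), logfc = m1 - m2, t = t_stat, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Derive group DEG signatures by moderated one-vs-rest tests
#'
#' For each group, genes are tested one-vs-rest with a moderated t-test
#' (empirical-Bayes variance shrinkage across genes); genes with
#' `p < p_cut` and `|log2FC| > lfc_cut` are kept and split by sign into
#' up/down sets. A final exclusivity pass drops any gene passing in more
#' than one group, so the signatures are non-overlapping.
#'
#' @param expr Expression matrix (genes x samples). If `linear = TRUE`
#'   (default) values are transformed with `log2(x + 1)` first.
#' @param labels Named vector mapping each sample to its group.
#' @param p_cut p-value threshold (default 0.01, strict).
#' @param lfc_cut |log2 fold-change| threshold (default 2, strict).
#' @param linear Whether `expr` is on the linear scale (default `TRUE`).
#' @return Object of class `deg_signature`: per group a list with `up` and
#'   `down` gene sets, plus the thresholds used.
#' @export
derive_degs <- function(expr, labels, p_cut = 0.01, lfc_cut = 2,
                        linear = TRUE) {
  labels <- labels[colnames(expr)]
  if (anyNA(labels)) stop_format("every sample needs a group label")
  if (any(table(labels) < 2)) stop_config("each group needs >= 2 samples")
  logexpr <- if (linear) log2(expr + 1) else expr
  groups <- sort(unique(as.character(labels)))
  pass <- list()
  for (g in groups) {
    res <- moderated_t(logexpr, labels == g)
    keep <- res$p < p_cut & abs(res$logfc) > lfc_cut
    pass[[g]] <- res[keep, , drop = FALSE]
  }
  all_pass <- unlist(lapply(pass, function(d) d$gene))
  dup <- unique(all_pass[duplicated(all_pass)])
  sig <- lapply(pass, function(d) {
    d <- d[!d$gene %in% dup, , drop = FALSE]
    list(up = sort(d$gene[d$logfc > 0]), down = sort(d$gene[d$logfc < 0]))
  })
  structure(list(groups = sig, p_cut = p_cut, lfc_cut = lfc_cut),
            class = "deg_signature")
}

#' Per-gene Z-scores across a cohort
#'
#' Standardizes each gene across the cohort's samples: `(x - mean) / sd`
#' with the sample (n-1) standard deviation. Constant genes get Z = 0 for
#' all samples. Cohorts are standardized separately (cell lines against
#' cell lines, tumors against the tumor cohort) -- pass one cohort at a
#' time.
#'
#' @param expr Numeric matrix (genes x samples), any monotone scale.
#' @return Z matrix of the same shape.
#' @export
zscore_genes <- function(expr) {
  if (ncol(expr) < 2) stop_format("Z-scores need >= 2 samples")
  m <- rowMeans(expr)
  s <- sqrt(rowVars(expr))
  z <- (expr - m) / ifelse(s == 0, 1, s)
  z[s == 0, ] <- 0
  z
}

#' Dependency signature score of samples for one group
#'
#' The signature score is the mean Z-score over the group's up-regulated
#' DEGs minus the mean Z-score over its down-regulated DEGs, per sample.
#' Genes missing from the Z matrix are dropped with a message; an empty up
#' or down set after intersection is an error.
#'
#' @param z Z matrix (genes x samples), see [zscore_genes()].
#' @param signature A [derive_degs()] result.
#' @param group Group name within the signature.
#' @return Named numeric vector of per-sample scores.
#' @export
signature_score <- function(z, signature, group) {
  stopifnot(inherits(signature, "deg_signature"))
  sig <- signature$groups[[group]]
  if (is.null(sig)) stop_format("unknown group: ", group)
  up <- intersect(sig$up, rownames(z))
  down <- intersect(sig$down, rownames(z))
  n_miss <- (length(sig$up) - length(up)) + (length(sig$down) - length(down))
  if (n_miss > 0)
    message(group, ": ", n_miss, " signature genes absent from Z matrix")
  if (!length(up) || !length(down))
    stop_format(group, ": empty up or down set after intersection")
  colMeans(z[up, , drop = FALSE]) - colMeans(z[down, , drop = FALSE])
}

#' Signature scores for all groups of a signature
#'
#' @inheritParams signature_score
#' @return `data.frame`: one row per sample, one score column per group.
#' @export
signature_scores <- function(z, signature) {
  stopifnot(inherits(signature, "deg_signature"))
  out <- vapply(names(signature$groups),
                function(g) signature_score(z, signature, g),
                numeric(ncol(z)))
  data.frame(sample = colnames(z), out, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Classify samples from their signature scores
#'
#' A sample is a core sample when its maximum score strictly exceeds
#' `core_cut`; its class is then the argmax group. Samples with no score
#' above the cutoff are `unclassified`; an exact tie at the maximum is
#' refused as `unclassified` with `tie = TRUE`.
#'
#' @param scores `data.frame` from [signature_scores()] (first column
#'   `sample`, then one column per group).
#' @param core_cut Strict threshold for core membership (default 0.5).
#' @return The input with added `class`, `core`, `tie` columns.
#' @export
classify_samples <- function(scores, core_cut = 0.5) {
  grp_cols <- setdiff(names(scores), "sample")
  m <- as.matrix(scores[grp_cols])
  if (anyNA(m)) stop_format("missing signature score")
  mx <- apply(m, 1, max)
  n_at_max <- rowSums(m == mx)
  core <- mx > core_cut
  cls <- rep("unclassified", nrow(m))
  tie <- core & n_at_max > 1
  ok <- core & !tie
  cls[ok] <- grp_cols[apply(m[ok, , drop = FALSE], 1, which.max)]
  cls[tie] <- "unclassified"
  scores$class <- cls
  scores$core <- core & !tie
  scores$tie <- tie
  scores
}

#' Hierarchical clustering of samples on their signature scores
#'
#' Agglomerative clustering (Euclidean distance, average linkage by
#' default) of the per-sample score vectors; the heatmap row order is the
#' dendrogram leaf order.
#'
#' @param scores `data.frame` from [signature_scores()].
#' @param method Linkage method for [stats::hclust()] (default "average").
#' @param k Optional number of clusters to cut at.
#' @return List with `hclust`, `order` (leaf order of sample names),
#'   `matrix` (samples x groups, leaf-ordered), and `cluster` (if `k`
#'   given).
#' @export
cluster_samples <- function(scores, method = "average", k = NULL) {
  grp_cols <- setdiff(names(scores), c("sample", "class", "core", "tie"))
  m <- as.matrix(scores[grp_cols])
  rownames(m) <- scores$sample
  hc <- stats::hclust(stats::dist(m), method = method)
  out <- list(hclust = hc, order = rownames(m)[hc$order],
              matrix = m[hc$order, , drop = FALSE])
  if (!is.null(k)) out$cluster <- stats::cutree(hc, k = k)
  out
}

#' Welch's two-sample t-test
#'
#' Unpaired t-test with Welch's (Satterthwaite) correction for unequal
#' variances, the default group comparison for unequal sample sizes. Two
#' constant groups with equal means return t = 0, p = 1.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop_format("each group needs >= 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Pearson correlation with a two-sided p-value
#'
#' Pearson r with the exact t-transform p-value,
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` against `t(n - 2)`. Constant input
#' yields `NA` with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_format("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
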