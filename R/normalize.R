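# Counts -> normalized log2 fold-changes -> copy-number-bias-corrected,
# quantile/batch-normalized gene-level CRISPR scores. The "CRISPR score" is
# the segmentation-corrected, quantile-normalized, batch-adjusted gene-level
# log2 fold-change; negative values indicate depletion (loss of fitness on
# knockout).

#' Median-ratio normalization of screen counts
#'
#' Classic median-of-ratios size factors: a per-row geometric-mean reference
#' is computed over all columns (rows with any zero are excluded from the
#' reference), and each column's size factor is the median of its ratios to
#' the reference. Size factors are rescaled to geometric mean 1, which makes
#' the operation idempotent; each column is then divided by its factor.
#'
#' @param ct A [count_table()].
#' @return A `count_table` whose `counts` are real-valued normalized counts,
#'   with attributes `size_factors` and the raw plasmid counts retained in
#'   `$raw_plasmid` for the plasmid-representation filter.
#' @export
median_ratio_normalize <- function(ct) {
  stopifnot(inherits(ct, "count_table"))
  x <- ct$counts
  pos <- rowSums(x <= 0) == 0
  if (sum(pos) < 2)
    stop_format("median-ratio normalization needs >= 2 sgRNAs with all-positive counts")
  ref <- exp(rowMeans(log(x[pos, , drop = FALSE])))
  sf  <- apply(x[pos, , drop = FALSE], 2, function(col) stats::median(col / ref))
  sf  <- sf / exp(mean(log(sf)))
  norm <- sweep(x, 2, sf, "/")
  out <- ct
  out$raw_plasmid <- ct$raw_plasmid %||% x[, plasmid_column(ct)]
  out$counts <- norm
  attr(out$counts, "size_factors") <- sf
  out
}

#' Compute sgRNA log2 fold-changes against the plasmid
#'
#' sgRNAs with a raw plasmid count below `plasmid_min` (default 30) are
#' excluded before computation, removing guides with unreliable library
#' representation. For each surviving sgRNA and end-point sample,
#' `log2((endpoint + pseudocount) / (plasmid + pseudocount))` is computed on
#' normalized counts; replicates of a cell line are then averaged.
#'
#' @param ct A (typically normalized) [count_table()].
#' @param plasmid_min Minimum raw plasmid count to retain an sgRNA.
#' @param pseudocount Stabilizer added to both numerator and denominator
#'   (default 0.5).
#' @return A list of class `logfc_table`: `logfc` (sgRNA x cell line,
#'   replicate-averaged), `per_replicate` (sgRNA x sample), `samples`, and
#'   `n_filtered`.
#' @export
compute_logfc <- function(ct, plasmid_min = 30, pseudocount = 0.5) {
  stopifnot(inherits(ct, "count_table"))
  raw_plasmid <- ct$raw_plasmid %||% ct$counts[, plasmid_column(ct)]
  keep <- raw_plasmid >= plasmid_min
  if (!any(keep))
    stop_format("all sgRNAs fail the plasmid filter (plasmid_min = ", plasmid_min, ")")
  x <- ct$counts[keep, , drop = FALSE]
  plasmid <- x[, plasmid_column(ct)]
  endpoints <- ct$samples[ct$samples$role == "endpoint", , drop = FALSE]
  per_rep <- log2(sweep(x[, endpoints$sample_id, drop = FALSE] + pseudocount,
                        1, plasmid + pseudocount, "/"))
  lines <- unique(endpoints$cell_line)
  logfc <- vapply(lines, function(cl) {
    cols <- endpoints$sample_id[endpoints$cell_line == cl]
    rowMeans(per_rep[, cols, drop = FALSE])
  }, numeric(nrow(per_rep)))
  colnames(logfc) <- lines
  structure(list(logfc = logfc, per_replicate = per_rep,
                 samples = endpoints, n_filtered = sum(!keep)),
            class = "logfc_table")
}

#' Pairwise replicate correlations per cell line
#'
#' Quality metric for screen reproducibility: Pearson correlation between
#' every replicate pair of each cell line. A constant replicate vector has
#' undefined correlation and is reported as `NA`.
#'
#' @param per_replicate sgRNA x sample numeric matrix (raw counts or logFCs).
#' @param samples Sample sheet with `sample_id`, `cell_line`, `replicate`.
#' @return `data.frame` with `cell_line`, `rep_a`, `rep_b`, `pearson_r`.
#' @export
replicate_correlation <- function(per_replicate, samples) {
  samples <- samples[samples$sample_id %in% colnames(per_replicate), , drop = FALSE]
  out <- list()
  for (cl in unique(samples$cell_line)) {
    cols <- samples$sample_id[samples$cell_line == cl]
    if (length(cols) < 2) next
    for (i in seq_len(length(cols) - 1)) for (j in seq(i + 1, length(cols))) {
      a <- per_replicate[, cols[i]]; b <- per_replicate[, cols[j]]
      r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
      out[[length(out) + 1]] <- data.frame(
        cell_line = cl, rep_a = cols[i], rep_b = cols[j], pearson_r = r,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(cell_line = character(), rep_a = character(),
                      rep_b = character(), pearson_r = numeric()))
  do.call(rbind, out)
}

# Recursive binary segmentation of a numeric sequence of per-gene means.
# A split is accepted when the Welch test between the two parts has
# p < split_p and both parts hold at least min_genes genes. Returns the
# sorted vector of segment start indices.
segment_means <- function(v, min_genes, split_p) {
  n <- length(v)
  if (n < 2 * min_genes) return(1L)
  best_p <- Inf; best_i <- NA_integer_
  for (i in seq(min_genes, n - min_genes)) {
    a <- v[seq_len(i)]; b <- v[seq(i + 1, n)]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      p <- if (mean(a) == mean(b)) 1 else 0
    } else {
      p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
    }
    if (is.finite(p) && p < best_p) { best_p <- p; best_i <- i }
  }
  if (is.na(best_i) || best_p >= split_p) return(1L)
  left  <- segment_means(v[seq_len(best_i)], min_genes, split_p)
  right <- segment_means(v[seq(best_i + 1, length(v))], min_genes, split_p)
  sort(c(left, right + best_i))
}

#' Correct copy-number-driven and other gene-independent depletion bias
#'
#' Knockout of genes in amplified regions depletes cells regardless of gene
#' function, inflating false-positive essentiality calls. For each cell line
#' and chromosome, per-gene mean logFCs are ordered by genomic position and
#' recursively segmented (binary segmentation; a split needs Welch p <
#' `split_p` and `min_genes` genes on each side). On chromosomes where at
#' least one split is accepted, each resulting segment's mean is subtracted
#' from its member sgRNA logFCs, flattening regional bias; unsplit
#' chromosomes are left untouched.
#'
#' @param logfc sgRNA x cell-line logFC matrix (or a `logfc_table`).
#' @param annotation Library annotation covering every sgRNA row.
#' @param min_genes Minimum distinct genes per segment (default 3).
#' @param split_p Welch p-value threshold to accept a split (default 0.01).
#' @return List with `corrected` (same shape as input) and `segments`, a
#'   report `data.frame` of corrected segments (`cell_line`, `chromosome`,
#'   `start_gene`, `end_gene`, `n_genes`, `mean_lfc`).
#' @export
correct_cn_bias <- function(logfc, annotation, min_genes = 3L, split_p = 0.01) {
  if (inherits(logfc, "logfc_table")) logfc <- logfc$logfc
  missing_ann <- setdiff(rownames(logfc), annotation$sgrna_id)
  if (length(missing_ann))
    stop_format("sgRNAs missing from annotation: ",
                paste(utils::head(missing_ann, 5), collapse = ", "))
  ann <- annotation[match(rownames(logfc), annotation$sgrna_id), ]
  corrected <- logfc
  seg_report <- list()

  # genomic order of genes within each chromosome
  gene_pos <- unique(ann[c("gene", "chromosome", "position")])
  for (cl in colnames(logfc)) {
    v <- logfc[, cl]
    gene_mean <- tapply(v, ann$gene, mean)
    for (chrom in unique(gene_pos$chromosome)) {
      gp <- gene_pos[gene_pos$chromosome == chrom, ]
      gp <- gp[order(gp$position), ]
      means <- gene_mean[gp$gene]
      starts <- segment_means(as.numeric(means), min_genes, split_p)
      if (length(starts) < 2) next  # chromosome unsplit: no correction
      ends <- c(starts[-1] - 1L, length(means))
      for (s in seq_along(starts)) {
        idx <- seq(starts[s], ends[s])
        if (length(idx) < min_genes) next
        seg_genes <- gp$gene[idx]
        seg_mean  <- mean(means[idx])
        rows <- which(ann$gene %in% seg_genes)
        corrected[rows, cl] <- corrected[rows, cl] - seg_mean
        seg_report[[length(seg_report) + 1]] <- data.frame(
          cell_line = cl, chromosome = chrom,
          start_gene = gp$gene[idx[1]], end_gene = gp$gene[idx[length(idx)]],
          n_genes = length(idx), mean_lfc = seg_mean,
          stringsAsFactors = FALSE)
      }
    }
  }
  segments <- if (length(seg_report)) do.call(rbind, seg_report) else
    data.frame(cell_line = character(), chromosome = character(),
               start_gene = character(), end_gene = character(),
               n_genes = integer(), mean_lfc = numeric())
  list(corrected = corrected, segments = segments)
}

#' Collapse sgRNA logFCs to gene-level scores
#'
#' Each gene's score per cell line is the mean logFC of its surviving
#' sgRNAs. Genes whose sgRNAs were all removed upstream are absent from the
#' output (reported via a message).
#'
#' @param logfc sgRNA x cell-line matrix.
#' @param annotation Library annotation.
#' @return Gene x cell-line numeric matrix.
#' @export
gene_level_scores <- function(logfc, annotation) {
  if (inherits(logfc, "logfc_table")) logfc <- logfc$logfc
  ann <- annotation[match(rownames(logfc), annotation$sgrna_id), ]
  if (anyNA(ann$gene)) stop_format("sgRNAs missing from annotation")
  n <- as.vector(table(ann$gene))
  scores <- rowsum(logfc, ann$gene) / n
  lost <- setdiff(unique(annotation$gene), rownames(scores))
  if (length(lost))
    message(length(lost), " genes lost all sgRNAs upstream and have no score")
  scores
}

#' Quantile normalization of a score matrix
#'
#' Classic quantile normalization: each column's order statistics are
#' replaced by the cross-column mean order statistics (ties receive the mean
#' of their would-be values), so every column shares an identical sorted
#' value multiset afterwards. Missing values are imputed by column median
#' for the transform and re-masked afterwards.
#'
#' @param scores Gene x cell-line numeric matrix.
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize <- function(scores) {
  if (ncol(scores) < 2) {
    warning("quantile normalization needs >= 2 columns; returning input")
    return(scores)
  }
  na_mask <- is.na(scores)
  if (any(na_mask)) {
    med <- apply(scores, 2, stats::median, na.rm = TRUE)
    for (j in seq_len(ncol(scores)))
      scores[na_mask[, j], j] <- med[j]
  }
  out <- limma::normalizeQuantiles(scores, ties = TRUE)
  dimnames(out) <- dimnames(scores)
  out[na_mask] <- NA
  out
}

# Moment-based inverse-gamma hyperpriors for batch variances (the standard
# parametric empirical-Bayes forms).
aprior <- function(d2) { m <- mean(d2); s2 <- stats::var(d2); (2 * s2 + m^2) / s2 }
bprior <- function(d2) { m <- mean(d2); s2 <- stats::var(d2); (m * s2 + m^3) / s2 }

#' Empirical-Bayes batch-effect adjustment of a score matrix
#'
#' Parametric empirical-Bayes location/scale batch adjustment: per gene the
#' matrix is standardized, per-batch gene-wise location and scale effects
#' are estimated and shrunk toward their batch-wide priors (normal prior on
#' locations, inverse-gamma on scales, hyperparameters by moments), the
#' shrunken effects are removed, and the per-gene grand location/scale is
#' restored exactly. A single batch is a no-op; a batch with one column
#' gets a location-only adjustment with a warning.
#'
#' @param scores Gene x cell-line matrix.
#' @param batches Named character vector mapping each column to a batch; if
#'   `NULL`, all columns are one batch (no-op).
#' @return Adjusted matrix of the same shape.
#' @export
batch_correct <- function(scores, batches = NULL) {
  if (is.null(batches)) batches <- stats::setNames(
    rep("batch1", ncol(scores)), colnames(scores))
  if (!all(colnames(scores) %in% names(batches)))
    stop_format("every column needs a batch assignment")
  batches <- batches[colnames(scores)]
  if (length(unique(batches)) < 2) return(scores)

  alpha <- rowMeans(scores)
  sigma <- sqrt(rowVars(scores))
  sigma[sigma == 0] <- 1
  Z <- (scores - alpha) / sigma
  Zadj <- Z

  for (b in unique(batches)) {
    cols <- which(batches == b)
    nb <- length(cols)
    Zb <- Z[, cols, drop = FALSE]
    gamma_hat <- rowMeans(Zb)
    if (nb < 2) {
      warning("batch '", b, "' has one column: location-only adjustment")
      Zadj[, cols] <- Zb - gamma_hat
      next
    }
    delta_hat <- rowVars(Zb)
    delta_hat[delta_hat == 0] <- 1e-8
    g_bar <- mean(gamma_hat); t2 <- stats::var(gamma_hat)
    a <- aprior(delta_hat); bp <- bprior(delta_hat)
    gamma_star <- gamma_hat; delta_star <- delta_hat
    for (it in 1:50) {
      g_new <- (nb * t2 * gamma_hat + delta_star * g_bar) /
               (nb * t2 + delta_star)
      ss <- rowSums((Zb - g_new)^2)
      d_new <- (bp + 0.5 * ss) / (nb / 2 + a - 1)
      if (max(abs(g_new - gamma_star), abs(d_new - delta_star)) < 1e-6) {
        gamma_star <- g_new; delta_star <- d_new; break
      }
      gamma_star <- g_new; delta_star <- d_new
    }
    Zadj[, cols] <- (Zb - gamma_star) / sqrt(delta_star)
  }
  out <- Zadj * sigma + alpha
  # restore per-gene grand mean exactly
  out <- out - rowMeans(out) + alpha
  dimnames(out) <- dimnames(scores)
  out
}

#' Counts to CRISPR scores in one call
#'
#' Runs the full scoring chain: median-ratio normalization, plasmid filter
#' and logFC computation, segmentation-based copy-number bias correction,
#' gene-level averaging, quantile normalization and (optionally) batch
#' adjustment.
#'
#' @inheritParams compute_logfc
#' @inheritParams correct_cn_bias
#' @param batches Optional column->batch map for [batch_correct()].
#' @param ct A raw [count_table()].
#' @return List with `scores` (gene x cell-line CRISPR score matrix),
#'   `logfc` (a `logfc_table` whose `logfc` element holds the
#'   bias-corrected sgRNA logFCs, with the uncorrected matrix kept in
#'   `logfc_uncorrected`), and the `segments` correction report.
#' @export
compute_crispr_scores <- function(ct, annotation, plasmid_min = 30,
                                  pseudocount = 0.5, min_genes = 3L,
                                  split_p = 0.01, batches = NULL) {
  norm <- median_ratio_normalize(ct)
  lfc  <- compute_logfc(norm, plasmid_min = plasmid_min,
                        pseudocount = pseudocount)
  corr <- correct_cn_bias(lfc$logfc, annotation, min_genes = min_genes,
                          split_p = split_p)
  scores <- gene_level_scores(corr$corrected, annotation)
  if (ncol(scores) >= 2) scores <- quantile_normalize(scores)
  scores <- batch_correct(scores, batches)
  lfc$logfc_uncorrected <- lfc$logfc
  lfc$logfc <- corr$corrected  # depletion tests run on corrected logFCs
  list(scores = scores, logfc = lfc, segments = corr$segments)
}
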