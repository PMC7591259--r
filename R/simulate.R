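# Synthetic-data generators with planted ground truth. These stand in for a
# deposited genome-wide knockout screen (sgRNA count tables over a cell-line
# panel) and matched expression cohorts, so that every downstream stage --
# normalization, bias correction, depletion testing, cataloguing, signature
# scoring -- can be validated against known truth.

#' Configuration for a simulated pooled CRISPR knockout screen
#'
#' Describes a screen of `n_genes` genes with `sgrnas_per_gene` guides each,
#' screened in `n_replicates` replicates (screens of this design are run in
#' triplicate) across `n_cell_lines` cell lines. A fraction of genes is
#' planted as essential: their guides deplete with mean log2 fold-change
#' `essential_lfc_shift`. Contiguous gene blocks can additionally carry a
#' copy-number-driven log-fold-change bias, emulating the gene-independent
#' depletion seen over amplified regions.
#'
#' @param n_genes Number of genes in the library.
#' @param n_cell_lines Number of screened cell lines.
#' @param sgrnas_per_gene Guides per gene (default 5).
#' @param n_replicates End-point replicates per cell line (default 3).
#' @param frac_essential Fraction of genes planted as essential, in `[0, 1]`.
#' @param essential_lfc_shift Mean log2 depletion of essential-gene guides
#'   (negative; default -2).
#' @param cn_segments List of planted copy-number segments, each a list with
#'   elements `chromosome`, `start_gene_index` (1-based index within that
#'   chromosome's gene order), `n_genes`, and `lfc_bias`.
#' @param depth Mean sequencing reads per sgRNA (default 500).
#' @param dispersion Negative-binomial overdispersion shared by all counts
#'   (variance = mu + dispersion * mu^2; default 0.05).
#' @param seed Integer seed; identical configs reproduce identical output.
#'
#' @return An object of class `screen_sim_config`.
#' @seealso [simulate_screen()]
#' @export
screen_sim_config <- function(n_genes, n_cell_lines, sgrnas_per_gene = 5L,
                              n_replicates = 3L, frac_essential = 0.1,
                              essential_lfc_shift = -2,
                              cn_segments = list(), depth = 500,
                              dispersion = 0.05, seed = 1L) {
  if (!is_count(n_genes) || !is_count(n_cell_lines) ||
      !is_count(sgrnas_per_gene) || !is_count(n_replicates))
    stop_config("n_genes, n_cell_lines, sgrnas_per_gene, n_replicates must be positive integers")
  if (!is.numeric(frac_essential) || frac_essential < 0 || frac_essential > 1)
    stop_config("frac_essential must lie in [0, 1]")
  if (!is.numeric(depth) || depth <= 0)
    stop_config("depth must be positive")
  if (!is.numeric(dispersion) || dispersion <= 0)
    stop_config("dispersion must be positive")
  for (seg in cn_segments) {
    need <- c("chromosome", "start_gene_index", "n_genes", "lfc_bias")
    if (!all(need %in% names(seg)))
      stop_config("each cn_segment needs fields: ", paste(need, collapse = ", "))
  }
  structure(list(
    n_genes = as.integer(n_genes), n_cell_lines = as.integer(n_cell_lines),
    sgrnas_per_gene = as.integer(sgrnas_per_gene),
    n_replicates = as.integer(n_replicates),
    frac_essential = frac_essential,
    essential_lfc_shift = essential_lfc_shift,
    cn_segments = cn_segments, depth = depth, dispersion = dispersion,
    seed = as.integer(seed)
  ), class = "screen_sim_config")
}

# Lay genes on 22 synthetic chromosomes in index order, unit spacing.
# Only the relative genomic ordering matters for segmentation-based
# correction, so positions are representative points, 1-based.
synthetic_library <- function(n_genes, sgrnas_per_gene) {
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  n_chrom  <- min(22L, n_genes)
  chrom_of <- rep(seq_len(n_chrom), length.out = n_genes)
  chrom_of <- sort(chrom_of)  # contiguous blocks per chromosome
  pos <- integer(n_genes)
  for (ch in seq_len(n_chrom)) {
    idx <- which(chrom_of == ch)
    pos[idx] <- seq_along(idx)
  }
  data.frame(
    sgrna_id  = paste0(rep(gene_ids, each = sgrnas_per_gene), "_sg",
                       rep(seq_len(sgrnas_per_gene), times = n_genes)),
    gene      = rep(gene_ids, each = sgrnas_per_gene),
    chromosome = paste0("chr", rep(chrom_of, each = sgrnas_per_gene)),
    position  = rep(pos, each = sgrnas_per_gene),
    stringsAsFactors = FALSE
  )
}

#' Simulate a pooled CRISPR knockout screen with planted ground truth
#'
#' Draws a plasmid library with log-normal sgRNA representation and, for each
#' cell line and replicate, end-point counts distributed negative-binomially
#' around the plasmid abundance scaled by `2^lfc`, where `lfc` combines the
#' planted essential-gene depletion (with per-guide efficacy noise, sd 0.2)
#' and any planted copy-number segment bias. The same planted essential set
#' is used for every cell line.
#'
#' @param config A [screen_sim_config()].
#' @return A list with components:
#'   \describe{
#'     \item{annotation}{Library annotation `data.frame` (`sgrna_id`, `gene`,
#'       `chromosome`, `position`).}
#'     \item{counts}{A [count_table()] with one `plasmid` column and
#'       `n_cell_lines * n_replicates` end-point columns.}
#'     \item{truth}{Planted ground truth: `essential_genes` (per cell line),
#'       `cn_biased_sgrnas`, `cn_segments` and the per-sgRNA true lfc matrix.}
#'   }
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_genes = 50, n_cell_lines = 2,
#'                                          seed = 7))
#' dim(sim$counts$counts)
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  with_seed(config$seed, {
    ann  <- synthetic_library(config$n_genes, config$sgrnas_per_gene)
    n_sg <- nrow(ann)
    genes <- unique(ann$gene)

    n_ess <- round(config$frac_essential * config$n_genes)
    essential <- sort(sample(genes, n_ess))

    # per-sgRNA planted log2 fold-change: essential shift + efficacy noise
    lfc <- numeric(n_sg)
    ess_sg <- ann$gene %in% essential
    lfc[ess_sg] <- config$essential_lfc_shift + stats::rnorm(sum(ess_sg), 0, 0.2)

    cn_sgrnas <- character(0)
    for (seg in config$cn_segments) {
      chrom <- if (grepl("^chr", seg$chromosome)) seg$chromosome
               else paste0("chr", seg$chromosome)
      chrom_genes <- unique(ann$gene[ann$chromosome == chrom])
      idx <- seq(seg$start_gene_index,
                 min(length(chrom_genes), seg$start_gene_index + seg$n_genes - 1L))
      hit <- ann$gene %in% chrom_genes[idx]
      lfc[hit] <- lfc[hit] + seg$lfc_bias
      cn_sgrnas <- union(cn_sgrnas, ann$sgrna_id[hit])
    }

    rel <- exp(stats::rnorm(n_sg, 0, 0.5))
    rel <- rel / mean(rel)
    size <- 1 / config$dispersion

    mu_plasmid <- config$depth * rel
    plasmid <- stats::rnbinom(n_sg, mu = mu_plasmid, size = size)

    n_cols <- config$n_cell_lines * config$n_replicates
    counts <- matrix(0L, n_sg, n_cols)
    cn_col <- character(n_cols); rep_col <- integer(n_cols); nm <- character(n_cols)
    j <- 0L
    for (cl in seq_len(config$n_cell_lines)) {
      mu_end <- mu_plasmid * 2^lfc
      for (r in seq_len(config$n_replicates)) {
        j <- j + 1L
        counts[, j] <- stats::rnbinom(n_sg, mu = mu_end, size = size)
        cn_col[j] <- sprintf("CL%02d", cl); rep_col[j] <- r
        nm[j] <- sprintf("CL%02d_R%d", cl, r)
      }
    }
    mat <- cbind(plasmid, counts)
    dimnames(mat) <- list(ann$sgrna_id, c("plasmid", nm))
    samples <- data.frame(
      sample_id = c("plasmid", nm),
      role      = c("plasmid", rep("endpoint", n_cols)),
      cell_line = c(NA, cn_col),
      replicate = c(NA, rep_col),
      batch     = "batch1",
      stringsAsFactors = FALSE
    )
    ct <- count_table(mat, samples)

    truth <- list(
      essential_genes = stats::setNames(
        rep(list(essential), config$n_cell_lines), unique(cn_col)),
      cn_biased_sgrnas = cn_sgrnas,
      cn_segments = config$cn_segments,
      sgrna_lfc = stats::setNames(lfc, ann$sgrna_id)
    )
    list(annotation = ann, counts = ct, truth = truth)
  })
}

#' Configuration for a simulated expression cohort with dependency groups
#'
#' Emulates an expression matrix over a cohort split into three sample
#' groups (e.g. dependency classes), each carrying a planted block of
#' up-regulated and a block of down-regulated genes, plus a binary mutation
#' label enriched in group 3.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param group_proportions Three fractions summing to 1.
#' @param n_deg_per_group Planted up-block size per group (an equally sized
#'   down-block is planted too, so `6 * n_deg_per_group <= n_genes`).
#' @param deg_effect Log2-scale mean shift of planted blocks (default 3).
#' @param noise_sd Log2-scale residual noise sd (default 0.5).
#' @param mutation_enrichment Odds multiplier linking the mutation label to
#'   group 3 (default 5; baseline mutation probability 0.2).
#' @param seed Integer seed.
#' @return An object of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_genes, n_samples,
                            group_proportions = c(1, 1, 1) / 3,
                            n_deg_per_group = 50L, deg_effect = 3,
                            noise_sd = 0.5, mutation_enrichment = 5,
                            seed = 1L) {
  if (!is_count(n_genes) || !is_count(n_samples))
    stop_config("n_genes and n_samples must be positive integers")
  if (length(group_proportions) != 3 || any(group_proportions < 0) ||
      abs(sum(group_proportions) - 1) > 1e-8)
    stop_config("group_proportions must be 3 non-negative fractions summing to 1")
  if (n_deg_per_group * 6 > n_genes)
    stop_config("6 * n_deg_per_group must not exceed n_genes")
  if (any(group_proportions == 0) && n_deg_per_group > 0)
    stop_config("a group with proportion 0 cannot carry planted DEGs")
  if (noise_sd < 0) stop_config("noise_sd must be non-negative")
  structure(list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    group_proportions = group_proportions,
    n_deg_per_group = as.integer(n_deg_per_group),
    deg_effect = deg_effect, noise_sd = noise_sd,
    mutation_enrichment = mutation_enrichment, seed = as.integer(seed)
  ), class = "expr_sim_config")
}

#' Simulate an expression cohort with three planted dependency groups
#'
#' Gene baselines are drawn log-normally (normal on the log2 scale); samples
#' of group g have `+deg_effect` added on that group's planted up-block and
#' `-deg_effect` on its down-block, before per-entry noise. Group sizes are
#' assigned deterministically by largest-remainder rounding of the
#' proportions, then shuffled under the seed. The returned matrix is on the
#' linear (FPKM-like) scale.
#'
#' @param config An [expr_sim_config()].
#' @return A list with `expr` (genes x samples, non-negative) and `truth`
#'   (`sample_groups`, `deg_blocks` per group with `up`/`down` gene sets,
#'   `mutated_samples`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expr_sim_config"))
  with_seed(config$seed, {
    sizes  <- largest_remainder(config$group_proportions, config$n_samples)
    groups <- sample(rep(seq_len(3), times = sizes))
    sample_ids <- sprintf("S%04d", seq_len(config$n_samples))
    names(groups) <- sample_ids

    gene_ids <- sprintf("G%05d", seq_len(config$n_genes))
    nd <- config$n_deg_per_group
    blocks <- list()
    pool <- if (nd > 0) sample(gene_ids, 6 * nd) else character(0)
    for (g in 1:3) {
      blocks[[g]] <- list(
        up   = sort(pool[seq_len(nd) + (g - 1) * 2 * nd]),
        down = sort(pool[seq_len(nd) + (g - 1) * 2 * nd + nd])
      )
    }
    names(blocks) <- paste0("group", 1:3)

    base <- stats::rnorm(config$n_genes, mean = 5, sd = 1.5)
    logx <- matrix(base, config$n_genes, config$n_samples)
    dimnames(logx) <- list(gene_ids, sample_ids)
    for (g in 1:3) {
      cols <- which(groups == g)
      if (!length(cols)) next
      logx[blocks[[g]]$up, cols]   <- logx[blocks[[g]]$up, cols]   + config$deg_effect
      logx[blocks[[g]]$down, cols] <- logx[blocks[[g]]$down, cols] - config$deg_effect
    }
    logx <- logx + matrix(stats::rnorm(length(logx), 0, config$noise_sd),
                          nrow(logx), ncol(logx))
    expr <- 2^logx

    base_odds <- 0.2 / 0.8
    odds <- ifelse(groups == 3, base_odds * config$mutation_enrichment, base_odds)
    mutated <- sample_ids[stats::runif(config$n_samples) < odds / (1 + odds)]

    list(expr = expr,
         truth = list(sample_groups = groups, deg_blocks = blocks,
                      mutated_samples = mutated))
  })
}
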