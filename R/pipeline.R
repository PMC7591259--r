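# End-to-end orchestration: simulate -> screen -> depletion test ->
# catalogue -> signature -> enrichment, with a reproducibility manifest.

#' Pipeline configuration
#'
#' Collects every stage's parameters and toggles in one place. A single
#' global `seed` fans out to per-stage seeds as `seed + 101 * stage_index`
#' (stage order: simulate = 1, screen = 2, test = 3, catalog = 4,
#' signature = 5, enrich = 6), so stages draw from independent,
#' individually reproducible streams.
#'
#' @param seed Global integer seed.
#' @param stages Character vector of stages to run (subset of the order
#'   above).
#' @param screen_config A [screen_sim_config()] for the simulate stage
#'   (its own `seed` field is overridden by the fanned-out stage seed).
#' @param expr_config An [expr_sim_config()] for the signature stage.
#' @param pseudocount,plasmid_min,min_genes,split_p Screen-stage knobs, see
#'   [compute_crispr_scores()].
#' @param alpha,n_perm,fdr_cut Depletion-test knobs, see [rra_gene_test()].
#' @param fpkm_cut Expression-plausibility cutoff (default 0.5, strict).
#' @param core_genes Optional character vector of core-fitness genes to
#'   remove in the catalog stage.
#' @param deg_p_cut,deg_lfc_cut,core_cut Signature-stage thresholds, see
#'   [derive_degs()] and [classify_samples()].
#' @param tau ssGSEA rank-weight exponent.
#' @param batches Optional column->batch map for [batch_correct()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c("simulate", "screen", "test",
                                       "catalog", "signature", "enrich"),
                            screen_config = NULL, expr_config = NULL,
                            pseudocount = 0.5, plasmid_min = 30,
                            min_genes = 3L, split_p = 0.01,
                            alpha = 0.5, n_perm = 2000L, fdr_cut = 0.05,
                            fpkm_cut = 0.5, core_genes = NULL,
                            deg_p_cut = 0.01, deg_lfc_cut = 2,
                            core_cut = 0.5, tau = 0.25, batches = NULL) {
  known <- c("simulate", "screen", "test", "catalog", "signature", "enrich")
  if (!all(stages %in% known))
    stop_config("unknown stages: ", paste(setdiff(stages, known), collapse = ", "))
  for (v in c(pseudocount, plasmid_min, alpha, n_perm, fdr_cut, fpkm_cut,
              deg_p_cut, deg_lfc_cut, core_cut, tau))
    if (!is.numeric(v) || v < 0) stop_config("thresholds must be non-negative")
  structure(as.list(environment()), class = "pipeline_config")
}

stage_seed <- function(config, stage) {
  order <- c(simulate = 1L, screen = 2L, test = 3L, catalog = 4L,
             signature = 5L, enrich = 6L)
  as.integer(config$seed + 101L * order[[stage]])
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in dependency order on simulated inputs,
#' writes every stage's outputs under `out_dir`, and records a manifest
#' (`manifest.json`) with the config echo, fanned-out seeds, per-stage row
#' counts and an md5 hash of every output file. Reruns with the same
#' config reproduce all stochastic stages bit-exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (a list; also written as JSON).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  manifest <- list(
    config = config[setdiff(names(config), c("screen_config", "expr_config"))],
    seeds = list(), counts = list(), outputs = list(), skipped = list())
  outputs <- character(0)
  state <- list()

  if ("simulate" %in% stages) {
    sc <- config$screen_config %||%
      screen_sim_config(n_genes = 400, n_cell_lines = 4)
    sc$seed <- stage_seed(config, "simulate")
    manifest$seeds$simulate <- sc$seed
    sim <- simulate_screen(sc)
    state$sim <- sim
    f <- file.path(out_dir, "counts.tsv")
    write_results(cbind(data.frame(sgrna_id = rownames(sim$counts$counts)),
                        as.data.frame(sim$counts$counts)), f)
    outputs <- c(outputs, f)
    f <- file.path(out_dir, "library.tsv")
    write_results(sim$annotation, f); outputs <- c(outputs, f)
    f <- file.path(out_dir, "truth.json")
    write_results(list(essential_genes = sim$truth$essential_genes,
                       cn_biased_sgrnas = sim$truth$cn_biased_sgrnas), f)
    outputs <- c(outputs, f)
    manifest$counts$simulate <- nrow(sim$counts$counts)
  } else manifest$skipped$simulate <- TRUE

  if ("screen" %in% stages) {
    if (is.null(state$sim)) stop_config("screen stage needs the simulate stage")
    res <- compute_crispr_scores(
      state$sim$counts, state$sim$annotation,
      plasmid_min = config$plasmid_min, pseudocount = config$pseudocount,
      min_genes = config$min_genes, split_p = config$split_p,
      batches = config$batches)
    state$scores <- res$scores
    state$logfc <- res$logfc
    f <- file.path(out_dir, "crispr_scores.tsv")
    write_results(res$scores, f); outputs <- c(outputs, f)
    f <- file.path(out_dir, "segments.tsv")
    write_results(res$segments, f); outputs <- c(outputs, f)
    manifest$counts$screen <- nrow(res$scores)
  } else manifest$skipped$screen <- TRUE

  if ("test" %in% stages) {
    if (is.null(state$logfc)) stop_config("test stage needs the screen stage")
    manifest$seeds$test <- stage_seed(config, "test")
    stats_df <- rra_test_matrix(state$logfc, state$sim$annotation,
                                alpha = config$alpha, n_perm = config$n_perm,
                                seed = manifest$seeds$test,
                                fdr_cut = config$fdr_cut)
    state$gene_stats <- stats_df
    f <- file.path(out_dir, "gene_stats.tsv")
    write_results(stats_df, f); outputs <- c(outputs, f)
    manifest$counts$test <- nrow(stats_df)
  } else manifest$skipped$test <- TRUE

  if ("catalog" %in% stages) {
    if (is.null(state$gene_stats)) stop_config("catalog stage needs the test stage")
    cat0 <- catalog_from_results(state$gene_stats)
    hits <- cat0$hits
    if (!is.null(config$core_genes))
      hits <- remove_core_fitness(hits, config$core_genes)$catalog$hits
    catal <- fitness_catalog(hits)
    part <- recurrence_partition(catal)
    state$catalog <- catal
    f <- file.path(out_dir, "catalog.json")
    write_results(list(hits = catal$hits, union = catal$union,
                       unique = part$unique, recurrent = part$recurrent,
                       histogram = as.list(part$histogram)), f)
    outputs <- c(outputs, f)
    manifest$counts$catalog <- length(catal$union)
  } else manifest$skipped$catalog <- TRUE

  if ("signature" %in% stages) {
    ec <- config$expr_config %||%
      expr_sim_config(n_genes = 600, n_samples = 60, n_deg_per_group = 25)
    ec$seed <- stage_seed(config, "signature")
    manifest$seeds$signature <- ec$seed
    esim <- simulate_expression(ec)
    state$esim <- esim
    sig <- derive_degs(esim$expr, esim$truth$sample_groups,
                       p_cut = config$deg_p_cut, lfc_cut = config$deg_lfc_cut)
    z <- zscore_genes(log2(esim$expr + 1))
    sc <- classify_samples(signature_scores(z, sig), core_cut = config$core_cut)
    state$signature_scores <- sc
    f <- file.path(out_dir, "signature_scores.tsv")
    write_results(sc, f); outputs <- c(outputs, f)
    manifest$counts$signature <- nrow(sc)
  } else manifest$skipped$signature <- TRUE

  if ("enrich" %in% stages) {
    if (is.null(state$esim)) stop_config("enrich stage needs the signature stage")
    manifest$seeds$enrich <- stage_seed(config, "enrich")
    sets <- lapply(state$esim$truth$deg_blocks, function(b) b$up)
    names(sets) <- paste0(names(sets), "_up")
    es <- ssgsea_matrix(state$esim$expr, sets, tau = config$tau)
    f <- file.path(out_dir, "ssgsea_scores.tsv")
    write_results(es, f); outputs <- c(outputs, f)
    manifest$counts$enrich <- nrow(es)
  } else manifest$skipped$enrich <- TRUE

  manifest$outputs <- as.list(tools::md5sum(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
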