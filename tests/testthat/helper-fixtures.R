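# Shared fixture builders: all fixtures are generated in code.

# Minimal annotation: n_genes genes with k sgRNAs each on one chromosome.
tiny_annotation <- function(n_genes = 3, k = 2, chromosome = "chr1") {
  genes <- sprintf("G%03d", seq_len(n_genes))
  data.frame(
    sgrna_id = paste0(rep(genes, each = k), "_sg", rep(seq_len(k), n_genes)),
    gene = rep(genes, each = k),
    chromosome = chromosome,
    position = rep(seq_len(n_genes), each = k),
    stringsAsFactors = FALSE
  )
}

# Count table with a plasmid column and one endpoint column per cell line
# and replicate, from a matrix of endpoint counts.
tiny_count_table <- function(plasmid, endpoints, cell_lines, replicates) {
  mat <- cbind(plasmid = plasmid, endpoints)
  nm <- paste0(cell_lines, "_R", replicates)
  colnames(mat) <- c("plasmid", nm)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("sg", seq_len(nrow(mat)))
  samples <- data.frame(
    sample_id = colnames(mat),
    role = c("plasmid", rep("endpoint", length(nm))),
    cell_line = c(NA, cell_lines),
    replicate = c(NA, replicates),
    batch = "batch1", stringsAsFactors = FALSE)
  count_table(mat, samples)
}

write_tsv_fixture <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile(tmpdir = dir, fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Brute-force BH step-up: q_(i) = min_{j >= i} p_(j) * n / j, mapped back
# to the original order. Independent of stats::p.adjust.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) q[i] <- min(pmin(ps[i:n] * n / (i:n), 1))
  out <- numeric(n)
  out[o] <- q
  out
}

# Exact Fisher by full enumeration over the hypergeometric support.
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  list(greater = sum(probs[support >= a]),
       less = sum(probs[support <= a]),
       two_sided = sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Brute-force weighted running sum for enrichment scores (integral form).
running_sum_oracle <- function(ord_genes, set, tau) {
  N <- length(ord_genes)
  hit <- ord_genes %in% set
  w <- (N:1)^tau
  run <- numeric(N); cur <- 0
  for (i in seq_len(N)) {
    cur <- cur + if (hit[i]) w[i] / sum(w[hit]) else -1 / (N - sum(hit))
    run[i] <- cur
  }
  run
}
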