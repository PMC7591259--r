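# Counts -> logFC -> bias correction -> CRISPR scores.

test_that("median-ratio size factors follow the geometric-mean reference", {
  ct <- tiny_count_table(plasmid = c(10L, 20L, 30L, 40L),
                         endpoints = matrix(c(20L, 40L, 60L, 80L), ncol = 1),
                         cell_lines = "A", replicates = 1L)
  rownames(ct$counts) <- paste0("sg", 1:4)
  norm <- median_ratio_normalize(ct)
  sf <- attr(norm$counts, "size_factors")
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(norm$counts[, 1], norm$counts[, 2])
})

test_that("median-ratio normalization is symmetric and idempotent", {
  set.seed(1)
  base <- as.integer(rpois(50, 100)) + 1L
  ct <- tiny_count_table(plasmid = base,
                         endpoints = cbind(base, as.integer(base * 3L)),
                         cell_lines = c("A", "A"), replicates = 1:2)
  rownames(ct$counts) <- paste0("sg", 1:50)
  norm <- median_ratio_normalize(ct)
  # identical columns share one size factor and change only by a constant
  sf <- attr(norm$counts, "size_factors")
  expect_equal(unname(sf["plasmid"]), unname(sf["A_R1"]))
  expect_equal(norm$counts[, "plasmid"] / ct$counts[, "plasmid"],
               rep(unname(1 / sf["plasmid"]), 50), ignore_attr = TRUE)
  # applying twice equals applying once (size factors become 1)
  again <- median_ratio_normalize(norm)
  expect_equal(again$counts, norm$counts, ignore_attr = TRUE)
  expect_equal(unname(attr(again$counts, "size_factors")), rep(1, 3),
               tolerance = 1e-12)

  zero <- ct; zero$counts[, 1] <- 0L
  expect_error(median_ratio_normalize(zero), "all-positive")
})

test_that("size factors agree with the DESeq2 median-of-ratios estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(7)
  mat <- matrix(as.integer(rpois(300, lambda = rep(c(50, 100, 200), each = 100))),
                ncol = 3, dimnames = list(paste0("sg", 1:100), c("plasmid", "A_R1", "A_R2")))
  ct <- count_table(mat, data.frame(
    sample_id = colnames(mat), role = c("plasmid", "endpoint", "endpoint"),
    cell_line = c(NA, "A", "A"), replicate = c(NA, 1, 2)))
  sf <- attr(median_ratio_normalize(ct)$counts, "size_factors")
  ref <- DESeq2::estimateSizeFactorsForMatrix(mat)
  expect_equal(unname(sf / ref), rep(unname(sf[1] / ref[1]), 3),
               tolerance = 1e-6)
})

test_that("logFC matches hand arithmetic and applies the plasmid filter", {
  ann <- tiny_annotation(n_genes = 2, k = 2)
  ct <- count_table(
    matrix(c(100L, 29L, 50L, 200L,
             50L, 10L, 50L, 200L), ncol = 2,
           dimnames = list(ann$sgrna_id, c("plasmid", "A_R1"))),
    data.frame(sample_id = c("plasmid", "A_R1"),
               role = c("plasmid", "endpoint"),
               cell_line = c(NA, "A"), replicate = c(NA, 1)))
  lfc <- compute_logfc(ct, plasmid_min = 30, pseudocount = 0.5)
  # raw plasmid 29 excluded before computation
  expect_false(ann$sgrna_id[2] %in% rownames(lfc$logfc))
  expect_identical(lfc$n_filtered, 1L)
  # log2((50 + 0.5) / (100 + 0.5))
  expect_equal(lfc$logfc[ann$sgrna_id[1], "A"], log2(50.5 / 100.5))
  # endpoint == plasmid -> logFC 0
  expect_equal(unname(lfc$logfc[ann$sgrna_id[3:4], "A"]), c(0, 0))

  expect_error(compute_logfc(ct, plasmid_min = 1000), "plasmid filter")
})

test_that("replicate correlations hit the exact and null benchmarks", {
  set.seed(2)
  x <- rnorm(10000)
  mat <- cbind(A_R1 = x, A_R2 = x, A_R3 = rnorm(10000), B_R1 = x, B_R2 = -x)
  samples <- data.frame(sample_id = colnames(mat),
                        cell_line = c("A", "A", "A", "B", "B"),
                        replicate = c(1, 2, 3, 1, 2))
  rc <- replicate_correlation(mat, samples)
  expect_equal(rc$pearson_r[rc$rep_a == "A_R1" & rc$rep_b == "A_R2"], 1)
  expect_equal(rc$pearson_r[rc$cell_line == "B"], -1)
  # independent noise: |r| below the null envelope at n = 10,000
  expect_lt(max(abs(rc$pearson_r[rc$rep_b == "A_R3"])), 0.05)
  # constant replicate -> missing
  mat2 <- cbind(A_R1 = rep(1, 5), A_R2 = rnorm(5))
  rc2 <- replicate_correlation(mat2, samples[1:2, ])
  expect_true(is.na(rc2$pearson_r))
})

test_that("bias correction leaves flat data alone and flattens planted blocks", {
  set.seed(3)
  ann <- tiny_annotation(n_genes = 40, k = 3)
  lfc <- matrix(rnorm(120, 0, 0.1), ncol = 1,
                dimnames = list(ann$sgrna_id, "A"))
  out <- correct_cn_bias(lfc, ann)
  expect_equal(out$corrected, lfc)
  expect_identical(nrow(out$segments), 0L)

  # planted 10-gene block at -1: recovered and flattened
  blk_genes <- sprintf("G%03d", 11:20)
  blk <- ann$gene %in% blk_genes
  lfc2 <- lfc; lfc2[blk, 1] <- lfc2[blk, 1] - 1
  out2 <- correct_cn_bias(lfc2, ann)
  expect_gt(nrow(out2$segments), 0)
  expect_lt(abs(mean(out2$corrected[blk, 1])), 0.1)

  # 2-gene deviating block is below the minimum segment width
  lfc3 <- lfc; lfc3[ann$gene %in% c("G005", "G006"), 1] <- -3
  out3 <- correct_cn_bias(lfc3, ann, min_genes = 3)
  expect_equal(out3$corrected[ann$gene == "G005", 1],
               lfc3[ann$gene == "G005", 1])

  expect_error(correct_cn_bias(lfc, ann[-1, ]), "missing")
})

test_that("correction conserves the genome-wide mean up to corrected-segment mass", {
  set.seed(4)
  ann <- tiny_annotation(n_genes = 60, k = 3)
  lfc <- matrix(rnorm(180, 0, 0.1), ncol = 1,
                dimnames = list(ann$sgrna_id, "A"))
  lfc[ann$gene %in% sprintf("G%03d", 21:32), 1] <- -1.5
  out <- correct_cn_bias(lfc, ann)
  mass <- sum(abs(out$segments$mean_lfc) * out$segments$n_genes) /
    length(unique(ann$gene))
  expect_lte(abs(mean(out$corrected) - mean(lfc)), mass + 1e-12)
})

test_that("gene scores are sgRNA means", {
  ann <- tiny_annotation(n_genes = 2, k = 3)
  lfc <- matrix(c(-1, -2, -3, 5, 5, 5), ncol = 1,
                dimnames = list(ann$sgrna_id, "A"))
  sc <- gene_level_scores(lfc, ann)
  expect_equal(sc["G001", "A"], -2)
  # single-sgRNA gene passes through
  sc2 <- gene_level_scores(lfc[1:4, , drop = FALSE], ann)
  expect_equal(sc2["G002", "A"], 5)
  # fully filtered gene is reported missing
  expect_message(sc3 <- gene_level_scores(lfc[1:3, , drop = FALSE], ann),
                 "no score")
  expect_false("G002" %in% rownames(sc3))
})

test_that("quantile normalization equalizes column distributions", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("x", "y")))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "x"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, "y"]), c(2.5, 3.5, 4.5))

  set.seed(5)
  r <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("g", 1:20), paste0("c", 1:3)))
  qn2 <- quantile_normalize(r)
  # identical sorted values in all columns; idempotent; column-permutation equivariant
  expect_equal(sort(qn2[, 1]), sort(qn2[, 2]), ignore_attr = TRUE)
  expect_equal(quantile_normalize(qn2), qn2)
  perm <- c(3, 1, 2)
  expect_equal(quantile_normalize(r[, perm]), qn2[, perm])
  # identical columns unchanged
  same <- r[, c(1, 1)]; colnames(same) <- c("c1", "c2")
  expect_equal(quantile_normalize(same), same)
  expect_warning(quantile_normalize(r[, 1, drop = FALSE]), "single|>= 2")
})

test_that("batch adjustment removes planted batch shifts and keeps gene means", {
  set.seed(6)
  n_gene <- 80; n_col <- 50
  batches <- setNames(rep(c("b1", "b2"), length.out = n_col),
                      paste0("CL", seq_len(n_col)))
  shift <- 2
  m <- matrix(rnorm(n_gene * n_col), n_gene, n_col,
              dimnames = list(paste0("g", seq_len(n_gene)), names(batches)))
  m[, batches == "b2"] <- m[, batches == "b2"] + shift
  adj <- batch_correct(m, batches)
  delta <- rowMeans(adj[, batches == "b1"]) - rowMeans(adj[, batches == "b2"])
  # the planted systematic shift (2) is gone up to estimation noise
  expect_lt(abs(mean(delta)), 0.1)
  expect_lt(mean(abs(delta)), 0.5)
  expect_equal(rowMeans(adj), rowMeans(m), tolerance = 1e-8)
  # single batch is a no-op
  expect_identical(batch_correct(m), m)
  # batch of one column: location-only with warning
  expect_warning(batch_correct(m[, 1:3],
                               setNames(c("b1", "b1", "b2"), colnames(m)[1:3])),
                 "one column")
})

test_that("batch adjustment agrees with the reference ComBat implementation", {
  skip_if_not_installed("sva")
  set.seed(8)
  n_gene <- 60; n_col <- 24
  batches <- setNames(rep(c("b1", "b2"), each = n_col / 2),
                      paste0("CL", seq_len(n_col)))
  m <- matrix(rnorm(n_gene * n_col, sd = 1), n_gene, n_col,
              dimnames = list(paste0("g", seq_len(n_gene)), names(batches)))
  m <- m + outer(rnorm(n_gene, 0, 0.5), ifelse(batches == "b2", 1.5, 0))
  adj <- batch_correct(m, batches)
  ref <- suppressMessages(sva::ComBat(m, batch = batches))
  expect_gt(cor(as.vector(adj), as.vector(ref)), 0.98)
})
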