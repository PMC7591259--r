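# DEG signatures, Z-scores, signature scoring, classification, clustering,
# and the elementary statistical tests.

test_that("null expression yields (almost) no DEGs across seeds", {
  counts <- vapply(1:20, function(s) {
    sim <- simulate_expression(expr_sim_config(n_genes = 200, n_samples = 30,
                                               n_deg_per_group = 10,
                                               deg_effect = 0, seed = s))
    sig <- derive_degs(sim$expr, sim$truth$sample_groups)
    sum(lengths(lapply(sig$groups, unlist)))
  }, numeric(1))
  # with no planted effect, the |logFC| > 2 gate alone should kill nearly
  # everything; allow at most the nominal p_cut budget per tail
  expect_lte(mean(counts), 200 * 0.01 * 2)
})

test_that("planted DEG blocks are recovered in the correct direction", {
  sim <- simulate_expression(expr_sim_config(n_genes = 400, n_samples = 60,
                                             n_deg_per_group = 25,
                                             deg_effect = 3, noise_sd = 0.5,
                                             seed = 21))
  sig <- derive_degs(sim$expr, sim$truth$sample_groups)
  for (g in 1:3) {
    truth <- sim$truth$deg_blocks[[g]]
    found <- sig$groups[[as.character(g)]]
    expect_gte(mean(truth$up %in% found$up), 0.9)
    expect_gte(mean(truth$down %in% found$down), 0.9)
  }
})

test_that("genes passing in two groups are dropped by the exclusivity pass", {
  set.seed(22)
  n <- 30
  labels <- setNames(rep(c("1", "2", "3"), each = 10), paste0("S", 1:n))
  expr <- matrix(2^rnorm(100 * n, 5, 0.2), 100, n,
                 dimnames = list(sprintf("G%03d", 1:100), names(labels)))
  # G001 is up in group 1 and down in group 2 -> passes in both -> dropped
  expr["G001", labels == "1"] <- 2^7.5
  expr["G001", labels == "2"] <- 2^2.5
  # G002 is high only in group 1 -> kept
  expr["G002", labels == "1"] <- 2^8
  sig <- derive_degs(expr, labels)
  expect_false("G001" %in% unlist(sig$groups))
  expect_true("G002" %in% sig$groups[["1"]]$up)
  expect_error(derive_degs(expr, setNames(c("1", rep("2", n - 1)), names(labels))),
               class = "osccfitness_config_error")
})

test_that("moderated test agrees with the limma reference on simulated data", {
  skip_if_not_installed("limma")
  sim <- simulate_expression(expr_sim_config(n_genes = 300, n_samples = 30,
                                             n_deg_per_group = 15,
                                             deg_effect = 1.5, seed = 23))
  logx <- log2(sim$expr + 1)
  in_g <- sim$truth$sample_groups[colnames(logx)] == 1
  mine <- osccfitness:::moderated_t(logx, in_g)
  design <- cbind(1, as.numeric(in_g))
  fit <- limma::eBayes(limma::lmFit(logx, design))
  expect_equal(mine$logfc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_gt(cor(-log10(mine$p), -log10(fit$p.value[, 2])), 0.98)
})

test_that("Z-scores standardize genes with the sample SD", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(4, 4, 4))
  colnames(m) <- paste0("s", 1:3)
  z <- zscore_genes(m)
  expect_equal(unname(z["g1", ]), c(-1, 0, 1))
  expect_equal(unname(z["g2", ]), c(0, 0, 0))
  expect_equal(unname(rowMeans(z)["g1"]), 0)
  expect_equal(sd(z["g1", ]), 1)
  expect_error(zscore_genes(m[, 1, drop = FALSE]), ">= 2")
})

test_that("signature scores are up-mean minus down-mean with stated edge rules", {
  z <- rbind(U1 = c(a = 1), U2 = c(a = 2), D1 = c(a = -1), D2 = c(a = 0))
  sig <- structure(list(groups = list(Y = list(up = c("U1", "U2"),
                                               down = c("D1", "D2"))),
                        p_cut = 0.01, lfc_cut = 2), class = "deg_signature")
  expect_equal(unname(signature_score(z, sig, "Y")), 1.5 - (-0.5))
  # all-zero Z -> 0; constant sample shift cancels
  z0 <- z; z0[] <- 0
  expect_equal(unname(signature_score(z0, sig, "Y")), 0)
  expect_equal(unname(signature_score(z + 3, sig, "Y")),
               unname(signature_score(z, sig, "Y")))
  # antisymmetric under swapping up/down
  swap <- sig; swap$groups$Y <- list(up = sig$groups$Y$down,
                                     down = sig$groups$Y$up)
  expect_equal(unname(signature_score(z, swap, "Y")),
               -unname(signature_score(z, sig, "Y")))
  # empty side after intersection is an error
  gone <- sig; gone$groups$Y$up <- "ABSENT"
  expect_error(suppressMessages(signature_score(z, gone, "Y")), "empty up or down")
})

test_that("classification follows the strict cutoff and the tie rule", {
  sc <- data.frame(sample = c("s1", "s2", "s3"),
                   Y = c(0.6, 0.5, 0.7), W = c(0.2, 0.4, 0.7),
                   C = c(0.1, 0.3, 0.1), check.names = FALSE)
  out <- classify_samples(sc, core_cut = 0.5)
  expect_identical(out$class, c("Y", "unclassified", "unclassified"))
  expect_identical(out$core, c(TRUE, FALSE, FALSE))
  expect_identical(out$tie, c(FALSE, FALSE, TRUE))
  expect_error(classify_samples(transform(sc, Y = NA)), "missing")
})

test_that("clustering recovers planted groups and is permutation invariant", {
  skip_if_not_installed("mclust")
  sim <- simulate_expression(expr_sim_config(n_genes = 400, n_samples = 60,
                                             n_deg_per_group = 25,
                                             deg_effect = 3, seed = 24))
  sig <- derive_degs(sim$expr, sim$truth$sample_groups)
  z <- zscore_genes(log2(sim$expr + 1))
  sc <- signature_scores(z, sig)
  cl <- cluster_samples(sc, k = 3)
  ari <- mclust::adjustedRandIndex(cl$cluster[sc$sample],
                                   sim$truth$sample_groups[sc$sample])
  expect_gte(ari, 0.9)
  # permuting input order preserves merge heights; duplicates merge at 0
  perm <- sc[sample(nrow(sc)), ]
  expect_equal(sort(cluster_samples(perm)$hclust$height),
               sort(cl$hclust$height))
  dup <- rbind(sc, sc[1, ])
  dup$sample[nrow(dup)] <- "dup"
  expect_equal(min(cluster_samples(dup)$hclust$height), 0)
})

test_that("Welch test matches hand computation and a permutation oracle", {
  res <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3 / sqrt(2 / 3))  # = -3.674
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-3 / sqrt(2 / 3), 4))
  expect_equal(welch_t(c(2, 2), c(2, 2)), list(t = 0, df = NA_real_, p = 1))

  set.seed(25)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(12, mean = runif(1, 0, 1.5))
    obs <- abs(welch_t(a, b)$t)
    pooled <- c(a, b)
    perm <- replicate(400, {
      idx <- sample(20, 8)
      abs(welch_t(pooled[idx], pooled[-idx])$t)
    })
    p_perm <- mean(perm >= obs)
    p_exact <- welch_t(a, b)$p
    mc_sd <- sqrt(p_perm * (1 - p_perm) / 400)
    expect_lt(abs(p_perm - p_exact), 4 * mc_sd + 0.02)
  }
})

test_that("Pearson p matches the t transform and a permutation oracle", {
  expect_equal(pearson_with_p(1:5, 2 * (1:5))$r, 1)
  # closed form at r = -0.934, n = 7
  r <- -0.934; n <- 7
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  x <- 1:7
  # build y achieving exactly r = -0.934 via orthogonal mixing
  set.seed(27)
  e <- residuals(lm(rnorm(7) ~ x))
  y <- r * scale(x)[, 1] + sqrt(1 - r^2) * scale(e)[, 1]
  res <- pearson_with_p(x, y)
  expect_equal(res$r, r, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(t), n - 2), tolerance = 1e-10)
  expect_equal(round(res$p, 4), 0.0021)

  set.seed(26)
  x2 <- rnorm(20); y2 <- x2 * 0.5 + rnorm(20)
  obs <- abs(pearson_with_p(x2, y2)$r)
  perm <- replicate(1000, abs(cor(x2, sample(y2))))
  p_perm <- mean(perm >= obs)
  expect_lt(abs(p_perm - pearson_with_p(x2, y2)$p), 0.05)
  expect_warning(pearson_with_p(rep(1, 5), rnorm(5)), "constant")
})
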