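test_that("simulated genotypes respect the configured design", {
  g <- simulate_genotypes(n_samples = 120, n_genes = 2, snps_per_gene = 40,
                          maf_range = c(0.2, 0.4), block_size_mean = 5,
                          within_block_r = 0.8, seed = 7)
  expect_equal(dim(g$dosages), c(120L, 80L))
  expect_invisible(validate_genotype_matrix(g, post_qc = TRUE))
  expect_true(all(g$dosages %in% 0:2))
  # blocks partition the SNPs and never span genes
  expect_false(anyNA(g$snp_info$block))
  spans <- tapply(g$snp_info$chrom, g$snp_info$block,
                  function(x) length(unique(x)))
  expect_true(all(spans == 1))
  # determinism under the seed
  g2 <- simulate_genotypes(n_samples = 120, n_genes = 2, snps_per_gene = 40,
                           maf_range = c(0.2, 0.4), block_size_mean = 5,
                           within_block_r = 0.8, seed = 7)
  expect_identical(g$dosages, g2$dosages)
  expect_identical(g$snp_info, g2$snp_info)
  expect_error(simulate_genotypes(within_block_r = 1), "within_block_r")
})

test_that("within-block correlation tracks the copula parameter", {
  n <- 250
  block_cors <- function(g) {
    unlist(lapply(split(seq_len(ncol(g$dosages)), g$snp_info$block),
                  function(ix) {
                    if (length(ix) < 2) return(NULL)
                    cc <- cor(g$dosages[, ix])
                    cc[upper.tri(cc)]
                  }))
  }
  g0 <- simulate_genotypes(n_samples = n, n_genes = 1, snps_per_gene = 60,
                           block_size_mean = 6, within_block_r = 0,
                           seed = 13)
  expect_lt(mean(abs(block_cors(g0))), 3 / sqrt(n))
  g9 <- simulate_genotypes(n_samples = n, n_genes = 1, snps_per_gene = 60,
                           block_size_mean = 6, within_block_r = 0.9,
                           seed = 13)
  expect_gt(mean(block_cors(g9)), 0.5)
})

test_that("regulator assignment draws the exact configured count", {
  g <- simulate_genotypes(n_samples = 40, n_genes = 1, snps_per_gene = 400,
                          seed = 2)
  flags <- assign_regulators(g, 0.05, seed = 3)
  expect_equal(sum(flags), round(0.05 * 400))
  expect_named(flags, g$snp_info$snp_id)
  expect_error(assign_regulators(g, 1.0), "open interval")
  expect_error(assign_regulators(g, 1e-6), "no regulator loci")
  # different seeds give different draws
  flags2 <- assign_regulators(g, 0.05, seed = 4)
  expect_false(identical(flags, flags2))
})

test_that("expression noise is calibrated exactly to the target r2", {
  g <- simulate_genotypes(n_samples = 150, n_genes = 3, snps_per_gene = 50,
                          seed = 5)
  flags <- assign_regulators(g, 0.1, seed = 5)
  sim <- simulate_expression(g, flags, r2_dist = function(n) rep(0.5, n),
                             seed = 6)
  # at target r2 = 0.5, noise_sd = sqrt(var(predictor)) exactly
  xstd <- scale(g$dosages)
  for (j in 1:3) {
    tr <- sim$truth$regulators[sim$truth$regulators$gene_id ==
                                 sim$truth$genes$gene_id[j], ]
    pred <- xstd[, match(tr$snp_id, g$snp_info$snp_id), drop = FALSE] %*%
      tr$effect
    expect_equal(sim$truth$genes$noise_sd[j], sqrt(var(pred)[1]),
                 tolerance = 1e-10)
  }
  # truth invariants: causal SNPs are flagged, effects nonzero
  expect_true(all(flags[sim$truth$regulators$snp_id]))
  expect_true(all(sim$truth$regulators$effect != 0))
  # determinism
  sim2 <- simulate_expression(g, flags, r2_dist = function(n) rep(0.5, n),
                              seed = 6)
  expect_identical(sim$expression$values, sim2$expression$values)
  expect_identical(sim$truth$regulators, sim2$truth$regulators)
})

test_that("realized explained variance averages to the target", {
  g <- simulate_genotypes(n_samples = 200, n_genes = 30, snps_per_gene = 40,
                          seed = 8)
  flags <- assign_regulators(g, 0.15, seed = 8)
  sim <- suppressWarnings(simulate_expression(g, flags, seed = 9))
  xstd <- scale(g$dosages)
  r2 <- vapply(seq_len(30), function(j) {
    tr <- sim$truth$regulators[sim$truth$regulators$gene_id ==
                                 sim$truth$genes$gene_id[j], ]
    pred <- xstd[, match(tr$snp_id, g$snp_info$snp_id), drop = FALSE] %*%
      tr$effect
    summary(lm(sim$expression$values[j, ] ~ pred))$r.squared
  }, numeric(1))
  expect_lt(abs(mean(r2) - mean(sim$truth$genes$target_r2)), 0.05)
})

test_that("per-gene causal counts follow the configured distribution", {
  g <- simulate_genotypes(n_samples = 50, n_genes = 200, snps_per_gene = 60,
                          seed = 10)
  flags <- assign_regulators(g, 0.15, seed = 10)
  sim <- suppressWarnings(simulate_expression(g, flags, seed = 11))
  counts <- table(factor(
    pmin(table(sim$truth$regulators$gene_id), 5), levels = 1:5))
  pk <- dpois(1:4, 2) / (1 - dpois(0, 2))
  pk <- c(pk, 1 - sum(pk)) # bin 5 = "5 or more"
  gof <- suppressWarnings(chisq.test(as.vector(counts), p = pk))
  expect_gt(gof$p.value, 0.01)
})

test_that("feature simulation separates regulators only when shifted", {
  g <- simulate_genotypes(n_samples = 30, n_genes = 2, snps_per_gene = 500,
                          seed = 12)
  flags <- assign_regulators(g, 0.1, seed = 12)
  pairs <- cis_pairs(g)

  # zero shift: regulator and background features indistinguishable
  ft0 <- simulate_features(flags, pairs, n_epigenetic = 3,
                           enhancer_shift = rep(0, 3), seed = 13)
  ks <- ks.test(ft0$epigenetic[flags, 1], ft0$epigenetic[!flags, 1])
  expect_gt(ks$p.value, 0.01)
  # standardized columns
  expect_invisible(validate_feature_table(ft0))
  # background construction: approx standard normal within sampling error
  expect_lt(abs(mean(ft0$epigenetic[!flags, 2])), 0.1)
  expect_lt(abs(sd(ft0$epigenetic[!flags, 2]) - 1), 0.1)

  # 3-sd shift: a logistic classifier separates the flags, AUC > 0.95
  ft3 <- simulate_features(flags, pairs, n_epigenetic = 3,
                           enhancer_shift = rep(3, 3), seed = 13)
  sc <- predict(suppressWarnings(glm(flags ~ ft3$epigenetic,
                                     family = binomial()))) # separable: fine
  ranks <- rank(sc)
  n1 <- sum(flags)
  auc <- (sum(ranks[flags]) - n1 * (n1 + 1) / 2) / (n1 * sum(!flags))
  expect_gt(auc, 0.95)

  expect_error(simulate_features(flags, pairs, n_epigenetic = 3,
                                 enhancer_shift = rep(1, 4)),
               "enhancer_shift")
})

test_that("truth serialization round-trips by SNP and gene id", {
  g <- simulate_genotypes(n_samples = 40, n_genes = 2, snps_per_gene = 50,
                          seed = 14)
  flags <- assign_regulators(g, 0.2, seed = 14)
  sim <- simulate_expression(g, flags, seed = 15)
  pre <- file.path(tempdir(), "truthchk")
  write_truth(sim$truth, pre)
  back <- read_truth(pre)
  expect_equal(back$regulators, sim$truth$regulators)
  expect_equal(back$regulator_flags, sim$truth$regulator_flags)
  expect_equal(back$genes, sim$truth$genes)
})
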