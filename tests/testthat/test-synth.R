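test_that("fixed seed makes every generator byte-identical", {
  cfg <- tiny_config(seed = 7L)
  a <- simulateCohorts(cfg)
  b <- simulateCohorts(cfg)
  expect_identical(dosages(a$study1$geno), dosages(b$study1$geno))
  expect_identical(exprValues(a$study2$expr), exprValues(b$study2$expr))
  expect_identical(a$truth$planted_pairs, b$truth$planted_pairs)
  iv1 <- simulateMrSummary(10, 0.3, seed = 7)
  iv2 <- simulateMrSummary(10, 0.3, seed = 7)
  expect_identical(instruments(iv1), instruments(iv2))
})

test_that("within_block_r = 0 gives independent variants", {
  cfg <- simulationConfig(seed = 1, n_blocks = 1L, snps_per_block = 10L,
                          n_genes = 1L, within_block_r = 0)
  g <- simulateGenotypes(cfg, n_samples = 2000L)
  r2 <- cor(t(dosages(g)))^2
  expect_lt(mean(r2[upper.tri(r2)]), 3 / 2000)
})

test_that("genotypes are in Hardy-Weinberg proportions at the configured
           frequency", {
  cfg <- simulationConfig(seed = 2, n_blocks = 1L, snps_per_block = 2L,
                          n_genes = 1L, maf_range = c(0.5, 0.5),
                          within_block_r = 0)
  g <- simulateGenotypes(cfg, n_samples = 10000L)
  d <- dosages(g)[1, ]
  freqs <- tabulate(d + 1, 3) / length(d)
  expect_equal(freqs, c(0.25, 0.5, 0.25), tolerance = 0.05)
  expect_gt(hweExactTest(sum(d == 0), sum(d == 1), sum(d == 2)), 0.001)
})

test_that("empirical MAF and within-block LD match the copula model", {
  cfg <- simulationConfig(seed = 4, n_blocks = 2L, snps_per_block = 4L,
                          n_genes = 2L, maf_range = c(0.5, 0.5),
                          within_block_r = 0.6)
  g <- simulateGenotypes(cfg, n_samples = 10000L)
  emp_maf <- pmin(rowMeans(dosages(g)) / 2, 1 - rowMeans(dosages(g)) / 2)
  expect_equal(unname(emp_maf), variantInfo(g)$maf_true, tolerance = 0.05)
  # at MAF 0.5 the thresholded-Gaussian (arcsine law) dosage correlation is
  # 2/pi * asin(rho) -- the independent closed-form oracle
  r <- cor(t(dosages(g)[1:4, ]))
  expected <- 2 / pi * asin(0.6)
  expect_equal(mean(r[upper.tri(r)]), expected, tolerance = 0.05)
  # variants in different blocks stay independent
  r_between <- cor(dosages(g)[1, ], dosages(g)[5, ])
  expect_lt(abs(r_between), 0.05)
})

test_that("planted cis effects are recovered by per-study regression", {
  cfg <- simulationConfig(seed = 5, n_blocks = 3L, snps_per_block = 4L,
                          n_genes = 3L, noise_sd = 0.1,
                          n_hidden_factors = 0L)
  g <- simulateGenotypes(cfg, n_samples = 280L)
  planted <- data.frame(gene = "gene2", snp = "rs2_1", beta = 1)
  se <- simulateExpression(g, cfg, planted = planted)
  si <- sampleInfo(g)
  y <- log2(exprValues(se$expr))["gene2", ]
  fit <- fitLinearAssociation(y, dosages(g)["rs2_1", ],
                              cbind(si$age, si$sex))
  expect_lt(abs(fit$beta - 1), 3 * fit$se)
})

test_that("planting a causal SNP outside the cis window is rejected", {
  cfg <- tiny_config()
  g <- simulateGenotypes(cfg, n_samples = 50L)
  expect_error(
    simulateExpression(g, cfg, planted = data.frame(
      gene = "gene1", snp = "rs6_1", beta = 1)),
    "cis")
})

test_that("with no hidden factors the estimator finds little structure,
           with one global factor it finds it", {
  set.seed(8)
  n <- 100; G <- 200
  null_mat <- matrix(rnorm(G * n), G, n)
  f0 <- estimateHiddenFactors(null_mat, NULL, k = 1)
  fac <- rnorm(n)
  load <- rnorm(G)
  planted_mat <- null_mat + load %o% fac
  f1 <- estimateHiddenFactors(planted_mat, NULL, k = 1)
  expect_gt(abs(cor(f1[, 1], fac)), 0.9)
  expect_lt(abs(cor(f0[, 1], fac)), 0.5)
})

test_that("trait scenarios produce the designed genetic architecture", {
  cfg <- simulationConfig(seed = 3, n_blocks = 4L, snps_per_block = 10L,
                          n_genes = 4L, frac_egenes = 0.5,
                          effect_size_sd = 1, n_samples_study1 = 200L)
  g <- simulateGenotypes(cfg)
  se <- simulateExpression(g, cfg)
  # shared: lead GWAS SNP tags the lead eSNP (r^2 > 0.8)
  tr <- simulateTrait(g, se$expr, se$truth, "shared", trait_effect = 0.8)
  lead <- tr$gwas$snp[which.min(tr$gwas$p)]
  expect_gt(ldR2(g, lead, tr$truth$trait_model$expression_snp), 0.8)
  # distinct: trait SNP constructed with r^2 < 0.2 to the eQTL SNP
  trd <- simulateTrait(g, se$expr, se$truth, "distinct", trait_effect = 0.8)
  expect_lt(ldR2(g, trd$truth$trait_model$trait_snp,
                 trd$truth$trait_model$expression_snp), 0.2)
  # null: no SNP should be strongly associated; p spread over (0,1)
  trn <- simulateTrait(g, se$expr, se$truth, "null")
  expect_gt(min(trn$gwas$p), 1e-4)
  expect_gt(suppressWarnings(
    ks.test(trn$gwas$p, "punif")$p.value), 0.01)
})

test_that("distinct scenario errors when no SNP meets the r^2 bound", {
  cfg <- simulationConfig(seed = 6, n_blocks = 1L, snps_per_block = 4L,
                          n_genes = 1L, frac_egenes = 1,
                          within_block_r = 0.995,
                          maf_range = c(0.5, 0.5), n_samples_study1 = 150L)
  g <- simulateGenotypes(cfg)
  se <- simulateExpression(g, cfg)
  expect_error(
    simulateTrait(g, se$expr, se$truth, "distinct", r2_bound = 1e-4),
    "r\\^2")
})

test_that("MR summary generator honours its ground truth", {
  # no pleiotropy, no estimation noise: every ratio equals theta exactly
  iv <- simulateMrSummary(10, theta = 0.4, se_x = 0, se_y = 0, seed = 2)
  d <- instruments(iv)
  expect_equal(d$beta_y / d$beta_x, rep(0.4, 10))
  # a single instrument is generated but refused downstream
  one <- simulateMrSummary(1, 0.4, seed = 3)
  expect_error(mrWeightedMedianPenalised(one), "at least 3")
  expect_error(mrEggerRobust(one), "at least 3")
})

test_that("degenerate configs are rejected up front", {
  expect_error(simulationConfig(n_blocks = 0), "positive")
  expect_error(simulationConfig(within_block_r = 1), "within_block_r")
  expect_error(simulationConfig(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulationConfig(frac_egenes = 1.2), "frac_egenes")
})
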