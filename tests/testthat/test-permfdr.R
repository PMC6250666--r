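test_that("adjusted p follows the (1+k)/(B+1) pseudocount convention", {
  expect_equal(adjustGeneP(1e-9, runif(2000, 0.01, 1)), 1 / 2001)
  expect_equal(adjustGeneP(1, runif(100, 0, 0.99)), 1)
  expect_equal(adjustGeneP(0.025, c(0.01, 0.02, 0.03, 0.04)), 3 / 5)
})

test_that("per-gene threshold is the type-1 (left-continuous) ECDF
           inverse", {
  nulls <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(perGeneThreshold(nulls, 0.5), 0.02)
  expect_equal(perGeneThreshold(nulls, 1), 0.04)
  expect_equal(perGeneThreshold(nulls, 1 / length(nulls)), 0.01)
  expect_equal(perGeneThreshold(nulls, 1e-6), 0.01)
  # order-statistic oracle on random nulls across a grid of pt
  set.seed(30)
  nv <- runif(37)
  for (pt in c(0.001, 0.1, 0.25, 0.5, 0.77, 0.99, 1)) {
    oracle <- min(nv[vapply(nv, function(x) mean(nv <= x) >= pt,
                            logical(1))])
    expect_equal(perGeneThreshold(nv, pt), oracle)
  }
})

test_that("genome-wide threshold picks the gene with q closest to the
           target, ties to the smaller adjusted p", {
  expect_equal(genomewideThreshold(c(1e-5, 3e-4, 0.3),
                                   c(0.01, 0.049, 0.2)), 3e-4)
  expect_equal(genomewideThreshold(0.02, 0.3), 0.02)     # single gene
  expect_equal(genomewideThreshold(c(0.01, 0.002),
                                   c(0.04, 0.06)), 0.002) # tie in |q-.05|
})

test_that("Storey q-values reduce to BH at pi0 = 1 and behave at the
           extremes", {
  expect_equal(qvaluesStorey(rep(1, 10)), rep(1, 10))
  set.seed(31)
  p <- runif(500)
  expect_equal(qvaluesStorey(p, pi0 = 1), p.adjust(p, "BH"),
               tolerance = 1e-12)
  # n < 100 forces the BH fallback
  p2 <- runif(50)
  expect_equal(qvaluesStorey(p2), p.adjust(p2, "BH"), tolerance = 1e-12)
  # uniform null: essentially nothing passes q < 0.05
  expect_lte(sum(qvaluesStorey(runif(1000)) < 0.05), 2)
  # monotone non-decreasing in p
  q <- qvaluesStorey(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("permutation null is deterministic, detects planted signal, and
           is uniform under the global null", {
  cfg <- simulationConfig(seed = 33, n_blocks = 30L, snps_per_block = 3L,
                          n_genes = 30L, frac_egenes = 0,
                          n_samples_study1 = 60L, n_samples_study2 = 40L,
                          n_hidden_factors = 0L)
  sim <- simulateCohorts(cfg)
  studies <- lapply(list(sim$study1, sim$study2), function(st) {
    si <- sampleInfo(st$geno)
    list(Y = normalizeExpression(st$expr), G = st$geno,
         covar_perm = cbind(age = si$age, sex = si$sex),
         covar_fixed = NULL)
  })
  pairs <- mapCisPairs(studies[[1]]$Y, studies[[1]]$G)
  n1 <- permuteMinP(studies, pairs, B = 150, seed = 5)
  n2 <- permuteMinP(studies, pairs, B = 150, seed = 5)
  expect_identical(n1, n2)
  expect_error(permuteMinP(studies, pairs, B = 0), "B must be")
  scans <- lapply(studies, function(s)
    runStudyEqtl(s$Y, s$G, s$covar_perm, pairs))
  meta <- runMetaEqtl(scans[[1]], scans[[2]])
  calib <- calibratePermutations(meta, n1)
  adj <- adjustedP(calib)
  expect_gt(suppressWarnings(ks.test(adj, "punif")$p.value), 0.01)
  # adjusted p is invariant to monotone transforms of the pair p-values
  meta_t <- meta; meta_t$p_meta <- sqrt(meta$p_meta)
  calib_t <- calibratePermutations(meta_t, sqrt(n1))
  expect_equal(adjustedP(calib_t), adj)
})

test_that("a strong planted eQTL attains the extreme adjusted p
           1/(B+1)", {
  cfg <- simulationConfig(seed = 34, n_blocks = 5L, snps_per_block = 3L,
                          n_genes = 5L, frac_egenes = 0, noise_sd = 0.3,
                          n_samples_study1 = 80L, n_samples_study2 = 50L,
                          n_hidden_factors = 0L)
  g1 <- simulateGenotypes(cfg, cfg$n_samples_study1, study = "study1")
  planted <- data.frame(gene = "gene2", snp = "rs2_1", beta = 2)
  e1 <- simulateExpression(g1, cfg, planted = planted)
  st <- list(list(Y = normalizeExpression(e1$expr), G = g1,
                  covar_perm = NULL, covar_fixed = NULL))
  pairs <- mapCisPairs(st[[1]]$Y, g1)
  B <- 200
  null <- permuteMinP(st, pairs, B = B, seed = 6)
  scan <- runStudyEqtl(st[[1]]$Y, g1, NULL, pairs)
  meta <- runMetaEqtl(scan, NULL)
  calib <- calibratePermutations(meta, null)
  expect_equal(unname(adjustedP(calib)["gene2"]), 1 / (B + 1))
})

test_that("eGene calling respects the q threshold and per-gene nominal
           thresholds", {
  # hand-built calibration: three genes around the q = 0.05 edge
  null <- matrix(rep(seq(0.001, 0.2, length.out = 100), 3), 3, 100,
                 byrow = TRUE, dimnames = list(paste0("g", 1:3), NULL))
  meta <- data.frame(gene = rep(paste0("g", 1:3), each = 2),
                     snp = paste0("s", 1:6),
                     pos = 1:6 * 100L,
                     p_meta = c(1e-4, 0.5, 0.002, 0.9, 0.15, 0.2))
  calib <- calibratePermutations(meta, null)
  calls <- callEgenes(meta, calib)
  q <- geneQvalues(calib)
  expect_setequal(calls$egenes, names(q)[q < 0.05])
  # every significant pair is below its gene threshold
  pti <- perGeneThresholds(calib)
  expect_true(all(calls$pairs$p_meta <= pti[calls$pairs$gene]))
  # threshold consistency: any gene whose adjusted p is at or below P_t
  # has its observed minimum p at or below its own P_t,i
  adj <- adjustedP(calib)
  ok_genes <- names(adj)[adj <= genomewideThresholdValue(calib)]
  in_ok <- calls$best$gene %in% ok_genes
  expect_true(all(calls$best$p_meta[in_ok] <=
                  pti[calls$best$gene[in_ok]]))
  # q-threshold edge cases via a direct fake calibration
  mk <- function(qv) {
    methods::new("PermutationCalibration",
                 null = matrix(0.5, 1, 10, dimnames = list("g", NULL)),
                 observed = c(g = 0.01), adjusted = c(g = 0.01),
                 qvalue = c(g = qv), pt = 0.5, pt_gene = c(g = 0.5),
                 B = 10L)
  }
  meta1 <- data.frame(gene = "g", snp = "s", p_meta = 0.01)
  expect_identical(callEgenes(meta1, mk(0.049))$egenes, "g")
  expect_identical(callEgenes(meta1, mk(0.051))$egenes, character(0))
  # best-eSNP tie broken by smaller bp position
  meta_tie <- data.frame(gene = "g", snp = c("sB", "sA"),
                         pos = c(500L, 900L), p_meta = c(0.001, 0.001))
  expect_identical(callEgenes(meta_tie, mk(0.01))$best$snp, "sB")
})
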