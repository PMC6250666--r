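test_that("proxy expansion uses strict r^2 > 0.8 with haplotype-table
           oracle values", {
  # two-locus haplotype tables at allele frequency 0.5:
  # counts (AB, Ab, aB, ab) = (95, 5, 5, 95) -> D = 0.225, r^2 = 0.81
  mk_hap <- function(n_ab, n_Ab, n_aB, n_AB) {
    a <- c(rep(1, n_AB), rep(1, n_Ab), rep(0, n_aB), rep(0, n_ab))
    b <- c(rep(1, n_AB), rep(0, n_Ab), rep(1, n_aB), rep(0, n_ab))
    rbind(v1 = a, v2 = b)
  }
  d81 <- mk_hap(95, 5, 5, 95)
  r2_hand <- (mean(d81[1, ] * d81[2, ]) -
                mean(d81[1, ]) * mean(d81[2, ]))^2 /
    (0.25 * 0.25)
  expect_equal(r2_hand, 0.81)
  expect_equal(ldR2(d81, "v1", "v2"), 0.81)
  g81 <- geno_from_matrix(d81)
  expect_setequal(expandProxies(g81, "v1")[["v1"]], c("v1", "v2"))
  # counts (94, 6, 6, 94) -> r^2 = 0.7744 < 0.8: not a proxy
  g77 <- geno_from_matrix(mk_hap(94, 6, 6, 94))
  expect_identical(expandProxies(g77, "v1")[["v1"]], "v1")
  # a duplicated column (r^2 = 1) is always a proxy; an independent SNP
  # never is
  set.seed(40)
  base <- rbinom(300, 2, 0.4)
  d <- rbind(v1 = base, v2 = base, v3 = rbinom(300, 2, 0.4))
  px <- expandProxies(geno_from_matrix(d), "v1")[["v1"]]
  expect_true("v2" %in% px)
  expect_false("v3" %in% px)
  # expansion is idempotent and window-limited
  d2 <- rbind(v1 = base, far = base)
  g2 <- GenotypeMatrix(d2, data.frame(id = c("v1", "far"), chrom = "1",
                                      pos = c(1000L, 5000000L),
                                      ref = "A", alt = "G"))
  expect_identical(expandProxies(g2, "v1")[["v1"]], "v1")
})

test_that("GWAS/eSNP overlap counts follow set algebra", {
  proxies <- list(s1 = c("s1", "p1"), s2 = c("s2"), s3 = c("s3", "p3"))
  ov <- overlapGwasEsnps(c("s1", "s2", "s3"), proxies,
                         esnp_set = c("p1", "s2", "zz"),
                         best_esnp_set = c("p1"))
  expect_equal(ov$n_overlap, 2L)          # s1 via proxy, s2 directly
  expect_equal(ov$n_overlap_best, 1L)
  expect_equal(ov$pairs$esnp, c("p1", "s2"))
  # empty target set
  expect_equal(overlapGwasEsnps("s1", proxies, character(0))$n_overlap, 0L)
  # a GWAS SNP that is itself an eSNP overlaps without proxies
  expect_equal(overlapGwasEsnps("x", list(), esnp_set = "x")$n_overlap, 1L)
})

test_that("Fisher 2x2 equals the hypergeometric enumeration oracle", {
  expect_equal(fisherExact2x2(3, 1, 1, 3)$p, 34 / 70, tolerance = 1e-12)
  expect_equal(fisherExact2x2(5, 5, 5, 5)$p, 1)
  set.seed(41)
  for (i in 1:60) {
    n <- sample(4:30, 1)
    cells <- as.vector(stats::rmultinom(1, n, rep(0.25, 4)))
    expect_equal(fisherExact2x2(cells[1], cells[2], cells[3], cells[4])$p,
                 fisher_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
})

test_that("matched SNP sets respect tolerances and non-overlap", {
  set.seed(42)
  input <- sprintf("in%d", 1:8)
  uni_in <- data.frame(snp = input, maf = runif(8, 0.1, 0.4),
                       ld_buddies = sample(5:50, 8),
                       gene_density = runif(8, 1, 10),
                       dist_nearest_gene = runif(8, 1e3, 1e5))
  # clones: identical properties, different ids
  clones <- do.call(rbind, lapply(1:5, function(k) {
    u <- uni_in; u$snp <- sprintf("cl%d_%d", k, 1:8); u
  }))
  universe <- rbind(uni_in, clones)
  ms <- matchedSnpSets(input, universe, n_sets = 20, seed = 7)
  expect_equal(ms$n_skipped, 0L)
  for (s in ms$sets) {
    expect_length(s, 8L)
    expect_length(intersect(s, input), 0L)   # non-overlapping with input
    expect_false(anyDuplicated(s) > 0)       # without replacement
    # audit: each member within tolerance of its input SNP
    for (j in seq_along(s)) {
      u0 <- uni_in[j, ]; u <- universe[universe$snp == s[j], ]
      expect_lte(abs(u$maf - u0$maf) / u0$maf, 0.10)
      expect_lte(abs(u$ld_buddies - u0$ld_buddies) / u0$ld_buddies, 0.50)
    }
  }
  # zero tolerance with unique properties: everything skipped, warning
  uni_far <- uni_in
  uni_far$snp <- sprintf("far%d", 1:8)
  uni_far$maf <- uni_far$maf + 0.2
  expect_warning(
    ms2 <- matchedSnpSets(input, rbind(uni_in, uni_far),
                          n_sets = 2, maf_tol = 0, other_tol = 0),
    "no eligible match")
  expect_equal(ms2$n_skipped, 8L)
})

test_that("enrichment fold and p behave across regimes", {
  # observed equals the null mean -> fold exactly 1
  e1 <- enrichmentTest(5, 100, rep(5, 50))
  expect_equal(e1$fold, 1)
  # all-zero null guarded with warning
  expect_warning(e2 <- enrichmentTest(3, 100, rep(0, 50)), "epsilon")
  expect_gt(e2$fold, 1e6)
  # toy counts: 30/117 observed vs 100 matched sets totalling 750 hits
  nulls <- rep(7.5, 100)
  e3 <- enrichmentTest(30, 117, nulls)
  expect_equal(e3$fold, 4)
  expect_equal(e3$p,
               fisherExact2x2(30, 87, 750, 100 * 117 - 750)$p)
  # empirical option is a valid rank p
  e4 <- enrichmentTest(30, 117, c(rep(5, 99), 31), method = "empirical")
  expect_equal(e4$p, 2 / 101)
  # label-shuffled target: fold ~ 1 over replicates
  set.seed(43)
  folds <- replicate(200, {
    counts <- rbinom(21, 20, 0.3)
    enrichmentTest(counts[1], 20, counts[-1])$fold
  })
  expect_equal(mean(folds), 1, tolerance = 0.05)
})

test_that("BED annotation follows the 0-based half-open convention", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("1\t100\t200\tenhancer", "1\t300\t400\ttss"), bed)
  tr <- readBedTrack(bed)
  snps <- data.frame(id = c("a", "b", "c", "d", "e"), chrom = "1",
                     pos = c(101L, 100L, 200L, 350L, 250L))
  ann <- annotateSnps(snps, tr)
  expect_identical(ann$a, "enhancer")  # 0-based 100 is inside [100,200)
  expect_identical(ann$b, character(0))  # 0-based 99 misses
  expect_identical(ann$c, "enhancer")  # 0-based 199, last covered base
  expect_identical(ann$d, "tss")
  expect_identical(ann$e, character(0))
  # brute-force scan oracle over the same 5 SNPs x 2 intervals
  iv <- data.frame(s = c(100, 300), e = c(200, 400),
                   lab = c("enhancer", "tss"))
  for (i in seq_len(nrow(snps))) {
    hit <- iv$lab[iv$s <= snps$pos[i] - 1 & snps$pos[i] - 1 < iv$e]
    expect_identical(ann[[snps$id[i]]], hit)
  }
  unlink(bed)
})
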