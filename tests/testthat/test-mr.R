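test_that("instrument selection is greedy LD pruning at r^2<0.2,
           p<0.08", {
  set.seed(60)
  base <- rbinom(400, 2, 0.4)
  d <- rbind(v1 = base, v2 = base, v3 = rbinom(400, 2, 0.4),
             v4 = rbinom(400, 2, 0.4))
  # all mutually correlated -> only the smallest p survives
  dd <- rbind(a = base, b = base, c = base)
  res <- data.frame(snp = c("a", "b", "c"), p = c(0.01, 0.001, 0.05))
  expect_warning(kept <- selectInstruments(res, dd), "single instrument")
  expect_identical(kept, "b")
  # independent SNPs with p = (0.01, 0.05, 0.2): p < 0.08 keeps two
  res2 <- data.frame(snp = c("v1", "v3", "v4"), p = c(0.01, 0.05, 0.2))
  expect_identical(selectInstruments(res2, d), c("v1", "v3"))
  expect_error(selectInstruments(data.frame(snp = "v1", p = 0.5), d),
               "no instruments")
  # 6-SNP toy panel vs an independent re-implementation of the rule
  set.seed(61)
  d6 <- rbind(s1 = base, s2 = base, s3 = rbinom(400, 2, 0.3),
              s4 = rbinom(400, 2, 0.3), s5 = rbinom(400, 2, 0.3),
              s6 = 1 - abs(base - 1))   # correlated with s1
  res6 <- data.frame(snp = rownames(d6),
                     p = c(0.04, 0.002, 0.01, 0.06, 0.079, 0.03))
  kept6 <- selectInstruments(res6, d6)
  # oracle: walk candidates in ascending p, keep iff independent of all
  # previously kept
  ord <- res6$snp[order(res6$p)]
  ord <- ord[res6$p[order(res6$p)] < 0.08]
  oracle <- character(0)
  for (s in ord)
    if (!length(oracle) ||
        all(cor(d6[s, ], t(d6[oracle, , drop = FALSE]))^2 < 0.2))
      oracle <- c(oracle, s)
  expect_identical(kept6, oracle)
})

test_that("harmonisation aligns alleles, flips swaps, drops
           palindromes", {
  expo <- data.frame(snp = c("r1", "r2", "r3", "r4", "r5"),
                     effect_allele = c("A", "A", "A", "A", "A"),
                     other_allele = c("G", "G", "T", "G", "G"),
                     beta = c(0.2, 0.2, 0.2, 0.2, 0.2), se = 0.05)
  outc <- data.frame(snp = c("r1", "r2", "r3", "r4", "x5"),
                     effect_allele = c("A", "G", "A", "T", "A"),
                     other_allele = c("G", "A", "T", "C", "G"),
                     beta = c(0.1, 0.1, 0.1, 0.1, 0.1), se = 0.02)
  h <- harmonise(expo, outc)
  ins <- instruments(h)
  expect_equal(ins$beta_y[ins$snp == "r1"], 0.1)    # same alleles
  expect_equal(ins$beta_y[ins$snp == "r2"], -0.1)   # swapped -> flipped
  expect_false("r3" %in% ins$snp)                   # A/T palindrome
  expect_equal(ins$beta_y[ins$snp == "r4"], 0.1)    # strand flip T/C=A/G
  expect_true(all(c("r3", "r5") %in% h@dropped$snp))
  # palindromes retained on request
  h2 <- harmonise(expo, outc, drop_palindromic = FALSE)
  expect_true("r3" %in% instruments(h2)$snp)
})

test_that("plain IVW equals its closed form and a WLS oracle", {
  d <- data.frame(snp = c("a", "b"), effect_allele = "A",
                  beta_x = c(0.5, 0.25), se_x = 0.01,
                  beta_y = c(0.1, 0.1), se_y = c(1, 1))
  expect_equal(mrIvw(d)$theta, 0.24)
  set.seed(62)
  iv <- simulateMrSummary(15, 0.35, se_x = 0.02, se_y = 0.04, seed = 3)
  di <- instruments(iv)
  fit <- lm(beta_y ~ beta_x - 1, data = di, weights = 1 / di$se_y^2)
  expect_equal(mrIvw(iv)$theta, unname(coef(fit)), tolerance = 1e-10)
})

test_that("all estimators agree when every ratio is identical", {
  iv <- simulateMrSummary(12, theta = 0.3, se_x = 0, se_y = 0, seed = 4)
  expect_equal(mrIvw(iv)$theta, 0.3, tolerance = 1e-10)
  expect_equal(mrIvwRobust(iv)$theta, 0.3, tolerance = 1e-6)
  expect_equal(mrWeightedMedianPenalised(iv, n_boot = 50)$theta, 0.3,
               tolerance = 1e-6)
})

test_that("weighted median interpolates the cumulative-weight percentile
           function", {
  # equal weights on (1,2,3) -> 2
  expect_equal(nephroQTL:::.weighted_median(c(1, 2, 3), rep(1, 3)), 2)
  # weights (0.5, 0.25, 0.25) on sorted (1,2,3): brute-force percentile
  # oracle -- cumulative weight minus half own weight, interpolated at 0.5
  w <- c(0.5, 0.25, 0.25); x <- c(1, 2, 3)
  cw <- cumsum(w) - w / 2              # 0.25 0.625 0.875
  oracle <- approx(cw, x, xout = 0.5)$y
  expect_equal(nephroQTL:::.weighted_median(x, w), oracle)
  expect_equal(oracle, 1 + (0.5 - 0.25) / 0.375)
  # invariant to relabelling
  o <- c(3, 1, 2)
  expect_equal(nephroQTL:::.weighted_median(x[o], w[o]),
               nephroQTL:::.weighted_median(x, w))
})

test_that("MR-Egger recovers an exact linear relation and needs 3
           instruments", {
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  d <- data.frame(snp = paste0("s", 1:5), effect_allele = "A",
                  beta_x = bx, se_x = 0.01,
                  beta_y = 0.05 + 0.4 * bx, se_y = 0.01)
  eg <- mrEggerRobust(d)
  expect_equal(eg$theta, 0.4, tolerance = 1e-6)
  expect_equal(eg$intercept, 0.05, tolerance = 1e-6)
  expect_error(mrEggerRobust(d[1:2, ]), "at least 3")
  # orientation: simultaneous sign flip of (beta_x, beta_y) changes
  # nothing
  d2 <- d; d2$beta_x[2] <- -d$beta_x[2]; d2$beta_y[2] <- -d$beta_y[2]
  eg2 <- mrEggerRobust(d2)
  expect_equal(eg2$theta, eg$theta, tolerance = 1e-10)
})

test_that("robust IVW resists a gross outlier that distorts plain IVW", {
  set.seed(63)
  iv <- simulateMrSummary(20, theta = 0.3, se_x = 0.01, se_y = 0.02,
                          seed = 5)
  d <- instruments(iv)
  d$beta_y[1] <- d$beta_y[1] + 1.5          # one wild pleiotropic outlier
  rob <- mrIvwRobust(d)
  plain <- mrIvw(d)
  expect_lt(abs(rob$theta - 0.3), 2 * rob$se)
  expect_gt(abs(plain$theta - 0.3), 2 * plain$se)
})

test_that("penalised weighted median withstands <50% of weight on wildly
           invalid instruments", {
  set.seed(64)
  errs <- vapply(1:40, function(i) {
    iv <- simulateMrSummary(20, theta = 0.3, pleiotropy_mean = 0,
                            pleiotropy_sd = 0.5, se_x = 0.01,
                            se_y = 0.02, seed = 100 + i,
                            invalid_frac = 0.4)
    d <- instruments(iv)
    w <- d$beta_x^2 / d$se_y^2
    invalid_share <- sum(w[1:8]) / sum(w)  # generator corrupts the first 8
    if (invalid_share >= 0.5) return(NA_real_)  # breakdown bound reached
    mrWeightedMedianPenalised(iv, n_boot = 2)$theta - 0.3
  }, numeric(1))
  expect_lt(abs(mean(errs, na.rm = TRUE)), 0.03)      # no systematic bias
  expect_lt(median(abs(errs), na.rm = TRUE), 0.05)    # typically on target
})

test_that("sensitivity statistics match hand formulas", {
  # identical ratios -> Q = 0, p = 1
  iv <- simulateMrSummary(6, 0.3, se_x = 0, se_y = 0, seed = 6)
  s <- mrSensitivity(iv)
  expect_equal(s$Q, 0, tolerance = 1e-12)
  expect_equal(s$Q_p, 1)
  # two instruments with hand-set ratios and weights
  d <- data.frame(snp = c("a", "b"), effect_allele = "A",
                  beta_x = c(1, 2), se_x = 0.01,
                  beta_y = c(0.2, 0.8), se_y = c(0.1, 0.1))
  th <- d$beta_y / d$beta_x               # 0.2, 0.4
  w <- d$beta_x^2 / d$se_y^2              # 100, 400
  ivw <- sum(w * th) / sum(w)             # 0.36
  Q_hand <- sum(w * (th - ivw)^2)
  s2 <- mrSensitivity(d)
  expect_equal(s2$Q, Q_hand, tolerance = 1e-10)
  expect_equal(s2$Q_df, 1L)
})

test_that("the causality verdict applies the Bonferroni family rule", {
  expect_true(mrVerdict(c(0.001, 0.002, 0.2), m = 7)$causal)
  expect_false(mrVerdict(c(0.001, 0.2, 0.3), m = 7)$causal)
  v <- mrVerdict(c(0.004, 0.004, 0.9), m = 11)
  expect_equal(v$threshold, 0.05 / 11)
  expect_true(v$causal)
  expect_false(mrVerdict(c(0.0046, 0.0046, 0.9), m = 11)$causal)
})
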