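# Shared small fixtures, all generated in code.

# tiny two-cohort simulation reused across tests
tiny_config <- function(seed = 3L, ...) {
  simulationConfig(seed = seed, n_blocks = 6L, snps_per_block = 5L,
                   n_genes = 6L, frac_egenes = 0.5, effect_size_sd = 0.8,
                   n_samples_study1 = 120L, n_samples_study2 = 80L, ...)
}

# genotype container from an explicit dosage matrix (variants x samples)
geno_from_matrix <- function(d, chrom = "1",
                             pos = seq_len(nrow(d)) * 1000L) {
  if (is.null(rownames(d))) rownames(d) <- paste0("v", seq_len(nrow(d)))
  GenotypeMatrix(d, data.frame(id = rownames(d), chrom = chrom, pos = pos,
                               ref = "A", alt = "G",
                               stringsAsFactors = FALSE))
}

# independent enumeration oracle for the exact HWE test: enumerate every
# genotype configuration compatible with the allele counts and weight it by
# the number of allele arrangements
hwe_oracle <- function(aa, ab, bb) {
  n <- aa + ab + bb
  na_ <- ab + 2 * bb
  hets <- seq(na_ %% 2, min(na_, 2 * n - na_), by = 2)
  weight <- function(h) {
    x_bb <- (na_ - h) / 2
    x_aa <- n - h - x_bb
    if (x_aa < 0 || x_bb < 0) return(0)
    exp(lgamma(n + 1) - lgamma(x_aa + 1) - lgamma(h + 1) -
          lgamma(x_bb + 1) + h * log(2))
  }
  w <- vapply(hets, weight, numeric(1))
  pr <- w / sum(w)
  obs <- pr[hets == ab]
  sum(pr[pr <= obs + 1e-12])
}

# independent normal-equations OLS oracle
ols_oracle <- function(y, X) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(s2 * solve(XtX)))
  list(beta = drop(b), se = se, df = df,
       p = 2 * pt(-abs(drop(b) / se), df))
}

# two-sided Fisher enumeration oracle over tables with fixed margins
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  av <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- dhyper(av, c1, n - c1, r1)
  sum(pr[pr <= dhyper(a, c1, n - c1, r1) * (1 + 1e-7)])
}
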