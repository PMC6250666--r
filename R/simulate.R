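#' Simulation configuration for the two-cohort synthetic study
#'
#' Bundles and validates every knob of the synthetic data generator. The
#' defaults emulate the two-cohort design the pipeline targets: cohorts of
#' 180 and 100 samples, block-LD genotypes in Hardy-Weinberg proportions,
#' expression with planted cis effects plus covariate and hidden-factor
#' structure.
#'
#' @param seed integer seed; fixing it makes every generator output
#'   byte-identical.
#' @param n_samples_study1,n_samples_study2 cohort sizes (defaults 180, 100).
#' @param n_blocks number of independent LD blocks (one gene per block).
#' @param snps_per_block SNPs per block.
#' @param within_block_r latent pairwise correlation within a block, in
#'   \[0, 1).
#' @param maf_range interval within (0, 0.5\] from which per-variant minor
#'   allele frequencies are drawn uniformly.
#' @param n_genes number of genes; must not exceed \code{n_blocks} so each
#'   gene owns a block of cis SNPs.
#' @param frac_egenes fraction of genes given a planted cis effect.
#' @param effect_size_sd SD of planted betas (expression SD units per
#'   allele).
#' @param n_hidden_factors number of latent expression factors.
#' @param noise_sd residual SD of expression on the latent log2 scale.
#' @param covariate_effects named numeric: \code{age} (per year) and
#'   \code{sex} coefficients on expression.
#' @param study_jitter_sd SD of an optional between-study perturbation of
#'   the planted betas (0 = identical effects in both cohorts).
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed = 1L,
                             n_samples_study1 = 180L,
                             n_samples_study2 = 100L,
                             n_blocks = 25L,
                             snps_per_block = 8L,
                             within_block_r = 0.6,
                             maf_range = c(0.05, 0.5),
                             n_genes = 25L,
                             frac_egenes = 0.2,
                             effect_size_sd = 0.5,
                             n_hidden_factors = 3L,
                             noise_sd = 1,
                             covariate_effects = c(age = 0.01, sex = 0.3),
                             study_jitter_sd = 0) {
  cfg <- list(seed = as.integer(seed),
              n_samples_study1 = as.integer(n_samples_study1),
              n_samples_study2 = as.integer(n_samples_study2),
              n_blocks = as.integer(n_blocks),
              snps_per_block = as.integer(snps_per_block),
              within_block_r = within_block_r,
              maf_range = maf_range,
              n_genes = as.integer(n_genes),
              frac_egenes = frac_egenes,
              effect_size_sd = effect_size_sd,
              n_hidden_factors = as.integer(n_hidden_factors),
              noise_sd = noise_sd,
              covariate_effects = covariate_effects,
              study_jitter_sd = study_jitter_sd)
  counts <- c("n_samples_study1", "n_samples_study2", "n_blocks",
              "snps_per_block", "n_genes")
  for (nm in counts)
    if (cfg[[nm]] < 1L) stop("'", nm, "' must be a positive count")
  if (cfg$within_block_r < 0 || cfg$within_block_r >= 1)
    stop("'within_block_r' must lie in [0, 1)")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop("'maf_range' must be an interval within (0, 0.5]")
  if (cfg$frac_egenes < 0 || cfg$frac_egenes > 1)
    stop("'frac_egenes' must lie in [0, 1]")
  if (cfg$n_genes > cfg$n_blocks)
    stop("'n_genes' may not exceed 'n_blocks' (one gene per LD block)")
  class(cfg) <- "SimulationConfig"
  cfg
}

# Block layout: block b occupies [.block_origin(b), +), SNPs every 1 kb,
# gene body 10 kb inside the block, blocks 3 Mb apart so that the cis window
# (1 Mb) of a gene never reaches a neighbouring block.
.block_spacing <- 3e6
.block_origin <- function(b) (b - 1L) * .block_spacing + 1e6

#' Simulate block-LD genotype dosages in Hardy-Weinberg proportions
#'
#' Haplotypes are drawn per LD block from a latent multivariate Gaussian with
#' compound-symmetric correlation \code{within_block_r} and thresholded at
#' the per-variant allele frequency (a Gaussian copula); the two haplotypes
#' of a sample are independent, so genotype frequencies are in
#' Hardy-Weinberg proportions by construction. Variants in different blocks
#' are independent.
#'
#' @param config a [simulationConfig()].
#' @param n_samples number of samples; defaults to
#'   \code{config$n_samples_study1}.
#' @param seed overrides \code{config$seed} when given.
#' @param study label stored in the sample covariates.
#' @return A \linkS4class{GenotypeMatrix} with sample covariates
#'   \code{age}, \code{sex} (0/1) and \code{study}.
#' @export
simulateGenotypes <- function(config, n_samples = config$n_samples_study1,
                              seed = config$seed, study = "study1") {
  stopifnot(inherits(config, "SimulationConfig"))
  m <- config$n_blocks * config$snps_per_block
  if (m < 1L) stop("degenerate config: zero variants")
  set.seed(config$seed)   # panel (allele frequencies) is fixed by the config
  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  set.seed(seed)          # cohort-specific haplotypes and covariates
  r <- config$within_block_r
  p <- config$snps_per_block
  L <- chol(matrix(r, p, p) + diag(1 - r, p))   # upper-triangular factor
  thr <- qnorm(maf)
  hap <- function() {
    z <- matrix(rnorm(n_samples * m), n_samples, m)
    if (r > 0)
      for (b in seq_len(config$n_blocks)) {
        idx <- ((b - 1L) * p + 1L):(b * p)
        z[, idx] <- z[, idx] %*% L
      }
    # allele carries the ALT with probability maf
    t(t(z) < thr) * 1L
  }
  dos <- t(hap() + hap())                       # variants x samples
  pos <- as.integer(.block_origin(rep(seq_len(config$n_blocks),
                                      each = p)) +
                    1000L * (rep(seq_len(p), config$n_blocks) - 1L))
  variants <- data.frame(
    id = sprintf("rs%d_%d", rep(seq_len(config$n_blocks), each = p),
                 rep(seq_len(p), config$n_blocks)),
    chrom = "1", pos = pos, ref = "A", alt = "G",
    maf_true = maf, block = rep(seq_len(config$n_blocks), each = p),
    stringsAsFactors = FALSE)
  samples <- data.frame(
    id = sprintf("%s_S%03d", study, seq_len(n_samples)),
    age = round(rnorm(n_samples, 55, 10), 1),
    sex = rbinom(n_samples, 1, 0.5),
    study = study, stringsAsFactors = FALSE)
  GenotypeMatrix(dos, variants, samples)
}

#' Gene annotation matching the simulated variant panel
#'
#' One gene per LD block, with a 10 kb body placed inside the block so that
#' all of the block's SNPs are within the 1 Mb cis window of the gene and no
#' SNP of any other block is.
#'
#' @param config a [simulationConfig()].
#' @return data.frame with id, chrom, start, end, block.
#' @export
simulatedGeneTable <- function(config) {
  b <- seq_len(config$n_genes)
  start <- as.integer(.block_origin(b) + 2000L)
  data.frame(id = sprintf("gene%d", b), chrom = "1",
             start = start, end = start + 9999L, block = b,
             stringsAsFactors = FALSE)
}

#' Simulate expression with planted cis effects and known ground truth
#'
#' Latent log2 expression is
#' \code{beta * dosage (eGenes only) + covariate effects + loadings x hidden
#' factors + Gaussian noise}; reported TPM is \code{2^latent}, so
#' \code{log2(TPM)} recovers the latent scale exactly and the full
#' TPM normalisation chain still has work to do downstream.
#'
#' @param geno a \linkS4class{GenotypeMatrix} from [simulateGenotypes()].
#' @param config a [simulationConfig()].
#' @param seed overrides \code{config$seed}.
#' @param planted optional data.frame (gene, snp, beta) fixing the planted
#'   pairs instead of drawing them; every snp must be cis to its gene.
#' @return list with \code{expr} (an \linkS4class{ExpressionMatrix}, stage
#'   \code{"tpm"}) and \code{truth} (class \code{"GroundTruth"}: planted
#'   pairs, hidden factor scores/loadings, the config used).
#' @export
simulateExpression <- function(geno, config, seed = config$seed + 1L,
                               planted = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (config$frac_egenes < 0 || config$frac_egenes > 1)
    stop("'frac_egenes' must lie in [0, 1]")
  set.seed(seed)
  genes <- simulatedGeneTable(config)
  vinfo <- variantInfo(geno)
  dos <- dosages(geno)                          # variants x samples
  n <- ncol(dos)
  G <- nrow(genes)
  if (is.null(planted)) {
    n_eg <- round(config$frac_egenes * G)
    eg <- if (n_eg) sort(sample.int(G, n_eg)) else integer()
    planted <- data.frame(
      gene = genes$id[eg],
      snp = vapply(eg, function(g) {
        blk <- vinfo$id[vinfo$block == genes$block[g]]
        blk[sample.int(length(blk), 1L)]
      }, character(1)),
      beta = rnorm(length(eg), 0, config$effect_size_sd),
      stringsAsFactors = FALSE)
  } else {
    cis <- mapCisPairs(genes, vinfo)
    key <- paste(cis$gene, cis$snp)
    if (!all(paste(planted$gene, planted$snp) %in% key))
      stop("every planted causal SNP must be cis to its gene")
  }
  k <- config$n_hidden_factors
  H <- if (k) matrix(rnorm(n * k), n, k) else matrix(0, n, 0)
  Lo <- if (k) matrix(rnorm(G * k, 0, 0.5) * (runif(G * k) < 0.3), G, k)
        else matrix(0, G, 0)
  cov <- sampleInfo(geno)
  ce <- config$covariate_effects
  base <- ce[["age"]] * (cov$age - mean(cov$age)) + ce[["sex"]] * cov$sex
  latent <- matrix(rnorm(G * n, 0, config$noise_sd), G, n)
  latent <- latent + rep(base, each = G) + Lo %*% t(H)
  if (nrow(planted)) {
    gi <- match(planted$gene, genes$id)
    si <- match(planted$snp, rownames(dos))
    latent[gi, ] <- latent[gi, ] + planted$beta * dos[si, , drop = FALSE]
  }
  dimnames(latent) <- list(genes$id, colnames(dos))
  expr <- ExpressionMatrix(2^latent, genes, sampleInfo(geno), stage = "tpm")
  truth <- structure(list(planted_pairs = planted, hidden_factors = H,
                          loadings = Lo, trait_model = NULL,
                          mr_truth = NULL, config = config),
                     class = "GroundTruth")
  list(expr = expr, truth = truth)
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf("GroundTruth: %d planted cis pairs, %d hidden factors\n",
              nrow(x$planted_pairs), ncol(x$hidden_factors)))
  if (!is.null(x$trait_model))
    cat(sprintf("  trait scenario: %s (driver %s)\n",
                x$trait_model$scenario, x$trait_model$driver_gene))
  invisible(x)
}

#' Simulate a quantitative trait and its GWAS summary statistics
#'
#' \code{scenario = "shared"}: the trait is driven through the expression of
#' one planted eGene, so trait and expression share one causal SNP.
#' \code{"distinct"}: the trait is driven directly by a second SNP in the
#' same LD block chosen to have r^2 below \code{r2_bound} with the
#' expression-causal SNP. \code{"null"}: pure noise. The returned GWAS table
#' holds per-SNP beta/se/p from trait-on-dosage regressions over all
#' variants of the driver block.
#'
#' @param geno,expr,truth outputs of the genotype/expression simulators.
#' @param scenario one of \code{"shared"}, \code{"distinct"}, \code{"null"}.
#' @param trait_effect effect of the driver (expression units or per-allele).
#' @param trait_noise_sd residual trait SD.
#' @param r2_bound upper r^2 bound between the expression-causal and the
#'   trait-causal SNP in the distinct scenario.
#' @param seed RNG seed.
#' @return list: \code{trait} (named vector), \code{gwas} (data.frame snp,
#'   chrom, pos, effect_allele, other_allele, beta, se, p), updated
#'   \code{truth}.
#' @export
simulateTrait <- function(geno, expr, truth,
                          scenario = c("shared", "distinct", "null"),
                          trait_effect = 0.5, trait_noise_sd = 1,
                          r2_bound = 0.2, seed = truth$config$seed + 2L) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  dos <- dosages(geno)
  n <- ncol(dos)
  vinfo <- variantInfo(geno)
  pp <- truth$planted_pairs
  if (scenario != "null" && !nrow(pp))
    stop("no planted eGene available to drive the trait")
  driver_gene <- if (nrow(pp)) pp$gene[which.max(abs(pp$beta))] else NA
  causal_snp <- if (nrow(pp)) pp$snp[which.max(abs(pp$beta))] else NA
  trait <- rnorm(n, 0, trait_noise_sd)
  trait_snp <- NA_character_
  if (scenario == "shared") {
    e <- log2(exprValues(expr))[driver_gene, ]
    trait <- trait + trait_effect * e
    trait_snp <- causal_snp
  } else if (scenario == "distinct") {
    blk <- vinfo$block[match(causal_snp, vinfo$id)]
    cand <- setdiff(vinfo$id[vinfo$block == blk], causal_snp)
    r2 <- vapply(cand, function(s)
      cor(dos[s, ], dos[causal_snp, ])^2, numeric(1))
    cand <- cand[r2 < r2_bound]
    if (!length(cand))
      stop("no SNP with r^2 < ", r2_bound,
           " to the eQTL SNP available in the driver block")
    trait_snp <- cand[1L]
    trait <- trait + trait_effect * dos[trait_snp, ]
  }
  blk_ids <- if (scenario == "null") vinfo$id
             else vinfo$id[vinfo$block ==
                           vinfo$block[match(causal_snp, vinfo$id)]]
  gw <- do.call(rbind, lapply(blk_ids, function(s) {
    f <- fitLinearAssociation(trait, dos[s, ])
    data.frame(snp = s, beta = f$beta, se = f$se, p = f$p)
  }))
  gw$chrom <- vinfo$chrom[match(gw$snp, vinfo$id)]
  gw$pos <- vinfo$pos[match(gw$snp, vinfo$id)]
  gw$effect_allele <- "G"; gw$other_allele <- "A"
  gw <- gw[c("snp", "chrom", "pos", "effect_allele", "other_allele",
             "beta", "se", "p")]
  truth$trait_model <- list(driver_gene = driver_gene,
                            expression_snp = causal_snp,
                            trait_snp = trait_snp,
                            trait_effect = trait_effect,
                            scenario = scenario)
  list(trait = setNames(trait, colnames(dos)), gwas = gw, truth = truth)
}

#' Simulate two-sample MR summary data with known causal effect
#'
#' Per instrument j: true exposure effects are drawn uniformly on
#' \[0.1, 0.5\]; \code{beta_y = theta * beta_x_true + alpha_j + noise} with
#' \code{alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2)} on the invalid
#' fraction of instruments; observed exposure effects add N(0, se_x^2)
#' estimation noise.
#'
#' @param n_instruments number of instruments.
#' @param theta true causal effect (trait units per 1-SD expression).
#' @param pleiotropy_mean,pleiotropy_sd directional pleiotropy distribution.
#' @param se_x,se_y reported (and actual) standard errors.
#' @param seed RNG seed.
#' @param invalid_frac fraction of instruments receiving pleiotropy.
#' @return an \linkS4class{MrInstrumentSet}; the ground truth is attached as
#'   \code{metadata} attribute (theta, pleiotropy, invalid fraction).
#' @export
simulateMrSummary <- function(n_instruments, theta,
                              pleiotropy_mean = 0, pleiotropy_sd = 0,
                              se_x = 0.02, se_y = 0.02, seed = 1L,
                              invalid_frac = 1) {
  stopifnot(n_instruments >= 1)
  set.seed(seed)
  bx_true <- runif(n_instruments, 0.1, 0.5)
  n_inv <- round(invalid_frac * n_instruments)
  alpha <- numeric(n_instruments)
  if (n_inv > 0)
    alpha[seq_len(n_inv)] <- rnorm(n_inv, pleiotropy_mean, pleiotropy_sd)
  bx <- bx_true + rnorm(n_instruments, 0, se_x)
  by <- theta * bx_true + alpha + rnorm(n_instruments, 0, se_y)
  ins <- data.frame(snp = sprintf("iv%d", seq_len(n_instruments)),
                    effect_allele = "A",
                    beta_x = bx, se_x = pmax(se_x, 1e-8),
                    beta_y = by, se_y = pmax(se_y, 1e-8),
                    stringsAsFactors = FALSE)
  out <- MrInstrumentSet(ins)
  attr(out, "metadata") <- list(theta = theta,
                                pleiotropy_mean = pleiotropy_mean,
                                pleiotropy_sd = pleiotropy_sd,
                                invalid_frac = invalid_frac,
                                alpha = alpha, beta_x_true = bx_true)
  out
}

#' Simulate both cohorts from one shared variant panel
#'
#' Draws the two study cohorts independently from the same variant panel
#' (same allele frequencies and positions), with shared planted cis effects;
#' \code{study_jitter_sd} optionally perturbs study-2 betas to create
#' between-study heterogeneity.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{study1}, \code{study2} (each: \code{geno},
#'   \code{expr}) and the shared \code{truth}.
#' @export
simulateCohorts <- function(config) {
  g1 <- simulateGenotypes(config, config$n_samples_study1,
                          seed = config$seed, study = "study1")
  s1 <- simulateExpression(g1, config, seed = config$seed + 1L)
  planted2 <- s1$truth$planted_pairs
  if (config$study_jitter_sd > 0 && nrow(planted2)) {
    set.seed(config$seed + 10L)
    planted2$beta <- planted2$beta +
      rnorm(nrow(planted2), 0, config$study_jitter_sd)
  }
  g2 <- simulateGenotypes(config, config$n_samples_study2,
                          seed = config$seed + 20L, study = "study2")
  s2 <- simulateExpression(g2, config, seed = config$seed + 21L,
                           planted = planted2)
  truth <- s1$truth
  truth$planted_pairs_study2 <- planted2
  list(study1 = list(geno = g1, expr = s1$expr),
       study2 = list(geno = g2, expr = s2$expr),
       truth = truth)
}
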