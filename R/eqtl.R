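#' Enumerate cis SNP-gene pairs
#'
#' A pair is included iff the SNP position lies in
#' \code{[gene_start - window, gene_end + window]} (1-based, boundaries
#' inclusive). Distance is 0 for SNPs inside the gene body, otherwise the
#' distance to the nearest gene boundary.
#'
#' @param genes data.frame (id, chrom, start, end) or
#'   \linkS4class{ExpressionMatrix}.
#' @param variants data.frame (id, chrom, pos) or
#'   \linkS4class{GenotypeMatrix}.
#' @param window cis window in bp (default 1 Mb).
#' @return data.frame (gene, snp, distance).
#' @export
mapCisPairs <- function(genes, variants, window = 1e6) {
  if (methods::is(genes, "ExpressionMatrix")) genes <- geneInfo(genes)
  if (methods::is(variants, "GenotypeMatrix"))
    variants <- variantInfo(variants)
  gr_g <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1, genes$start - window), genes$end + window))
  gr_v <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos,
                                                  variants$pos))
  # query and subject may legitimately cover different chromosome sets
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_v, gr_g))
  vi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  pos <- variants$pos[vi]
  dist <- pmax(0L, pmax(genes$start[gi] - pos, pos - genes$end[gi]))
  out <- data.frame(gene = genes$id[gi], snp = variants$id[vi],
                    distance = as.integer(dist),
                    stringsAsFactors = FALSE)
  out[order(match(out$gene, genes$id), out$distance), , drop = FALSE]
}

#' Linear association of a phenotype with genotype dosage
#'
#' Ordinary least squares of \code{y} on \code{dosage} plus an intercept and
#' optional covariates; the reported coefficient is the dosage term, with a
#' two-sided p-value from the t distribution at residual degrees of freedom.
#' A perfect fit (residual variance 0) is reported as p = 0.
#'
#' @param y response vector (normalised expression, methylation,
#'   isoform abundance, trait ...).
#' @param dosage genotype dosage vector.
#' @param covariates optional numeric matrix of adjustment covariates.
#' @return list(beta, se, t, p, n, df).
#' @export
fitLinearAssociation <- function(y, dosage, covariates = NULL) {
  ok <- complete.cases(y, dosage,
                       if (is.null(covariates)) rep(0, length(y))
                       else covariates)
  y <- y[ok]; dosage <- dosage[ok]
  X <- cbind(`(Intercept)` = 1, dosage = dosage)
  if (!is.null(covariates))
    X <- cbind(X, as.matrix(covariates)[ok, , drop = FALSE])
  if (var(dosage) == 0) stop("constant dosage")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("collinear covariates")
  n <- length(y)
  df <- n - ncol(X)
  if (df < 1) stop("n too small for the covariate count")
  beta_all <- qr.coef(qx, y)
  res <- y - drop(X %*% beta_all)
  sigma2 <- sum(res^2) / df
  XtXinv_22 <- chol2inv(qr.R(qx))[2, 2]
  se <- sqrt(sigma2 * XtXinv_22)
  beta <- unname(beta_all["dosage"])
  if (se == 0) {
    tval <- sign(beta) * Inf
    p <- 0
  } else {
    tval <- beta / se
    p <- 2 * pt(-abs(tval), df)
  }
  list(beta = beta, se = se, t = tval, p = p, n = n, df = df)
}

#' Fixed-effect inverse-variance meta-analysis of two estimates
#'
#' \code{w_k = 1/se_k^2}; pooled beta is the weighted mean, pooled
#' \code{se = 1/sqrt(sum w)}, z = beta/se, two-sided normal p. Either study
#' may be absent (NA), in which case the other study's estimate is returned
#' unchanged. Vectorised.
#'
#' @param b1,se1,b2,se2 per-study estimates and standard errors.
#' @return data.frame (beta, se, z, p, n_studies).
#' @export
metaFixedEffect <- function(b1, se1, b2, se2) {
  k <- max(length(b1), length(b2))
  b1 <- rep_len(b1, k); se1 <- rep_len(se1, k)
  b2 <- rep_len(b2, k); se2 <- rep_len(se2, k)
  has1 <- !is.na(b1) & !is.na(se1)
  has2 <- !is.na(b2) & !is.na(se2)
  if (any(se1[has1] <= 0) || any(se2[has2] <= 0))
    stop("standard errors must be > 0")
  w1 <- ifelse(has1, 1 / se1^2, 0)
  w2 <- ifelse(has2, 1 / se2^2, 0)
  wsum <- w1 + w2
  beta <- ifelse(wsum > 0,
                 (ifelse(has1, w1 * b1, 0) + ifelse(has2, w2 * b2, 0)) / wsum,
                 NA_real_)
  se <- ifelse(wsum > 0, 1 / sqrt(wsum), NA_real_)
  z <- beta / se
  data.frame(beta = beta, se = se, z = z,
             p = 2 * pnorm(-abs(z)),
             n_studies = has1 + has2)
}

#' Partial variance explained by the dosage after covariates
#'
#' Partial R^2 of the dosage term: the share of the covariate-adjusted
#' response variance explained by the covariate-adjusted dosage.
#'
#' @inheritParams fitLinearAssociation
#' @return numeric in \[0, 1\].
#' @export
varianceExplained <- function(y, dosage, covariates = NULL) {
  X0 <- cbind(rep(1, length(y)),
              if (!is.null(covariates)) as.matrix(covariates))
  Q <- qr.Q(qr(X0))
  ry <- y - Q %*% crossprod(Q, y)
  rg <- dosage - Q %*% crossprod(Q, dosage)
  if (sum(rg^2) == 0) return(0)
  drop(crossprod(ry, rg))^2 / (sum(ry^2) * sum(rg^2))
}

# Batched per-study cis-eQTL engine (Frisch-Waugh-Lovell): residualise the
# expression matrix and the dosage matrix on the covariate design once, then
# obtain per-pair beta/se/t/p from residual cross-products. Identical to
# per-pair OLS with intercept + covariates (tested to 1e-10).
#
# Y: genes x samples; G: variants x samples; covariates: samples x q.
.study_eqtl_engine <- function(Y, G, covariates, pairs) {
  n <- ncol(Y)
  X <- cbind(rep(1, n), if (!is.null(covariates)) as.matrix(covariates))
  Q <- qr.Q(qr(X))
  df <- n - ncol(X) - 1L
  RY <- t(Y) - Q %*% crossprod(Q, t(Y))      # samples x genes
  RG <- t(G) - Q %*% crossprod(Q, t(G))      # samples x variants
  gi <- match(pairs$gene, rownames(Y))
  vi <- match(pairs$snp, rownames(G))
  yy <- colSums(RY^2)[gi]
  gg <- colSums(RG^2)[vi]
  xy <- colSums(RY[, gi, drop = FALSE] * RG[, vi, drop = FALSE])
  beta <- xy / gg
  sigma2 <- pmax(yy - beta * xy, 0) / df
  se <- sqrt(sigma2 / gg)
  tval <- beta / se
  data.frame(gene = pairs$gene, snp = pairs$snp,
             beta = beta, se = se, t = tval,
             p = ifelse(se == 0, 0, 2 * pt(-abs(tval), df)),
             n = n, stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-study cis-eQTL scan
#'
#' Runs the linear dosage-expression association for every cis pair using a
#' batched covariate projection that is exactly equivalent to per-pair OLS.
#'
#' @param expr \linkS4class{ExpressionMatrix} at stage \code{"rbint"} (or a
#'   numeric genes x samples matrix).
#' @param geno \linkS4class{GenotypeMatrix} on the same samples.
#' @param covariates samples x q numeric matrix (age, sex, genotype PCs,
#'   hidden factors, cohort indicators...). NULL for intercept-only.
#' @param pairs data.frame from [mapCisPairs()]; computed when NULL.
#' @param window cis window when \code{pairs} is NULL.
#' @return data.frame (gene, snp, beta, se, t, p, n).
#' @export
runStudyEqtl <- function(expr, geno, covariates = NULL, pairs = NULL,
                         window = 1e6) {
  Y <- if (methods::is(expr, "ExpressionMatrix")) exprValues(expr) else expr
  G <- if (methods::is(geno, "GenotypeMatrix")) dosages(geno) else geno
  stopifnot(identical(colnames(Y), colnames(G)))
  if (is.null(pairs)) pairs <- mapCisPairs(expr, geno, window)
  mono <- rownames(G)[apply(G, 1, var) == 0]
  skipped <- pairs$snp %in% mono
  if (any(skipped))
    message(sum(skipped), " pairs skipped: monomorphic dosage")
  .study_eqtl_engine(Y, G, covariates, pairs[!skipped, , drop = FALSE])
}

#' Two-study cis-eQTL meta-analysis
#'
#' Joins the per-study scans on (gene, snp) and combines estimates by
#' fixed-effect inverse-variance weighting; pairs present in a single study
#' carry that study's estimate through unchanged.
#'
#' @param res1,res2 data.frames from [runStudyEqtl()] (res2 may be NULL).
#' @return data.frame (gene, snp, beta_s1, se_s1, p_s1, beta_s2, se_s2,
#'   p_s2, beta_meta, se_meta, z_meta, p_meta, n_studies).
#' @export
runMetaEqtl <- function(res1, res2 = NULL) {
  key1 <- paste(res1$gene, res1$snp)
  if (is.null(res2)) {
    out <- data.frame(gene = res1$gene, snp = res1$snp,
                      beta_s1 = res1$beta, se_s1 = res1$se, p_s1 = res1$p,
                      beta_s2 = NA_real_, se_s2 = NA_real_, p_s2 = NA_real_,
                      stringsAsFactors = FALSE)
  } else {
    key2 <- paste(res2$gene, res2$snp)
    keys <- union(key1, key2)
    i1 <- match(keys, key1); i2 <- match(keys, key2)
    out <- data.frame(
      gene = ifelse(is.na(i1), res2$gene[i2], res1$gene[i1]),
      snp = ifelse(is.na(i1), res2$snp[i2], res1$snp[i1]),
      beta_s1 = res1$beta[i1], se_s1 = res1$se[i1], p_s1 = res1$p[i1],
      beta_s2 = res2$beta[i2], se_s2 = res2$se[i2], p_s2 = res2$p[i2],
      stringsAsFactors = FALSE)
  }
  m <- metaFixedEffect(out$beta_s1, out$se_s1, out$beta_s2, out$se_s2)
  out$beta_meta <- m$beta; out$se_meta <- m$se
  out$z_meta <- m$z; out$p_meta <- m$p; out$n_studies <- m$n_studies
  out
}
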