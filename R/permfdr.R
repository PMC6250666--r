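#' Permutation null of the per-gene smallest meta-P
#'
#' At each of B permutations one shared random permutation of sample labels
#' is applied jointly to the expression matrix and the non-genetic
#' covariates (age, sex, hidden factors, cohort indicators), while the
#' genotypes and the genotype principal components keep their original
#' order. The full per-study regression and two-study meta-analysis chain is
#' re-run and the smallest meta-P per gene recorded.
#'
#' @param studies list of per-study inputs; each element is a list with
#'   \code{Y} (genes x samples normalised expression matrix or
#'   \linkS4class{ExpressionMatrix}), \code{G} (variants x samples dosages or
#'   \linkS4class{GenotypeMatrix}), \code{covar_perm} (samples x q matrix of
#'   covariates permuted with expression; may be NULL) and
#'   \code{covar_fixed} (samples x q2 matrix staying with the genotypes,
#'   i.e. genotype PCs; may be NULL).
#' @param pairs data.frame (gene, snp) of cis pairs shared by the studies.
#' @param B number of permutations (default 2000).
#' @param seed RNG seed.
#' @return genes x B matrix of permuted minimum meta-P values.
#' @export
permuteMinP <- function(studies, pairs, B = 2000L, seed = 1L) {
  if (B < 1L) stop("B must be >= 1")
  set.seed(seed)
  prep <- lapply(studies, function(s) {
    Y <- if (methods::is(s$Y, "ExpressionMatrix")) exprValues(s$Y) else s$Y
    G <- if (methods::is(s$G, "GenotypeMatrix")) dosages(s$G) else s$G
    sp <- pairs[pairs$gene %in% rownames(Y) & pairs$snp %in% rownames(G), ,
                drop = FALSE]
    list(Ys = t(Y), Gs = t(G), n = ncol(Y),
         cp = if (!is.null(s$covar_perm)) as.matrix(s$covar_perm),
         cf = if (!is.null(s$covar_fixed)) as.matrix(s$covar_fixed),
         gi = match(sp$gene, rownames(Y)), vi = match(sp$snp, rownames(G)),
         key = paste(sp$gene, sp$snp))
  })
  genes <- unique(pairs$gene)
  keys <- paste(pairs$gene, pairs$snp)
  gene_of_key <- factor(pairs$gene, levels = genes)
  null <- matrix(NA_real_, length(genes), B,
                 dimnames = list(genes, NULL))
  for (b in seq_len(B)) {
    bmat <- semat <- matrix(NA_real_, length(keys), length(prep))
    for (si in seq_along(prep)) {
      s <- prep[[si]]
      perm <- sample.int(s$n)
      X <- cbind(rep(1, s$n),
                 if (!is.null(s$cp)) s$cp[perm, , drop = FALSE], s$cf)
      Q <- qr.Q(qr(X))
      df <- s$n - ncol(X) - 1L
      Yp <- s$Ys[perm, , drop = FALSE]
      RY <- Yp - Q %*% crossprod(Q, Yp)
      RG <- s$Gs - Q %*% crossprod(Q, s$Gs)
      gg <- colSums(RG^2)[s$vi]
      yy <- colSums(RY^2)[s$gi]
      xy <- colSums(RY[, s$gi, drop = FALSE] * RG[, s$vi, drop = FALSE])
      beta <- xy / gg
      se <- sqrt(pmax(yy - beta * xy, 0) / df / gg)
      idx <- match(s$key, keys)
      bmat[idx, si] <- beta
      semat[idx, si] <- se
    }
    p_meta <- if (length(prep) >= 2L)
      metaFixedEffect(bmat[, 1], semat[, 1], bmat[, 2], semat[, 2])$p
    else 2 * pnorm(-abs(bmat[, 1] / semat[, 1]))
    null[, b] <- tapply(p_meta, gene_of_key, min, na.rm = TRUE)
  }
  null
}

#' Permutation-adjusted gene-level p-value
#'
#' \code{(1 + #\{null <= observed\}) / (B + 1)} — the pseudocount keeps the
#' adjusted p strictly positive.
#'
#' @param observed_min_p observed smallest meta-P of the gene.
#' @param null_vector its B permuted smallest meta-P values.
#' @export
adjustGeneP <- function(observed_min_p, null_vector) {
  (1 + sum(null_vector <= observed_min_p)) / (length(null_vector) + 1)
}

#' Storey q-values with smoother-estimated pi0
#'
#' Estimates the null proportion pi0 on the lambda grid
#' \code{seq(0.05, 0.95, 0.05)} with a df=3 smoothing spline (evaluated at
#' the largest lambda) and converts p-values into monotone q-values. With
#' fewer than 100 p-values, or when the smoother is unstable, pi0 falls back
#' to 1, in which case the q-values equal Benjamini-Hochberg adjusted p.
#'
#' @param p vector of p-values.
#' @param pi0 optional fixed pi0 override.
#' @return q-values, same order as \code{p}.
#' @export
qvaluesStorey <- function(p, pi0 = NULL) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (is.null(pi0)) {
    lambda <- seq(0.05, 0.95, 0.05)
    pi0 <- 1
    if (m >= 100) {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- tryCatch(smooth.spline(lambda, pi0_l, df = 3),
                      error = function(e) NULL)
      if (!is.null(fit)) {
        est <- predict(fit, x = max(lambda))$y
        if (is.finite(est) && est > 0) pi0 <- min(est, 1)
      }
    }
  }
  o <- order(p, decreasing = TRUE)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- pmin(cummin(q), 1)
  q[order(o)]
}

#' Genome-wide adjusted-P threshold
#'
#' The permutation-adjusted P of the gene whose q-value is closest to the
#' target FDR; ties are broken toward the smaller adjusted P.
#'
#' @param adjusted_ps,qs per-gene adjusted P and q-values.
#' @param target FDR target (default 0.05).
#' @export
genomewideThreshold <- function(adjusted_ps, qs, target = 0.05) {
  d <- abs(qs - target)
  cand <- which(d == min(d))
  min(adjusted_ps[cand])
}

#' Per-gene nominal threshold P_t,i
#'
#' Left-continuous (type-1) inversion of the gene's empirical null cdf of
#' smallest meta-P values: the smallest null value x with F_i(x) >= P_t.
#'
#' @param null_vector the gene's B permuted minimum meta-P values.
#' @param pt genome-wide threshold P_t.
#' @export
perGeneThreshold <- function(null_vector, pt) {
  s <- sort(null_vector)
  B <- length(s)
  s[min(max(ceiling(pt * B), 1L), B)]
}

#' Calibrate gene-level significance from a permutation null
#'
#' Combines the observed meta-scan with its permutation null into a
#' \linkS4class{PermutationCalibration}: per-gene adjusted P, Storey
#' q-values, the genome-wide threshold P_t and per-gene nominal thresholds
#' P_t,i.
#'
#' @param meta data.frame from [runMetaEqtl()].
#' @param null genes x B matrix from [permuteMinP()].
#' @param target FDR target for P_t (default 0.05).
#' @param pi0 optional fixed pi0 passed to [qvaluesStorey()].
#' @export
calibratePermutations <- function(meta, null, target = 0.05, pi0 = NULL) {
  genes <- rownames(null)
  obs <- vapply(genes, function(g)
    min(meta$p_meta[meta$gene == g]), numeric(1))
  adj <- vapply(genes, function(g)
    adjustGeneP(obs[[g]], null[g, ]), numeric(1))
  q <- setNames(qvaluesStorey(adj, pi0 = pi0), genes)
  pt <- genomewideThreshold(adj, q, target)
  pti <- setNames(apply(null, 1, perGeneThreshold, pt = pt), genes)
  methods::new("PermutationCalibration", null = null, observed = obs,
               adjusted = adj, qvalue = q, pt = pt, pt_gene = pti,
               B = ncol(null))
}

#' Call eGenes, significant pairs and best eSNPs
#'
#' An eGene has q < \code{fdr}; a significant pair belongs to an eGene and
#' has nominal meta-P <= the gene's threshold P_t,i; the best eSNP per eGene
#' is the smallest meta-P (ties broken by smaller bp position when a
#' \code{pos} column is present, then by snp id).
#'
#' @param meta data.frame from [runMetaEqtl()]; an optional \code{pos}
#'   column is used for tie-breaking.
#' @param calibration a \linkS4class{PermutationCalibration}.
#' @param fdr eGene q-value cutoff (default 0.05).
#' @return list: \code{egenes} (character), \code{pairs} (data.frame of
#'   significant pairs), \code{best} (data.frame gene/snp/p_meta).
#' @export
callEgenes <- function(meta, calibration, fdr = 0.05) {
  q <- geneQvalues(calibration)
  pti <- perGeneThresholds(calibration)
  egenes <- names(q)[q < fdr]
  sig <- meta[meta$gene %in% egenes &
              meta$p_meta <= pti[meta$gene], , drop = FALSE]
  best <- do.call(rbind, lapply(egenes, function(g) {
    mg <- meta[meta$gene == g, , drop = FALSE]
    mg <- mg[mg$p_meta == min(mg$p_meta), , drop = FALSE]
    if (nrow(mg) > 1L) {
      o <- if ("pos" %in% colnames(mg)) order(mg$pos, mg$snp)
           else order(mg$snp)
      mg <- mg[o, , drop = FALSE]
    }
    mg[1L, c("gene", "snp", "p_meta")]
  }))
  if (is.null(best))
    best <- data.frame(gene = character(), snp = character(),
                       p_meta = numeric())
  list(egenes = egenes, pairs = sig, best = best)
}
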