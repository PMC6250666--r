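#' Pseudo-phenotype: expression residualised on the GWAS SNP
#'
#' Residuals of the standard linear regression of normalised expression on
#' the GWAS SNP dosage (plus, by default, the usual covariates); mean 0 by
#' construction.
#'
#' @param expr_gene numeric vector of the gene's normalised expression.
#' @param gwas_dosage dosage vector of the GWAS SNP.
#' @param covariates optional samples x q covariate matrix.
#' @return residual vector.
#' @export
pseudoPhenotype <- function(expr_gene, gwas_dosage, covariates = NULL) {
  X <- cbind(1, gwas_dosage,
             if (!is.null(covariates)) as.matrix(covariates))
  resid(lm.fit(X, expr_gene))
}

#' Regulatory trait concordance score
#'
#' Within one interval: the expression of the eGene is residualised on the
#' GWAS SNP (pseudo-phenotype), the pseudo-phenotype is regressed on each of
#' the N interval SNPs, SNPs are ranked by descending p-value (highest p ->
#' rank 0) and the score is \code{(N - rank)/N} at the rank of the eQTL SNP.
#' A high score means conditioning on the GWAS SNP removed the eQTL signal,
#' i.e. both tag the same causal variant. Tied p-values receive average
#' ranks.
#'
#' @param interval_snps variant ids of all SNPs in the interval (must
#'   contain \code{gwas_snp} and \code{eqtl_snp}; N >= 2).
#' @param geno \linkS4class{GenotypeMatrix} with the interval dosages.
#' @param expr_gene normalised expression vector of the eGene.
#' @param gwas_snp,eqtl_snp the two sentinel variant ids.
#' @param covariates optional covariates used in both regressions
#'   (covariate-inclusive by default; pass NULL for the GWAS-SNP-only
#'   residualisation).
#' @param threshold colocalisation call threshold (default 0.9).
#' @return data.frame row: gwas_snp, eqtl_snp, n_snps, rank, rtc,
#'   colocalised.
#' @export
rtcScore <- function(interval_snps, geno, expr_gene, gwas_snp, eqtl_snp,
                     covariates = NULL, threshold = 0.9) {
  stopifnot(gwas_snp %in% interval_snps, eqtl_snp %in% interval_snps)
  N <- length(interval_snps)
  if (N < 2L) stop("interval must contain at least 2 SNPs")
  d <- dosages(geno)
  if (var(d[eqtl_snp, ]) == 0)
    stop("eQTL SNP is monomorphic in the interval panel")
  pseudo <- pseudoPhenotype(expr_gene, d[gwas_snp, ], covariates)
  pvals <- vapply(interval_snps, function(s) {
    if (var(d[s, ]) == 0) return(1)
    fitLinearAssociation(pseudo, d[s, ], covariates)$p
  }, numeric(1))
  # highest p -> rank 0; ties share their average rank
  rk <- rank(-pvals, ties.method = "average") - 1
  r <- unname(rk[eqtl_snp])
  data.frame(gwas_snp = gwas_snp, eqtl_snp = eqtl_snp, n_snps = N,
             rank = r, rtc = (N - r) / N,
             colocalised = (N - r) / N >= threshold,
             stringsAsFactors = FALSE)
}

#' Flag colocalised signals
#'
#' @param results data.frame with an \code{rtc} column (rows from
#'   [rtcScore()]).
#' @param threshold score threshold, inclusive (default 0.9).
#' @return the input with the \code{colocalised} flag (re)computed.
#' @export
callColocalisation <- function(results, threshold = 0.9) {
  if (!nrow(results)) {
    results$colocalised <- logical(0)
    return(results)
  }
  results$colocalised <- results$rtc >= threshold
  results
}
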