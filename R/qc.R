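#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the sum of the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count
#' (the plink convention).
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (vectorised).
#' @return exact two-sided p-value(s) in (0, 1].
#' @examples
#' hweExactTest(25, 50, 25)  # modal heterozygote count -> 1
#' @export
hweExactTest <- function(n_hom_ref, n_het, n_hom_alt) {
  mapply(.hwe_exact_one, n_hom_ref, n_het, n_hom_alt, USE.NAMES = FALSE)
}

.hwe_exact_one <- function(aa, ab, bb) {
  if (any(c(aa, ab, bb) < 0)) stop("genotype counts must be non-negative")
  n <- aa + ab + bb
  n_alt <- ab + 2L * bb               # minor-or-not is irrelevant: symmetric
  n_a <- min(n_alt, 2L * n - n_alt)   # rarer allele count
  if (n == 0L || n_a == 0L) return(1)
  het <- seq(n_a %% 2L, n_a, by = 2L) # feasible heterozygote counts
  # log P(het | n, n_a) up to a constant, via log-factorials
  lp <- lfactorial(n) - lfactorial((n_a - het) / 2) - lfactorial(het) -
    lfactorial(n - (n_a + het) / 2) + het * log(2)
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  obs <- pr[match(ab, het)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

.qc_report <- function(stage, reasons) {
  structure(list(stage = stage, excluded = reasons,
                 n_excluded = sum(unlist(reasons))), class = "QcReport")
}

#' @export
print.QcReport <- function(x, ...) {
  cat(sprintf("QcReport [%s]: %d excluded\n", x$stage, x$n_excluded))
  for (nm in names(x$excluded))
    cat(sprintf("  %-22s %d\n", nm, x$excluded[[nm]]))
  invisible(x)
}

#' Variant quality-control filter
#'
#' Drops variants failing any of: minor allele frequency below
#' \code{maf_min}; Hardy-Weinberg exact P below \code{hwe_p_min} (callers
#' pass 0.001 for a genotyped panel and 1e-6 for an imputed panel);
#' call rate below \code{call_rate_min}; imputation R^2 below
#' \code{impute_r2_min} (only when an \code{impR2} column is present);
#' duplicated (chrom, pos); non-SNP alleles; variants on Y/MT (and X when
#' \code{drop_sex_mt}). Dosages are rounded to the nearest genotype for the
#' MAF/HWE counts.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param maf_min,hwe_p_min,call_rate_min,impute_r2_min thresholds.
#' @param drop_sex_mt drop X/Y/MT variants.
#' @param hwe_test \code{"exact"} (default) or \code{"chisq"}.
#' @return list with the filtered \code{geno} and a \code{report}
#'   itemising exclusions per reason (first failing rule wins).
#' @export
filterVariants <- function(geno, maf_min = 0.05, hwe_p_min = 0.001,
                           call_rate_min = 0.95, impute_r2_min = 0.4,
                           drop_sex_mt = TRUE, hwe_test = c("exact", "chisq")) {
  hwe_test <- match.arg(hwe_test)
  v <- variantInfo(geno)
  d <- dosages(geno)
  reason <- rep(NA_character_, nrow(v))
  mark <- function(bad, why) {
    bad[is.na(bad)] <- FALSE
    reason[is.na(reason) & bad] <<- why
  }
  mark(duplicated(paste(v$chrom, v$pos)) |
       duplicated(paste(v$chrom, v$pos), fromLast = TRUE), "duplicated_pos")
  if (all(c("ref", "alt") %in% colnames(v)))
    mark(nchar(v$ref) != 1L | nchar(v$alt) != 1L |
         !(v$ref %in% c("A", "C", "G", "T")) |
         !(v$alt %in% c("A", "C", "G", "T")), "non_snp")
  if (drop_sex_mt)
    mark(v$chrom %in% c("X", "Y", "MT", "M", "chrX", "chrY", "chrM"),
         "sex_mt_chrom")
  call_rate <- rowMeans(!is.na(d))
  mark(call_rate < call_rate_min, "call_rate")
  if ("impR2" %in% colnames(v))
    mark(!is.na(v$impR2) & v$impR2 < impute_r2_min, "imputation_r2")
  g <- round(d)
  nAA <- rowSums(g == 0, na.rm = TRUE)
  nAa <- rowSums(g == 1, na.rm = TRUE)
  naa <- rowSums(g == 2, na.rm = TRUE)
  af <- (nAa + 2 * naa) / (2 * pmax(nAA + nAa + naa, 1L))
  maf <- pmin(af, 1 - af)
  mark(maf < maf_min, "maf")
  todo <- which(is.na(reason))
  if (length(todo)) {
    hp <- if (hwe_test == "exact")
      hweExactTest(nAA[todo], nAa[todo], naa[todo])
    else .hwe_chisq(nAA[todo], nAa[todo], naa[todo])
    bad <- rep(FALSE, nrow(v)); bad[todo] <- hp < hwe_p_min
    mark(bad, "hwe")
  }
  keep <- is.na(reason)
  if (!any(keep)) warning("no variants survive the QC filters")
  counts <- table(factor(reason[!keep]))
  list(geno = geno[keep, ],
       report = .qc_report("variants", as.list(counts)))
}

.hwe_chisq <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  p <- (2 * nAA + nAa) / (2 * n)
  e <- cbind(n * p^2, 2 * n * p * (1 - p), n * (1 - p)^2)
  o <- cbind(nAA, nAa, naa)
  x2 <- rowSums((o - e)^2 / pmax(e, .Machine$double.eps))
  ifelse(p %in% c(0, 1), 1, pchisq(x2, df = 1, lower.tail = FALSE))
}

#' Sample quality-control filter
#'
#' Removes samples whose genotype missing rate exceeds \code{miss_max} or
#' whose heterozygosity rate lies outside \code{het_sd} standard deviations
#' of the cohort mean. Relatedness/ancestry/sex exclusions are consumed as a
#' caller-provided id list (computing them is out of scope here).
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param miss_max maximum genotype missing rate.
#' @param het_sd heterozygosity-rate exclusion width in SD units.
#' @param exclude ids excluded a priori (IBD, ancestry, sex checks).
#' @return list: \code{keep} (sample ids retained) and \code{report}.
#' @export
filterSamples <- function(geno, miss_max = 0.05, het_sd = 3,
                          exclude = character()) {
  d <- dosages(geno)
  reason <- setNames(rep(NA_character_, ncol(d)), colnames(d))
  reason[colnames(d) %in% exclude] <- "caller_exclusion"
  miss <- colMeans(is.na(d))
  reason[is.na(reason) & miss > miss_max] <- "missing_rate"
  het <- colMeans(round(d) == 1, na.rm = TRUE)
  mu <- mean(het); s <- sd(het)
  if (is.finite(s) && s > 0)
    reason[is.na(reason) & abs(het - mu) > het_sd * s] <- "heterozygosity"
  keep <- names(reason)[is.na(reason)]
  counts <- table(factor(reason[!is.na(reason)]))
  list(keep = keep, report = .qc_report("samples", as.list(counts)))
}

#' Expression-level gene filter
#'
#' A gene is kept iff its TPM is strictly greater than \code{tpm_min} in at
#' least \code{frac} of the samples within EVERY batch; sex-chromosome genes
#' are removed when \code{drop_sex}.
#'
#' @param expr an \linkS4class{ExpressionMatrix} at stage \code{"tpm"};
#'   batches are read from the \code{batch} sample covariate (single batch
#'   when absent).
#' @param tpm_min,frac expression threshold and required sample fraction.
#' @param drop_sex remove genes on X/Y.
#' @return list: filtered \code{expr} and \code{report}.
#' @export
filterGenes <- function(expr, tpm_min = 0.1, frac = 0.5, drop_sex = TRUE) {
  stopifnot(exprStage(expr) == "tpm")
  v <- exprValues(expr)
  gi <- geneInfo(expr)
  si <- sampleInfo(expr)
  batch <- if ("batch" %in% colnames(si)) si$batch else rep("all", ncol(v))
  ok <- rep(TRUE, nrow(v))
  for (b in unique(batch)) {
    vb <- v[, batch == b, drop = FALSE]
    ok <- ok & rowMeans(vb > tpm_min) >= frac
  }
  reason <- ifelse(!ok, "low_expression", NA_character_)
  if (drop_sex) {
    sexchr <- gi$chrom %in% c("X", "Y", "chrX", "chrY")
    reason[is.na(reason) & sexchr] <- "sex_chrom"
  }
  keep <- is.na(reason)
  counts <- table(factor(reason[!keep]))
  list(expr = expr[keep, ], report = .qc_report("genes", as.list(counts)))
}
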