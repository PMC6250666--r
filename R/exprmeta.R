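#' Stouffer's weighted Z meta-analysis
#'
#' \code{Z = sum(w_k z_k) / sqrt(sum(w_k^2))} with study z-scores signed by
#' the effect direction; the conventional sample-size weights are
#' \code{w_k = sqrt(n_k)}.
#'
#' @param study_zs signed per-study z-scores.
#' @param weights per-study weights (default \code{sqrt(ns)} when
#'   \code{ns} given, else equal).
#' @param ns per-study sample sizes (used only for the default weights).
#' @return list(Z, p).
#' @export
stoufferWeighted <- function(study_zs, weights = NULL, ns = NULL) {
  if (is.null(weights))
    weights <- if (is.null(ns)) rep(1, length(study_zs)) else sqrt(ns)
  stopifnot(length(weights) == length(study_zs))
  Z <- sum(weights * study_zs) / sqrt(sum(weights^2))
  list(Z = Z, p = 2 * pnorm(-abs(Z)))
}

#' Signed z-score from a two-sided p and an effect direction
#'
#' @param p two-sided p-value.
#' @param direction sign of the effect (e.g. of the log2 fold difference).
#' @export
signedZ <- function(p, direction) {
  sign(direction) * qnorm(p / 2, lower.tail = FALSE)
}

#' Olkin-Pratt fixed-effect meta-analysis of correlations
#'
#' Each study correlation is first de-biased,
#' \code{G_k = r_k (1 + (1 - r_k^2) / (2 (n_k - 3)))}, then pooled with
#' fixed-effect weights \code{n_k - 1}; the p-value uses the Fisher z of the
#' pooled estimate at effective n = sum(n_k).
#'
#' @param study_rs per-study Pearson correlations (|r| < 1).
#' @param study_ns per-study sample sizes (>= 4).
#' @param weights pooling weights; \code{"n-1"} (default) or \code{"n-3"}.
#' @return list(r_meta, p, G).
#' @export
olkinPrattMeta <- function(study_rs, study_ns, weights = c("n-1", "n-3")) {
  weights <- match.arg(weights)
  stopifnot(all(abs(study_rs) < 1), all(study_ns >= 4))
  G <- study_rs * (1 + (1 - study_rs^2) / (2 * (study_ns - 3)))
  w <- if (weights == "n-1") study_ns - 1 else study_ns - 3
  r_meta <- sum(w * G) / sum(w)
  n_eff <- sum(study_ns)
  z <- atanh(min(max(r_meta, -1 + 1e-12), 1 - 1e-12)) * sqrt(n_eff - 3)
  list(r_meta = r_meta, p = 2 * pnorm(-abs(z)), G = G)
}

#' Cochran's Q heterogeneity test across studies
#'
#' Correlation mode: Q on the Fisher-z scale with inverse-variance weights
#' \code{n_k - 3}. Case-control mode: Q over the signed z-scores (unit
#' variance each). Chi-square reference with k-1 df.
#'
#' @param stats per-study correlations (\code{mode = "correlation"}) or
#'   signed z-scores (\code{mode = "case_control"}).
#' @param ns per-study sample sizes (correlation mode only).
#' @param mode one of \code{"correlation"}, \code{"case_control"}.
#' @return list(Q, df, p).
#' @export
heterogeneityQ <- function(stats, ns = NULL,
                           mode = c("correlation", "case_control")) {
  mode <- match.arg(mode)
  if (mode == "correlation") {
    stopifnot(!is.null(ns))
    y <- atanh(stats)
    w <- ns - 3
  } else {
    y <- stats
    w <- rep(1, length(stats))
  }
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  df <- length(y) - 1L
  list(Q = Q, df = df, p = pchisq(Q, df, lower.tail = FALSE))
}

#' Bonferroni-corrected significance threshold
#'
#' @param m number of tests in the family.
#' @param alpha family-wise alpha (default 0.05).
#' @return \code{alpha / m}.
#' @examples
#' bonferroni(29)  # 0.0017
#' bonferroni(7)   # 0.0071
#' bonferroni(11)  # 0.0045
#' @export
bonferroni <- function(m, alpha = 0.05) {
  stopifnot(m >= 1)
  alpha / m
}

#' Direction-consistency check against the GWAS risk allele
#'
#' Concordant iff the sign of the meta effect equals the sign implied by
#' composing the risk-allele eQTL direction with the phenotype definition:
#' a disease-type phenotype is expected to move WITH the risk-driven
#' expression change, an eGFR-type (protective-scale) phenotype AGAINST it.
#'
#' @param meta_direction sign of the meta-analysed expression-phenotype
#'   effect.
#' @param eqtl_direction sign of the risk-allele effect on expression.
#' @param phenotype \code{"disease"} or \code{"egfr"}.
#' @return \code{"concordant"}, \code{"discordant"} or
#'   \code{"indeterminate"} (zero effect).
#' @export
consistencyCheck <- function(meta_direction, eqtl_direction,
                             phenotype = c("disease", "egfr")) {
  phenotype <- match.arg(phenotype)
  if (meta_direction == 0 || eqtl_direction == 0) return("indeterminate")
  expected <- if (phenotype == "disease") sign(eqtl_direction)
              else -sign(eqtl_direction)
  if (sign(meta_direction) == expected) "concordant" else "discordant"
}

#' Cross-study expression-phenotype meta-analysis
#'
#' For each gene: case-control studies (signed z from p and the fold-change
#' direction) are combined by Stouffer's sqrt(n)-weighted Z; correlation
#' studies by the Olkin-Pratt fixed-effect pool. Heterogeneity is examined
#' with Cochran's Q, and a gene is called significant only when its meta p
#' falls below the Bonferroni threshold AND no heterogeneity is detected
#' (Q p >= 0.05).
#'
#' @param effects data.frame with columns study, gene, mode
#'   (\code{"case_control"}/\code{"correlation"}), stat (log2 fold
#'   difference or Pearson r), p (case-control only), n.
#' @param m Bonferroni family size (default: number of distinct
#'   gene x mode analyses).
#' @param alpha family-wise alpha (default 0.05).
#' @return data.frame per gene x mode: estimate (Z or pooled r), p, Q, Q_p,
#'   threshold, significant.
#' @export
runExprMeta <- function(effects, m = NULL, alpha = 0.05) {
  key <- interaction(effects$gene, effects$mode, drop = TRUE)
  if (is.null(m)) m <- nlevels(key)
  thr <- bonferroni(m, alpha)
  out <- lapply(split(effects, key), function(d) {
    mode <- d$mode[1]
    if (mode == "case_control") {
      z <- signedZ(d$p, d$stat)
      mt <- stoufferWeighted(z, ns = d$n)
      est <- mt$Z; p <- mt$p
      het <- heterogeneityQ(z, mode = "case_control")
    } else {
      mt <- olkinPrattMeta(d$stat, d$n)
      est <- mt$r_meta; p <- mt$p
      het <- heterogeneityQ(d$stat, d$n, mode = "correlation")
    }
    data.frame(gene = d$gene[1], mode = mode, k = nrow(d),
               estimate = est, p = p, Q = het$Q, Q_p = het$p,
               threshold = thr,
               significant = p < thr & het$p >= 0.05,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
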